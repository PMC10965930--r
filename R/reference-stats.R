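# Published per-group summary statistics for the 10 subcortical structures:
# mean (SD) susceptibility in ppm and volume in mm^3 for healthy controls
# (HC, n = 50), major depressive disorder (MDD, n = 49) and schizophrenia
# (SCZ, n = 24), with the printed one-way ANOVA F statistic alongside.
# These printed cells are the inputs for the summary-statistics ANOVA
# reproduction and the defaults of the cohort simulator.

#' Reference subcortical summary statistics
#'
#' Long-format table of published group means and standard deviations of
#' bilateral-averaged subcortical susceptibility (ppm) and volume (mm^3),
#' one row per region x measure x group, with group sizes and the published
#' F statistic for the three-group comparison.
#'
#' @return Data frame with columns `region`, `measure`
#'   (`"susceptibility_ppm"` / `"volume_mm3"`), `group`
#'   (`"HC"`/`"MDD"`/`"SCZ"`), `mean`, `sd`, `n`, `f_published`.
#' @export
subcortical_reference_stats <- function() {
  regions <- subcortical_structures()
  sus <- list(
    # region: HC mean/sd, MDD mean/sd, SCZ mean/sd, published F
    "red nucleus"             = c(0.094, 0.039, 0.099, 0.036, 0.097, 0.035, 0.25),
    "substantia nigra"        = c(0.11, 0.029, 0.102, 0.029, 0.092, 0.031, 2.72),
    "caudate"                 = c(0.019, 0.010, 0.023, 0.011, 0.020, 0.011, 2.22),
    "putamen"                 = c(0.035, 0.017, 0.038, 0.016, 0.040, 0.019, 1.05),
    "thalamus"                = c(0.0011, 0.011, 0.0019, 0.011, 0.00010, 0.0088, 0.29),
    "hippocampus"             = c(-0.012, 0.0079, -0.0078, 0.0098, -0.0088, 0.0093, 2.58),
    "nucleus accumbens"       = c(0.0063, 0.0089, 0.015, 0.015, 0.012, 0.015, 5.25),
    "amygdala"                = c(-0.014, 0.0092, -0.0073, 0.011, -0.0097, 0.011, 4.90),
    "globus pallidus externa" = c(0.11, 0.029, 0.117, 0.024, 0.112, 0.023, 1.01),
    "globus pallidus interna" = c(0.11, 0.030, 0.109, 0.025, 0.107, 0.019, 0.18))
  vol <- list(
    "red nucleus"             = c(185, 17, 181, 15, 177, 15, 2.02),
    "substantia nigra"        = c(480, 45, 471, 38, 461, 39, 1.85),
    "caudate"                 = c(3044, 311, 3073, 251, 2976, 389, 0.81),
    "putamen"                 = c(2991, 321, 3032, 268, 2920, 334, 1.10),
    "thalamus"                = c(5542, 471, 5476, 450, 5234, 564, 3.38),
    "hippocampus"             = c(2682, 217, 2624, 198, 2519, 215, 4.97),
    "nucleus accumbens"       = c(316, 33, 310, 27, 304, 38, 1.23),
    "amygdala"                = c(1125, 101, 1112, 89, 1075, 105, 2.14),
    "globus pallidus externa" = c(1143, 110, 1149, 88, 1127, 103, 0.39),
    "globus pallidus interna" = c(369, 35, 366, 28, 362, 32, 0.46))
  n <- c(HC = 50L, MDD = 49L, SCZ = 24L)
  expand <- function(lst, measure) {
    do.call(rbind, lapply(regions, function(r) {
      v <- lst[[r]]
      data.frame(region = r, measure = measure,
                 group = c("HC", "MDD", "SCZ"),
                 mean = v[c(1, 3, 5)], sd = v[c(2, 4, 6)],
                 n = as.integer(n), f_published = v[7],
                 stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(expand(sus, "susceptibility_ppm"), expand(vol, "volume_mm3"))
  rownames(out) <- NULL
  out
}

#' Default cohort group sizes
#' @return Named integer vector (HC, MDD, SCZ).
#' @export
default_group_sizes <- function() c(HC = 50L, MDD = 49L, SCZ = 24L)
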