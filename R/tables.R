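# Orchestration of the per-region statistics and rendering of the
# susceptibility/volume summary tables.

#' Full group-level analysis of a cohort table
#'
#' For each measure (susceptibility, volume): per-region one-way ANOVA with
#' BH-FDR across the regions (each measure its own FDR family), Tukey HSD
#' post hocs for regions whose FDR-corrected q passes the gate, assumption
#' checks, and the standardized group-by-volume GLM for susceptibility in
#' the gated regions (or an explicit region list).
#'
#' @param cohort Long cohort table (as from [simulate_cohort()] or
#'   [cohort_extract()]).
#' @param gate Omnibus significance gate for post hocs / GLM follow-up
#'   (FDR-corrected q, default 0.05).
#' @param glm_regions Regions to fit the GLM in; default: regions passing
#'   the susceptibility gate.
#' @param fdr_across_pairs Second-level BH across Tukey pairs (default
#'   TRUE).
#' @return List: `anova` (region x measure rows with F, df, p, q),
#'   `posthoc`, `glm`, `assumptions`.
#' @export
run_group_stats <- function(cohort, gate = 0.05, glm_regions = NULL,
                            fdr_across_pairs = TRUE) {
  if (!nrow(cohort))
    stop("cohort table is empty (were all subjects excluded upstream?)")
  measures <- c("susceptibility_ppm", "volume_mm3")
  regions <- unique(cohort$region)
  anova_tab <- do.call(rbind, lapply(measures, function(ms) {
    rows <- do.call(rbind, lapply(regions, function(r) {
      d <- cohort[cohort$region == r, ]
      a <- anova_oneway(d[[ms]], d$group)
      cbind(data.frame(region = r, measure = ms, stringsAsFactors = FALSE), a)
    }))
    rows$q <- fdr_bh(rows$p)
    rows
  }))

  posthoc <- do.call(rbind, lapply(seq_len(nrow(anova_tab)), function(i) {
    r <- anova_tab$region[i]; ms <- anova_tab$measure[i]
    d <- cohort[cohort$region == r, ]
    ph <- suppressMessages(
      tukey_hsd(d[[ms]], d$group, anova_q = anova_tab$q[i], gate = gate,
                fdr_across_pairs = fdr_across_pairs))
    if (!nrow(ph)) return(NULL)
    cbind(data.frame(region = r, measure = ms, stringsAsFactors = FALSE), ph)
  }))

  if (is.null(glm_regions)) {
    sus <- anova_tab[anova_tab$measure == "susceptibility_ppm", ]
    glm_regions <- sus$region[sus$q < gate]
  }
  glm_tab <- if (length(glm_regions))
    do.call(rbind, lapply(glm_regions, function(r) {
      g <- tryCatch(glm_group_volume(cohort, r), error = function(e) {
        warning("GLM skipped for region ", r, ": ", conditionMessage(e))
        NULL
      })
      if (is.null(g)) return(NULL)
      attr(g, "fit") <- NULL
      cbind(data.frame(region = r, stringsAsFactors = FALSE), g)
    }))
  else NULL

  assumptions <- do.call(rbind, lapply(measures, function(ms) {
    do.call(rbind, lapply(regions, function(r) {
      ck <- check_assumptions(cohort, r, measure = ms)
      sh <- ck$shapiro
      cbind(data.frame(region = r, measure = ms, stringsAsFactors = FALSE),
            sh, data.frame(levene_F = ck$levene$F, levene_p = ck$levene$p))
    }))
  }))

  list(anova = anova_tab, posthoc = posthoc, glm = glm_tab,
       assumptions = assumptions)
}

#' Render summary tables in the published layout
#'
#' One table per measure: per-group "mean (SD)" cells, the F statistic,
#' raw p and FDR-corrected q, and the post hoc Tukey p-values for gated
#' regions.  Written as CSV and Markdown.
#'
#' @param cohort Long cohort table.
#' @param results Output of [run_group_stats()] on the same cohort.
#' @param out_dir Directory to write `table_susceptibility.{csv,md}` and
#'   `table_volume.{csv,md}` into; `NULL` to skip writing.
#' @return Named list of the two data frames, invisibly if written.
#' @export
build_tables <- function(cohort, results, out_dir = NULL) {
  fmt <- function(x) vapply(x, function(v)
    if (is.na(v)) "" else formatC(signif(v, 3), format = "fg", flag = "#"),
    character(1))
  groups <- c("HC", "MDD", "SCZ")
  tabs <- lapply(c(susceptibility_ppm = "susceptibility_ppm",
                   volume_mm3 = "volume_mm3"), function(ms) {
    an <- results$anova[results$anova$measure == ms, ]
    rows <- lapply(seq_len(nrow(an)), function(i) {
      r <- an$region[i]
      d <- cohort[cohort$region == r, ]
      cells <- vapply(groups, function(g) {
        x <- d[[ms]][d$group == g]
        if (!length(x)) return("")
        paste0(fmt(mean(x)), " (", fmt(stats::sd(x)), ")")
      }, character(1))
      ph <- results$posthoc
      ph <- if (!is.null(ph)) ph[ph$region == r & ph$measure == ms, ] else NULL
      ph_txt <- if (!is.null(ph) && nrow(ph))
        paste(sprintf("%s: %s", ph$pair, fmt(ph$p_fdr)), collapse = "; ")
      else "-"
      data.frame(region = r, HC = cells[1], MDD = cells[2], SCZ = cells[3],
                 F = fmt(an$F[i]), p = fmt(an$p[i]), q = fmt(an$q[i]),
                 posthoc = ph_txt, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  names(tabs) <- c("susceptibility", "volume")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tabs)) {
      utils::write.csv(tabs[[nm]],
                       file.path(out_dir, paste0("table_", nm, ".csv")),
                       row.names = FALSE)
      writeLines(render_markdown_table(tabs[[nm]]),
                 file.path(out_dir, paste0("table_", nm, ".md")))
    }
    return(invisible(tabs))
  }
  tabs
}

render_markdown_table <- function(df) {
  esc <- function(x) gsub("\\|", "/", as.character(x))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(row)
    paste0("| ", paste(esc(row), collapse = " | "), " |"))
  c(header, sep, body)
}
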