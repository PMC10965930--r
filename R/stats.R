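# Group-level statistics for per-region susceptibility/volume tables:
# one-way ANOVA (raw data or printed summaries) with Benjamini-Hochberg FDR,
# Tukey HSD post hocs, the standardized group-by-volume GLM, ANCOVA with
# handedness, Pearson correlation screens and assumption checks.

#' One-way ANOVA on raw values
#'
#' Classic between/within sums-of-squares decomposition,
#' `F = MSB / MSW` with df `(k - 1, N - k)`.
#'
#' @param values Numeric vector.
#' @param group_labels Factor or character vector of group membership.
#' @return Data frame with `F`, `df1`, `df2`, `p`.
#' @export
anova_oneway <- function(values, group_labels) {
  g <- factor(group_labels)
  stopifnot(length(values) == length(g), nlevels(g) >= 2)
  cnt <- table(g)
  if (any(cnt < 2))
    stop("every group needs at least 2 members; too small: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  k <- nlevels(g)
  N <- length(values)
  gm <- mean(values)
  m <- tapply(values, g, mean)
  ssb <- sum(cnt * (m - gm)^2)
  ssw <- sum((values - m[as.integer(g)])^2)
  f <- if (ssb == 0) 0 else (ssb / (k - 1)) / (ssw / (N - k))
  data.frame(F = f, df1 = k - 1, df2 = N - k,
             p = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
}

#' One-way ANOVA from group summary statistics
#'
#' Recomputes the F statistic from per-group means, SDs and sizes:
#' `SSB = sum(n_i (m_i - m)^2)` with the weighted grand mean `m`, and
#' `SSW = sum((n_i - 1) s_i^2)`.  Applied to printed table cells this
#' reproduces the published F statistics without raw data.
#'
#' @param means,sds,n Numeric vectors, one entry per group.
#' @return Data frame with `F`, `df1`, `df2`, `p`.
#' @export
anova_from_summary <- function(means, sds, n) {
  k <- length(means)
  stopifnot(length(sds) == k, length(n) == k, k >= 2,
            all(sds > 0), all(n >= 2))
  N <- sum(n)
  if (N <= k) stop("total sample size must exceed the number of groups")
  gm <- sum(n * means) / N
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum((n - 1) * sds^2)
  f <- if (ssb == 0) 0 else (ssb / (k - 1)) / (ssw / (N - k))
  data.frame(F = f, df1 = k - 1, df2 = N - k,
             p = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up procedure: `q_(i) = min_{j >= i} p_(j) m / j` on the order
#' statistics, mapped back to the input order.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Vector of q-values in the input order.
#' @export
fdr_bh <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  q_sorted <- rev(cummin(rev(p_values[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Tukey HSD post hoc comparisons
#'
#' All pairwise group comparisons using the pooled within-group mean square:
#' `t = (m_i - m_j) / sqrt(MSW (1/n_i + 1/n_j))`, with the adjusted p-value
#' from the studentized-range distribution (`q = |t| sqrt(2)`, k groups,
#' df `N - k`).  Optionally an additional BH-FDR across the pairs is layered
#' on the Tukey-adjusted p-values.  When `anova_q` is supplied, the
#' comparisons run only if it passes `gate` (post hocs follow a significant
#' omnibus test).
#'
#' @param values Numeric vector.
#' @param group_labels Group membership.
#' @param anova_q Optional omnibus (FDR-corrected) p-value to gate on.
#' @param gate Significance gate (default 0.05).
#' @param fdr_across_pairs Apply BH across the pairwise Tukey p-values
#'   (default TRUE).
#' @return Data frame with one row per pair: `pair`, `diff`, `t`, `p_tukey`,
#'   `p_fdr`; zero rows (with a message) if the gate is not met.
#' @export
tukey_hsd <- function(values, group_labels, anova_q = NULL, gate = 0.05,
                      fdr_across_pairs = TRUE) {
  g <- factor(group_labels)
  stopifnot(length(values) == length(g), nlevels(g) >= 2)
  empty <- data.frame(pair = character(), diff = numeric(), t = numeric(),
                      p_tukey = numeric(), p_fdr = numeric())
  if (!is.null(anova_q) && anova_q >= gate) {
    message("omnibus q = ", signif(anova_q, 3), " >= gate ", gate,
            "; post hoc comparisons skipped")
    return(empty)
  }
  k <- nlevels(g)
  n <- tapply(values, g, length)
  m <- tapply(values, g, mean)
  dfw <- length(values) - k
  msw <- sum(tapply(values, g, function(x) sum((x - mean(x))^2))) / dfw
  combs <- utils::combn(levels(g), 2)
  res <- apply(combs, 2, function(pr) {
    i <- pr[2]; j <- pr[1]          # later level minus earlier (MDD - HC)
    d <- m[[i]] - m[[j]]
    se <- sqrt(msw * (1 / n[[i]] + 1 / n[[j]]))
    tt <- if (se > 0) d / se else 0
    p <- if (se > 0)
      stats::ptukey(abs(tt) * sqrt(2), k, dfw, lower.tail = FALSE)
    else 1
    data.frame(pair = paste(i, j, sep = "-"), diff = d, t = tt,
               p_tukey = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_fdr <- if (fdr_across_pairs) fdr_bh(res$p_tukey) else res$p_tukey
  rownames(res) <- NULL
  res
}

#' Standardized group-by-volume general linear model
#'
#' Ordinary least squares of pooled-z-scored susceptibility on group
#' (treatment contrasts, HC reference), pooled-z-scored volume, and their
#' interaction; because susceptibility and volume carry different units,
#' both are standardized over the full sample before fitting.  The
#' interaction terms test whether the volume-susceptibility slope differs
#' by diagnostic group.  BH-FDR is applied across the five non-intercept
#' terms within the region.
#'
#' @param table Cohort table (long format, as from [simulate_cohort()]).
#' @param region Region name to analyse.
#' @return Data frame with one row per term: `term`, `B`, `SE`, `t`, `p`,
#'   `q` (`q` is `NA` for the intercept); attribute `fit` holds the `lm`
#'   object.
#' @export
glm_group_volume <- function(table, region) {
  d <- table[table$region == region, ]
  if (!nrow(d)) stop("region not present: ", region)
  d$group <- factor(d$group, levels = c("HC", "MDD", "SCZ"))
  if (any(is.na(d$group)) || nlevels(droplevels(d$group)) < 3)
    stop("all three groups (HC, MDD, SCZ) required")
  if (stats::sd(d$susceptibility_ppm) == 0 || stats::sd(d$volume_mm3) == 0)
    stop("zero variance in susceptibility or volume for region ", region,
         "; standardized GLM undefined")
  d$chi_z <- as.numeric(scale(d$susceptibility_ppm))
  d$vol_z <- as.numeric(scale(d$volume_mm3))
  fit <- stats::lm(chi_z ~ group * vol_z, data = d)
  if (fit$rank < 6) stop("design matrix is rank deficient")
  cf <- summary(fit)$coefficients
  out <- data.frame(term = rownames(cf), B = cf[, 1], SE = cf[, 2],
                    t = cf[, 3], p = cf[, 4], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$q <- NA_real_
  non_int <- out$term != "(Intercept)"
  out$q[non_int] <- fdr_bh(out$p[non_int])
  attr(out, "fit") <- fit
  out
}

#' One-way ANCOVA with handedness as covariate
#'
#' OLS of the outcome on group plus categorical handedness; the group effect
#' is the partial (type II) F test adjusting for handedness.  Handedness
#' categories absent from the data are dropped with a message.
#'
#' @param values Numeric outcome.
#' @param group_labels Group membership.
#' @param handedness Character/factor with levels among
#'   `right`, `mixed`, `left`.
#' @return Data frame with `F`, `df1`, `df2`, `p` for the group term.
#' @export
ancova_handedness <- function(values, group_labels, handedness) {
  g <- factor(group_labels)
  h <- factor(handedness)
  stopifnot(length(values) == length(g), length(values) == length(h))
  h <- droplevels(h)
  full_levels <- c("right", "mixed", "left")
  missing_lv <- setdiff(full_levels, levels(h))
  if (length(missing_lv))
    message("handedness categories absent and dropped: ",
            paste(missing_lv, collapse = ", "))
  d <- data.frame(y = values, g = g, h = h)
  fit <- stats::lm(y ~ g + h, data = d)
  a2 <- car::Anova(fit, type = 2)
  i <- match("g", rownames(a2))
  data.frame(F = a2$`F value`[i], df1 = a2$Df[i],
             df2 = stats::df.residual(fit), p = a2$`Pr(>F)`[i])
}

#' Pearson correlation screen against clinical variables
#'
#' Pairwise-complete Pearson correlations between a region's susceptibility
#' and each clinical variable, with two-sided p-values from the t transform.
#' Variables with fewer than 3 complete pairs or zero variance are flagged
#' rather than dropped.
#'
#' @param table Cohort table (long format).
#' @param region Region to analyse.
#' @param clinical_vars Character vector of column names.
#' @param group Optional group to restrict to (correlations are typically
#'   within-group because missingness differs by group).
#' @return Data frame with `variable`, `r`, `n`, `p`, `flagged`.
#' @export
correlation_screen <- function(table, region, clinical_vars,
                               group = NULL) {
  d <- table[table$region == region, ]
  if (!is.null(group)) d <- d[d$group %in% group, ]
  if (!nrow(d)) stop("no rows for region ", region)
  out <- lapply(clinical_vars, function(v) {
    if (!v %in% names(d)) stop("unknown clinical variable: ", v)
    ok <- stats::complete.cases(d$susceptibility_ppm, d[[v]])
    x <- d$susceptibility_ppm[ok]; y <- d[[v]][ok]
    if (sum(ok) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(variable = v, r = NA_real_, n = sum(ok),
                        p = NA_real_, flagged = TRUE))
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(variable = v, r = unname(ct$estimate), n = sum(ok),
               p = ct$p.value, flagged = FALSE)
  })
  do.call(rbind, out)
}

#' Normality and homogeneity-of-variance checks
#'
#' Shapiro-Wilk per group and Levene's test (centred on the mean) across
#' groups for one region and measure.  Results are reported only; nothing
#' downstream is gated on them.
#'
#' @param table Cohort table (long format).
#' @param region Region to check.
#' @param measure Column to check (default `susceptibility_ppm`).
#' @return List with data frames `shapiro` (`group`, `W`, `p`, `flagged`)
#'   and `levene` (`F`, `df1`, `df2`, `p`).
#' @export
check_assumptions <- function(table, region,
                              measure = "susceptibility_ppm") {
  d <- table[table$region == region, ]
  if (!nrow(d)) stop("no rows for region ", region)
  g <- factor(d$group)
  y <- d[[measure]]
  sh <- lapply(levels(g), function(lv) {
    x <- y[g == lv]
    if (length(x) < 3 || stats::sd(x) == 0)
      return(data.frame(group = lv, W = NA_real_, p = NA_real_,
                        flagged = TRUE))
    s <- stats::shapiro.test(x)
    data.frame(group = lv, W = unname(s$statistic), p = s$p.value,
               flagged = FALSE)
  })
  lev <- car::leveneTest(y ~ g, center = mean)
  list(shapiro = do.call(rbind, sh),
       levene = data.frame(F = lev$`F value`[1], df1 = lev$Df[1],
                           df2 = lev$Df[2], p = lev$`Pr(>F)`[1]))
}
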