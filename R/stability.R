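# Feature-level stability statistics: signed percentage difference of each
# feature between rotated (R5..R80) and baseline (R0) extractions, IQR of
# those differences with Student-t confidence intervals, and Spearman rank
# trends of |%diff| against the rotation-set label with effect-size strata.

#' Signed percentage difference
#'
#' `100 * (f_rot - f_0) / max(|f_0|, eps)`. The epsilon guard keeps the
#' value finite when the baseline is (near) zero; the recommended guard is
#' scale-aware: `1e-6 *` the per-feature cohort median absolute baseline,
#' floored at machine epsilon (see [feature_stability()]).
#'
#' @param f_rot,f_0 feature values (vectors recycle).
#' @param eps denominator floor (> 0).
#' @return signed percentage difference(s).
#' @export
percent_difference <- function(f_rot, f_0, eps = .Machine$double.eps) {
  100 * (f_rot - f_0) / pmax(abs(f_0), eps)
}

#' Per-label IQR with a Student-t confidence interval of the mean
#'
#' @param values_by_label named list mapping rotation label to a vector of
#'   percentage differences (>= 2 labels with >= 4 values each).
#' @param conf confidence level (default 0.95).
#' @return list with `per_label_iqr`, `mean_iqr`, `ci` (length-2), `n`.
#' @export
iqr_with_ci <- function(values_by_label, conf = 0.95) {
  stopifnot(length(values_by_label) >= 2)
  iqrs <- vapply(values_by_label, function(v) {
    q <- quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    q[2] - q[1]
  }, numeric(1))
  n <- length(iqrs)
  m <- mean(iqrs)
  s <- sd(iqrs)
  half <- if (n > 1 && is.finite(s)) qt(1 - (1 - conf) / 2, n - 1) * s / sqrt(n) else 0
  list(per_label_iqr = iqrs, mean_iqr = m, ci = c(m - half, m + half), n = n)
}

#' Effect-size stratum of a Spearman coefficient
#'
#' trivial `|CC| < 0.1`, weak `0.1 <= |CC| < 0.3`,
#' moderate `0.3 <= |CC| < 0.7`, strong `|CC| >= 0.7` (boundaries
#' inclusive on the left).
#'
#' @param cc correlation coefficient.
#' @return character stratum.
#' @export
effect_stratum <- function(cc) {
  a <- abs(cc)
  if (a < 0.1) "trivial" else if (a < 0.3) "weak"
  else if (a < 0.7) "moderate" else "strong"
}

#' Spearman trend of percentage differences against rotation label
#'
#' Pools all (label, y) points, with `y = |%diff|` by default (signed
#' differences of opposite sign would cancel a monotone spread; a signed
#' mode is available). Tie-corrected two-sided test. A constant `y` has an
#' undefined coefficient and returns CC = 0, p = 1 with a warning.
#'
#' @param pd_by_label named list mapping label (degrees) to a vector of
#'   percentage differences.
#' @param magnitude correlate `|%diff|` (default) instead of signed values.
#' @return list with `cc`, `p`, `stratum`, `n`, and
#'   `significant_nontrivial` (p < 0.05 and |CC| >= 0.1).
#' @export
spearman_vs_rotation <- function(pd_by_label, magnitude = TRUE) {
  labs <- as.numeric(names(pd_by_label))
  stopifnot(length(labs) >= 3)
  x <- rep(labs, lengths(pd_by_label))
  y <- unlist(pd_by_label, use.names = FALSE)
  if (magnitude) y <- abs(y)
  if (length(x) < 10) stop("need at least 10 pooled points")
  if (length(unique(y)) == 1L) {
    warning("constant response; Spearman coefficient undefined, returning 0")
    return(list(cc = 0, p = 1, stratum = "trivial", n = length(x),
                significant_nontrivial = FALSE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  cc <- unname(ct$estimate)
  p <- ct$p.value
  list(cc = cc, p = p, stratum = effect_stratum(cc), n = length(x),
       significant_nontrivial = isTRUE(p < 0.05 && abs(cc) >= 0.1))
}

#' Feature-level stability analysis of a rotated-cohort feature table
#'
#' For every (channel, category, feature): per-patient signed percentage
#' differences against the patient's R0 value at each rotation label, the
#' per-label IQR, the mean IQR across labels with its 95% CI, and the
#' pooled Spearman trend versus the label with effect-size stratum. The
#' epsilon guard of the percentage difference is
#' `1e-6 * median(|R0 value|)` per feature, floored at machine epsilon.
#'
#' No multiplicity correction is applied by default (`p_adjust = "none"`);
#' Benjamini-Hochberg is available via `p_adjust = "BH"`.
#'
#' @param feature_table long `data.table` with columns patient_id, rotation
#'   (label degrees), channel, category, feature, value, is_wd (from
#'   [extract_cohort_features()]).
#' @param magnitude passed to [spearman_vs_rotation()].
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return `data.table` of stability records, one row per feature, with the
#'   per-label IQRs in wide columns `iqr_R<label>`.
#' @export
feature_stability <- function(feature_table, magnitude = TRUE,
                              p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  ft <- data.table::as.data.table(feature_table)
  stopifnot(all(c("patient_id", "rotation", "channel", "category",
                  "feature", "value") %in% names(ft)))
  base <- ft[ft$rotation == 0,
             c("patient_id", "channel", "category", "feature", "value")]
  data.table::setnames(base, "value", "value0")
  rot <- ft[ft$rotation != 0]
  m <- merge(rot, base, by = c("patient_id", "channel", "category", "feature"))
  # scale-aware epsilon per feature
  value0 <- pd <- eps <- value <- NULL  # NSE bindings
  m[, eps := pmax(1e-6 * median(abs(value0)), .Machine$double.eps),
    by = c("channel", "category", "feature")]
  m[, pd := percent_difference(value, value0, eps)]
  labs <- sort(unique(m$rotation))
  recs <- m[, {
    by_lab <- split(pd, rotation)[as.character(labs)]
    names(by_lab) <- as.character(labs)
    ic <- iqr_with_ci(by_lab)
    sp <- tryCatch(spearman_vs_rotation(by_lab, magnitude = magnitude),
                   warning = function(w)
                     list(cc = 0, p = 1, stratum = "trivial",
                          n = sum(lengths(by_lab)),
                          significant_nontrivial = FALSE))
    out <- c(list(is_wd = is_wd[1], mean_iqr = ic$mean_iqr,
                  iqr_ci_lo = ic$ci[1], iqr_ci_hi = ic$ci[2],
                  spearman_cc = sp$cc, spearman_p = sp$p,
                  stratum = sp$stratum,
                  significant_nontrivial = sp$significant_nontrivial),
             stats::setNames(as.list(ic$per_label_iqr),
                             paste0("iqr_R", labs)))
    out
  }, by = c("channel", "category", "feature")]
  if (p_adjust == "BH") {
    padj <- stats::p.adjust(recs$spearman_p, "BH")
    recs$spearman_p_adj <- padj
    recs$significant_nontrivial <- padj < 0.05 & abs(recs$spearman_cc) >= 0.1
  }
  recs[]
}

#' Aggregate stability records by imaging filter and texture category
#'
#' @param records output of [feature_stability()].
#' @return list of `data.table`s: `iqr` (mean of per-feature mean IQR per
#'   channel x category cell), `pct_significant` (percentage of features per
#'   cell with a significant non-trivial trend), and `per_channel` totals
#'   (flagged count and percentage out of the features per channel). Cells
#'   with no features are absent, not zero.
#' @export
aggregate_subgroups <- function(records) {
  r <- data.table::as.data.table(records)
  mean_iqr <- significant_nontrivial <- NULL
  iqr_tab <- r[, list(mean_iqr = mean(mean_iqr), n_features = .N),
               by = c("channel", "category")]
  pct_tab <- r[, list(pct_significant = 100 * mean(significant_nontrivial),
                      n_flagged = sum(significant_nontrivial),
                      n_features = .N),
               by = c("channel", "category")]
  per_channel <- r[, list(mean_iqr = mean(mean_iqr),
                          n_flagged = sum(significant_nontrivial),
                          n_features = .N,
                          pct_significant = 100 * mean(significant_nontrivial)),
                   by = "channel"]
  list(iqr = iqr_tab[], pct_significant = pct_tab[],
       per_channel = per_channel[])
}
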