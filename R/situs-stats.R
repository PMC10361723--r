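# Organ situs scoring and the exact / classical tests used on count and
# measurement tables.

#' Score organ situs from heart and gut laterality
#'
#' *Situs solitus* is normal patterning (left heart and gut), *situs
#' inversus* is the full mirror image (both right); every other combination,
#' including a centered heart, is heterotaxia. Records with a missing organ
#' call are returned as `NA` (unscorable).
#'
#' @param heart Character vector, `"left"`, `"center"` or `"right"`.
#' @param gut Character vector, `"left"` or `"right"`.
#' @return Character vector: `"solitus"`, `"inversus"` or `"heterotaxia"`.
#' @export
call_situs <- function(heart, gut) {
  ok_h <- heart %in% c("left", "center", "right")
  ok_g <- gut %in% c("left", "right")
  if (any(!ok_h & !is.na(heart))) stop("invalid heart level")
  if (any(!ok_g & !is.na(gut))) stop("invalid gut level")
  out <- ifelse(heart == "left" & gut == "left", "solitus",
                ifelse(heart == "right" & gut == "right", "inversus",
                       "heterotaxia"))
  out[is.na(heart) | is.na(gut)] <- NA_character_
  out
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The two-sided p-value sums the hypergeometric probabilities of all tables
#' (with the observed margins) no more probable than the observed one, the
#' convention of `fisher.test`. Degenerate tables (a zero margin) return
#' p = 1 by convention.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List with `p_value` and `odds_ratio` (conditional MLE).
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(list(p_value = 1, odds_ratio = NA_real_))
  }
  ft <- stats::fisher.test(table)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Welch's t-test from raw samples or summary statistics
#'
#' Either supply `x` and `y` (raw samples) or the group summaries
#' (`mean1`, `sem1`, `n1`, `mean2`, `sem2`, `n2`), as figures often report
#' mean +/- SEM. Uses the Welch statistic with Satterthwaite degrees of
#' freedom.
#'
#' @param x,y Raw samples (optional).
#' @param mean1,sem1,n1,mean2,sem2,n2 Group summaries (used when `x` is
#'   missing).
#' @return List with `t`, `df` and `p_value` (two-sided).
#' @export
welch_t <- function(x = NULL, y = NULL, mean1, sem1, n1, mean2, sem2, n2) {
  if (!is.null(x)) {
    tt <- stats::t.test(x, y, var.equal = FALSE)
    return(list(t = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value))
  }
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  if (sem1 <= 0 || sem2 <= 0) stop("SEM must be positive")
  v1 <- sem1^2
  v2 <- sem2^2
  t_stat <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t_stat, df = df, p_value = 2 * pt(-abs(t_stat), df))
}

#' Paired t-test on per-embryo left/right counts
#'
#' A paired t-test on per-embryo differences, as used to compare transcript
#' counts on the left and right sides of the organizer. A zero-variance
#' difference vector (all differences identical and non-zero) would give an
#' infinite statistic; it is reported as `p_value = 0` with a warning.
#'
#' @param left,right Equal-length paired numeric vectors (n >= 2).
#' @return List with `t`, `df` and `p_value`.
#' @export
paired_t <- function(left, right) {
  if (length(left) != length(right)) stop("left and right must be paired")
  if (length(left) < 2) stop("need at least 2 pairs")
  d <- left - right
  if (sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = length(d) - 1, p_value = 1))
    warning("zero-variance paired differences; reporting p = 0")
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1, p_value = 0))
  }
  tt <- stats::t.test(left, right, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test with tie correction (exact for small untied
#' samples).
#'
#' @param x,y Numeric samples.
#' @return List with `U` and `p_value`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}
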