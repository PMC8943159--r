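#' Z-average cognitive composite with baseline reference
#'
#' Each subtest is z-transformed using the mean and SD of the baseline
#' (time 0) visits; the composite is the mean of the available z-scores,
#' defined only when at most `max_missing` subtests are missing. Subtests
#' where higher raw scores mean worse performance (e.g. timed trails) are
#' sign-flipped after z-transformation so the composite increases with
#' better performance.
#'
#' @param data Data frame with `subject`, `time` and the subtest columns.
#' @param subtest_cols Character vector of subtest column names.
#' @param flip_cols Subset of `subtest_cols` to sign-flip.
#' @param max_missing Maximum missing subtests tolerated per row.
#' @param baseline Optional precomputed reference: list with named numeric
#'   vectors `mean` and `sd`; default computes both from `time == 0` rows.
#' @return `data` with added z-score columns (`<subtest>_z`) and
#'   `composite`; the baseline reference is attached as attribute
#'   `"baseline"`.
#' @export
compute_composite <- function(data, subtest_cols, flip_cols = character(),
                              max_missing = 1, baseline = NULL) {
  stopifnot(all(subtest_cols %in% names(data)))
  if (is.null(baseline)) {
    base_rows <- data[data$time == 0, , drop = FALSE]
    if (!nrow(base_rows)) stop("reference error: no baseline (time 0) rows")
    baseline <- list(
      mean = vapply(subtest_cols, function(cn) mean(base_rows[[cn]], na.rm = TRUE), numeric(1)),
      sd = vapply(subtest_cols, function(cn) stats::sd(base_rows[[cn]], na.rm = TRUE), numeric(1)))
  }
  if (any(!is.finite(baseline$sd)) || any(baseline$sd == 0))
    stop("reference error: baseline SD is zero or undefined for subtest(s): ",
         paste(subtest_cols[!is.finite(baseline$sd) | baseline$sd == 0], collapse = ", "))
  zmat <- sapply(subtest_cols, function(cn) {
    z <- (data[[cn]] - baseline$mean[[cn]]) / baseline$sd[[cn]]
    if (cn %in% flip_cols) -z else z
  })
  zmat <- matrix(zmat, nrow = nrow(data),
                 dimnames = list(NULL, subtest_cols))
  for (cn in subtest_cols) data[[paste0(cn, "_z")]] <- zmat[, cn]
  n_miss <- rowSums(is.na(zmat))
  comp <- rowMeans(zmat, na.rm = TRUE)
  comp[n_miss > max_missing] <- NA_real_
  data$composite <- comp
  attr(data, "baseline") <- baseline
  data
}

#' PACC5 cognitive composite
#'
#' The five-subtest preclinical cognitive composite: digit-symbol
#' substitution, free+total selective reminding recall, delayed logical
#' memory, MMSE, and category fluency, each z-transformed against baseline
#' means/SDs and averaged. At most one missing subtest is allowed; missing
#' subtests are excluded from the average.
#'
#' @param data Data frame with `subject`, `time` and the five subtest
#'   columns.
#' @param subtest_cols Names of the five subtest columns.
#' @param baseline Optional precomputed baseline reference (see
#'   [compute_composite()]).
#' @return `data` with z-score columns and a `composite` column.
#' @export
compute_pacc5 <- function(data,
                          subtest_cols = c("dsst", "fcsrt", "lm_delayed",
                                           "mmse", "cat_fluency"),
                          baseline = NULL) {
  if (length(subtest_cols) != 5) stop("PACC5 requires exactly 5 subtests")
  compute_composite(data, subtest_cols, max_missing = 1, baseline = baseline)
}

#' Paired comparison of condition amplitudes
#'
#' Two-tailed paired t-test on run-averaged HRF amplitudes (novelty vs
#' repetition), one pair per subject.
#'
#' @param amp_nov,amp_rep Paired numeric vectors.
#' @return List: `t`, `df`, `p`, `mean_difference`.
#' @export
paired_amplitude_test <- function(amp_nov, amp_rep) {
  if (length(amp_nov) != length(amp_rep)) stop("paired vectors differ in length")
  if (length(amp_nov) < 3) stop("need n >= 3 pairs")
  d <- amp_nov - amp_rep
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = length(d) - 1L, p = 1,
                                 mean_difference = 0))
    stop("degenerate error: zero-variance non-zero differences")
  }
  tt <- stats::t.test(amp_nov, amp_rep, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_difference = unname(tt$estimate))
}

#' Test-retest reliability via the intraclass correlation coefficient
#'
#' Two-way mixed-effects, consistency, single-measure ICC from the
#' two-way ANOVA decomposition `score ~ subject + visit`:
#' `ICC = (MS_subject - MS_error) / (MS_subject + (k - 1) MS_error)`, with
#' `k` the (mean) number of visits per subject. Subjects with fewer than two
#' visits are excluded (count reported).
#'
#' @param data Data frame with `subject`, `visit`, `score`.
#' @return List: `icc`, `n_subjects`, `k`, `n_excluded`.
#' @export
icc_reliability <- function(data) {
  stopifnot(all(c("subject", "visit", "score") %in% names(data)))
  cnt <- table(data$subject)
  keep <- names(cnt)[cnt >= 2]
  n_excluded <- sum(cnt < 2)
  data <- data[data$subject %in% keep, , drop = FALSE]
  if (!nrow(data)) stop("no subjects with >= 2 visits")
  fit <- stats::aov(score ~ factor(subject) + factor(visit), data = data)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  ms_subj <- ms[1]; ms_err <- ms[3]
  k <- mean(table(data$subject))
  icc <- (ms_subj - ms_err) / (ms_subj + (k - 1) * ms_err)
  list(icc = icc, n_subjects = length(keep), k = k, n_excluded = n_excluded)
}
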