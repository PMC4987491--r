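#' @title Interrater reliability statistics and training gates
#'
#' @description
#' Two reviewers co-score a set of websites during training; the sample is
#' divided between them only once agreement clears a benchmark. Nominal
#' (yes/no) disclosure items are pooled into a single contingency table and
#' assessed with Cohen's kappa against a gate of .80 (HC/HIT-8.1). Ordinal
#' 1-4 usability ratings are assessed with a two-way intraclass correlation
#' (absolute agreement, single rater) against a gate of .61 (HC/HIT-8.2).
#' Agreement strength is also reported on Altman's qualitative benchmark
#' scale (Poor to Very good).
#'
#' @name irr
NULL

new_irr_result <- function(kind, value, threshold, extra = list()) {
  res <- c(list(
    statistic_kind = kind,
    value = value,
    altman_category = altman_category(value),
    threshold = threshold,
    passed = !is.na(value) && value >= threshold
  ), extra)
  class(res) <- "qhws_irr_result"
  res
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement for nominal ratings:
#' \deqn{\kappa = (p_o - p_e) / (1 - p_e)}
#' where \eqn{p_o} is the observed fraction of identical ratings and
#' \eqn{p_e} the chance agreement from the raters' marginal distributions.
#' Item-level responses from all co-rated websites are pooled into one
#' contingency table per instrument.
#'
#' @param ratings_a,ratings_b equal-length vectors of categorical ratings
#'   (factors, characters or integers). Pairs with NA in either rater are
#'   dropped (count reported in the result).
#' @param threshold pass benchmark for the gate (default .80, the HC/HIT-8.1
#'   training gate).
#' @return \code{qhws_irr_result} with \code{value}, observed agreement
#'   \code{p_o}, expected agreement \code{p_e}, dropped-pair count,
#'   Altman category and pass flag. When both raters are constant and
#'   identical (\eqn{p_e = 1}) kappa is undefined: \code{value} is NA with
#'   a warning of class \code{qhws_undefined_kappa}, and \code{p_o} is still
#'   reported.
#' @examples
#' a <- c(rep("yes", 50), rep("no", 50))
#' b <- c(rep("yes", 40), rep("no", 10), rep("no", 40), rep("yes", 10))
#' cohens_kappa(a, b)$value  # 0.6
#' @export
cohens_kappa <- function(ratings_a, ratings_b, threshold = 0.80) {
  if (length(ratings_a) != length(ratings_b))
    qhws_stop("qhws_bad_input", "rating vectors differ in length")
  keep <- !is.na(ratings_a) & !is.na(ratings_b)
  dropped <- sum(!keep)
  a <- as.character(ratings_a[keep])
  b <- as.character(ratings_b[keep])
  if (length(a) < 2L)
    qhws_stop("qhws_bad_input", "need at least 2 complete rating pairs")
  lev <- sort(unique(c(a, b)))
  tab <- table(factor(a, lev), factor(b, lev))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1 - .Machine$double.eps^0.5) {
    warning(warningCondition(
      "both raters constant in the same category; kappa undefined",
      class = "qhws_undefined_kappa"))
    kappa <- NA_real_
  } else {
    kappa <- (p_o - p_e) / (1 - p_e)
  }
  new_irr_result("kappa", kappa, threshold,
                 list(p_o = p_o, p_e = p_e, n_pairs = n, dropped = dropped,
                      table = tab))
}

#' Intraclass correlation for two raters
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC
#' (McGraw & Wong's ICC(A,1)), from the mean squares of the
#' subjects-by-raters ANOVA decomposition:
#' \deqn{ICC = \frac{MS_S - MS_E}{MS_S + (k-1) MS_E + \frac{k}{n}(MS_R - MS_E)}}
#' with \eqn{n} subjects, \eqn{k} raters, \eqn{MS_S} between-subject,
#' \eqn{MS_R} between-rater and \eqn{MS_E} residual mean squares. Absolute
#' agreement is the relevant form when reviewers subsequently score
#' different sites alone: a constant shift between raters counts against
#' agreement.
#'
#' @param ratings_matrix numeric matrix or data.frame, subjects in rows and
#'   exactly 2 rater columns. Rows containing NA are dropped (count
#'   reported).
#' @param threshold pass benchmark (default .61, the HC/HIT-8.2 training
#'   gate).
#' @param form \code{"absolute"} (default) or \code{"consistency"}
#'   (ICC(C,1), which ignores rater mean differences); the form used is
#'   recorded in the result.
#' @return \code{qhws_irr_result} with \code{value}, the three mean
#'   squares as \code{variance_components}, dropped-row count, Altman
#'   category and pass flag. Zero between-subject variance is degenerate:
#'   NA value with a warning of class \code{qhws_degenerate_variance}.
#' @export
icc <- function(ratings_matrix, threshold = 0.61,
                form = c("absolute", "consistency")) {
  form <- match.arg(form)
  m <- as.matrix(ratings_matrix)
  if (ncol(m) != 2L)
    qhws_stop("qhws_bad_input", "ratings_matrix must have exactly 2 rater columns")
  keep <- stats::complete.cases(m)
  dropped <- sum(!keep)
  m <- m[keep, , drop = FALSE]
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L)
    qhws_stop("qhws_bad_input", "need at least 2 complete subjects")

  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  ms_s <- ss_rows / (n - 1)
  ms_r <- ss_cols / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))

  if (ms_s <= .Machine$double.eps^0.5 * max(1, grand^2)) {
    warning(warningCondition(
      "no between-subject variance; ICC degenerate",
      class = "qhws_degenerate_variance"))
    value <- NA_real_
  } else if (form == "absolute") {
    value <- (ms_s - ms_e) /
      (ms_s + (k - 1) * ms_e + k * (ms_r - ms_e) / n)
  } else {
    value <- (ms_s - ms_e) / (ms_s + (k - 1) * ms_e)
  }
  new_irr_result("icc", value, threshold,
                 list(variance_components = c(between_subject = ms_s,
                                              between_rater = ms_r,
                                              residual = ms_e),
                      form = form, n_subjects = n, dropped = dropped))
}

#' Altman's qualitative benchmark for agreement statistics
#'
#' Maps a kappa (or ICC) value to Altman's strength-of-agreement bands.
#' Values are rounded to 2 decimals first so the published bins are
#' exhaustive: up to .20 Poor, .21-.40 Fair, .41-.60 Moderate, .61-.80
#' Good, .81-1.00 Very good.
#'
#' @param value agreement statistic in [-1, 1].
#' @return one of \code{"Poor"}, \code{"Fair"}, \code{"Moderate"},
#'   \code{"Good"}, \code{"Very good"} (NA input gives NA).
#' @examples
#' altman_category(0.83)  # "Very good"
#' altman_category(0.50)  # "Moderate"
#' @export
altman_category <- function(value) {
  if (is.na(value)) return(NA_character_)
  if (value < -1 - 1e-12 || value > 1 + 1e-12)
    qhws_stop("qhws_bad_input", "agreement statistic must lie in [-1, 1]")
  r <- round_half_up(value, 2)
  if (r <= 0.20) "Poor"
  else if (r <= 0.40) "Fair"
  else if (r <= 0.60) "Moderate"
  else if (r <= 0.80) "Good"
  else "Very good"
}

#' Training gate for an objective's interrater reliability
#'
#' HC/HIT-8.1 (nominal disclosure items) gates on Cohen's kappa at .80;
#' HC/HIT-8.2 (ordinal usability ratings) gates on the ICC at .61. The
#' statistic kind must match the objective.
#'
#' @param objective \code{"HC/HIT-8.1"} or \code{"HC/HIT-8.2"}.
#' @param result a \code{qhws_irr_result}.
#' @return logical: does the result clear the objective's benchmark?
#' @export
irr_gate <- function(objective = c("HC/HIT-8.1", "HC/HIT-8.2"), result) {
  objective <- match.arg(objective)
  expected <- if (objective == "HC/HIT-8.1") "kappa" else "icc"
  if (!inherits(result, "qhws_irr_result"))
    qhws_stop("qhws_bad_input", "result must be a qhws_irr_result")
  if (result$statistic_kind != expected)
    qhws_stop("qhws_config_error",
              "objective %s gates on %s, got %s",
              objective, expected, result$statistic_kind)
  threshold <- if (objective == "HC/HIT-8.1") 0.80 else 0.61
  !is.na(result$value) && result$value >= threshold
}

#' @export
print.qhws_irr_result <- function(x, ...) {
  cat(sprintf("<qhws_irr_result: %s = %s (%s)>\n",
              x$statistic_kind,
              ifelse(is.na(x$value), "NA", sprintf("%.3f", x$value)),
              ifelse(is.na(x$altman_category), "undefined", x$altman_category)))
  if (x$statistic_kind == "kappa")
    cat(sprintf("  observed agreement %.3f, chance agreement %.3f, %d pairs (%d dropped)\n",
                x$p_o, x$p_e, x$n_pairs, x$dropped))
  else
    cat(sprintf("  mean squares: subject %.4f, rater %.4f, residual %.4f (%s form)\n",
                x$variance_components[["between_subject"]],
                x$variance_components[["between_rater"]],
                x$variance_components[["residual"]], x$form))
  cat(sprintf("  benchmark %.2f: %s\n", x$threshold,
              if (isTRUE(x$passed)) "PASS" else "FAIL"))
  invisible(x)
}
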