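#' Published Healthy People 2020 baseline compliance rows
#'
#' The element/criterion compliance table (HC/HIT-8.1) and per-principle
#' compliance table (HC/HIT-8.2) from the 2014 baseline review of the 100
#' top-ranked health websites, as printed: count, denominator, percent,
#' Wald SE and 95% CI bounds. These printed rows are inputs for regression
#' checks of the estimation machinery — every row's percent/SE/CI can be
#' recomputed from its (count, n).
#'
#' The principle-5 row is recorded with its effective denominator of 99:
#' its printed percent (39.4) and SE (4.91) are consistent only with one
#' site being unscorable on that principle and dropped from the
#' denominator.
#'
#' @return data.frame with columns \code{table} (reliability/usability),
#'   \code{kind}, \code{id}, \code{n}, \code{count}, \code{percent},
#'   \code{se}, \code{ci_low}, \code{ci_high}.
#' @export
published_baseline_rows <- function() {
  path <- system.file("extdata", "hp2020-baseline-tables.csv",
                      package = "qhws", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$n <- as.integer(df$n)
  df$count <- as.integer(df$count)
  df
}
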