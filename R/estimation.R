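#' @title Compliance estimation and target setting
#'
#' @description
#' Each compliance figure is a binomial proportion: of the \eqn{n} sites
#' for which an item could be assessed, \eqn{x} complied. Reported with the
#' normal-approximation (Wald) machinery used for Healthy People tracking:
#' \deqn{\hat p = x/n, \quad SE = 100\sqrt{\hat p (1-\hat p)/n}, \quad
#'   CI = 100\hat p \pm z\,SE}
#' with \eqn{z = 1.96} for 95% confidence. All quantities are kept on the
#' percentage scale. Intermediates are carried at full precision; rounding
#' (percent and CI bounds to 1 decimal, SE to 2, halves away from zero)
#' happens only at presentation, and CI bounds are clipped to [0, 100].
#'
#' Targets for the next decade are set at minimal statistical significance:
#' the smallest increase over the baseline that would be statistically
#' detectable between two independent samples of the same size,
#' \eqn{target = \hat p + z\sqrt{2}\,SE}.
#'
#' @name estimation
NULL

#' Binomial proportion with Wald standard error and confidence interval
#'
#' @param count number of compliant sites (0..n).
#' @param n number of sites assessed (denominator; sites where the item was
#'   not applicable are excluded upstream).
#' @param z critical value (default 1.96 for a 95% interval).
#' @return object of class \code{qhws_proportion}: list with \code{count},
#'   \code{n}, \code{percent}, \code{se}, \code{ci_low}, \code{ci_high}
#'   (all unrounded, percentage scale, CI clipped to [0, 100]) and \code{z}.
#'   Use [presented()] for table-ready rounded values.
#' @examples
#' presented(proportion_estimate(37, 100))  # 37.0, SE 4.83, CI [27.5, 46.5]
#' presented(proportion_estimate(28, 60))   # 46.7, SE 6.44, CI [34.0, 59.3]
#' @export
proportion_estimate <- function(count, n, z = 1.96) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != floor(n))
    qhws_stop("qhws_domain_error", "n must be a positive integer, got %s", n)
  if (!is.numeric(count) || length(count) != 1L || is.na(count) ||
      count < 0 || count > n || count != floor(count))
    qhws_stop("qhws_domain_error",
              "count must be an integer in [0, n]; got count=%s, n=%s", count, n)
  p <- count / n
  percent <- 100 * p
  se <- 100 * sqrt(p * (1 - p) / n)
  structure(list(
    count = as.integer(count), n = as.integer(n),
    percent = percent, se = se,
    ci_low = max(0, percent - z * se),
    ci_high = min(100, percent + z * se),
    z = z
  ), class = "qhws_proportion")
}

#' Presentation rounding for a proportion estimate
#'
#' Rounds to the precision used in published compliance tables: percent and
#' CI bounds to 1 decimal place, SE to 2, halves away from zero; CI bounds
#' clipped to [0, 100] after rounding.
#'
#' @param x a \code{qhws_proportion}.
#' @return named numeric vector: \code{percent}, \code{se}, \code{ci_low},
#'   \code{ci_high}.
#' @export
presented <- function(x) {
  stopifnot(inherits(x, "qhws_proportion"))
  c(percent = round_half_up(x$percent, 1),
    se = round_half_up(x$se, 2),
    ci_low = max(0, round_half_up(x$ci_low, 1)),
    ci_high = min(100, round_half_up(x$ci_high, 1)))
}

#' @export
print.qhws_proportion <- function(x, ...) {
  p <- presented(x)
  cat(sprintf("%d/%d = %.1f%% (SE %.2f, %d%% CI %.1f-%.1f)\n",
              x$count, x$n, p[["percent"]], p[["se"]],
              round(100 * (2 * stats::pnorm(x$z) - 1)),
              p[["ci_low"]], p[["ci_high"]]))
  invisible(x)
}

#' Compliance table across criteria, elements and principles
#'
#' One row per reliability criterion (denominator: all scored sites), per
#' disclosure element (denominator: sites where the element was applicable,
#' i.e. non-NA — for example, differentiating advertising is only assessable
#' on sites that carry advertising) and per usability principle
#' (denominator: sites where the principle was scorable). Rows follow
#' instrument order.
#'
#' @param scores a \code{qhws_scores} object from [score_dataset()].
#' @param instrument the \code{qhws_instrument} the data were scored with.
#' @param z critical value for the Wald intervals (default 1.96).
#' @return data.frame with columns \code{kind} (criterion/element/principle),
#'   \code{id}, \code{label}, \code{n}, \code{count}, \code{percent},
#'   \code{se}, \code{ci_low}, \code{ci_high} (unrounded) and the rounded
#'   presentation columns \code{percent_1dp}, \code{se_2dp},
#'   \code{ci_low_1dp}, \code{ci_high_1dp}. A zero denominator yields an
#'   all-NA estimate row with a warning.
#' @export
compliance_table <- function(scores, instrument = load_instrument(), z = 1.96) {
  stopifnot(inherits(scores, "qhws_scores"))
  sc <- scores$scorecards
  er <- scores$element_results
  ps <- scores$principle_scores

  rows <- list()
  add_row <- function(kind, id, label, count, n) {
    if (n == 0L) {
      warning(sprintf("%s '%s': no assessable sites; estimate undefined",
                      kind, id))
      rows[[length(rows) + 1L]] <<- data.frame(
        kind = kind, id = id, label = label, n = 0L, count = NA_integer_,
        percent = NA_real_, se = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, percent_1dp = NA_real_, se_2dp = NA_real_,
        ci_low_1dp = NA_real_, ci_high_1dp = NA_real_,
        stringsAsFactors = FALSE)
      return(invisible())
    }
    est <- proportion_estimate(count, n, z)
    pres <- presented(est)
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, id = id, label = label, n = est$n, count = est$count,
      percent = est$percent, se = est$se, ci_low = est$ci_low,
      ci_high = est$ci_high,
      percent_1dp = pres[["percent"]], se_2dp = pres[["se"]],
      ci_low_1dp = pres[["ci_low"]], ci_high_1dp = pres[["ci_high"]],
      stringsAsFactors = FALSE)
  }

  for (cr in instrument$criteria) {
    col <- paste0("crit_", cr$criterion_id)
    add_row("criterion", cr$criterion_id, cr$name,
            sum(sc[[col]]), nrow(sc))
    for (el in cr$elements) {
      res <- er$result[er$element_id == el$element_id]
      ok <- !is.na(res)
      add_row("element", el$element_id, el$text,
              sum(res[ok] == "yes"), sum(ok))
    }
  }
  for (p in instrument$principles) {
    rows_p <- ps[ps$principle_id == p$principle_id, , drop = FALSE]
    ok <- !is.na(rows_p$score)
    add_row("principle", as.character(p$principle_id),
            sprintf("%d. %s", p$principle_id, p$name),
            sum(rows_p$met[ok]), sum(ok))
  }
  do.call(rbind, rows)
}

#' Distribution of criteria or principles met across sites
#'
#' Histogram of how many reliability criteria (0-6) or usability principles
#' (0-19) each site met; the benchmark share is the tail sum at the
#' benchmark minimum.
#'
#' @param scorecards the \code{scorecards} data.frame from [score_dataset()]
#'   (or a \code{qhws_scores} object).
#' @param which \code{"criteria"} or \code{"principles"}.
#' @param max_count top of the histogram range; defaults to the number of
#'   \code{crit_} columns for criteria and 19 for principles.
#' @return data.frame with columns \code{k} (0..max) and \code{count};
#'   counts sum to the number of sites.
#' @export
met_count_distribution <- function(scorecards,
                                   which = c("criteria", "principles"),
                                   max_count = NULL) {
  which <- match.arg(which)
  if (inherits(scorecards, "qhws_scores")) scorecards <- scorecards$scorecards
  vals <- if (which == "criteria") scorecards$criteria_met_count
          else scorecards$principles_met_count
  if (is.null(max_count)) {
    max_count <- if (which == "criteria")
      sum(startsWith(names(scorecards), "crit_")) else 19L
  }
  k <- 0:max_count
  data.frame(k = k, count = vapply(k, function(i) sum(vals == i), integer(1)))
}

#' Set a Healthy People style improvement target
#'
#' The target is the baseline plus the minimal statistically significant
#' improvement: the smallest difference detectable at the two-sided 95%
#' level between two independent samples of the baseline's size,
#' \eqn{baseline + z\sqrt{2}\,SE}, reported to 1 decimal place.
#'
#' @param baseline a \code{qhws_proportion} (e.g. from
#'   [proportion_estimate()]), or a compliant count when \code{n} is given.
#' @param n denominator, when \code{baseline} is a count.
#' @param z critical value (default 1.96).
#' @param override optional externally mandated target percentage, recorded
#'   alongside (never replacing) the formula value.
#' @return object of class \code{qhws_target}: list with
#'   \code{baseline_percent}, \code{n}, \code{se}, \code{target_percent}
#'   (rounded to 1 dp), \code{target_override}, and
#'   \code{method = "minimal-statistical-significance"}.
#' @examples
#' set_target(42, 100)$target_percent  # 55.7
#' @export
set_target <- function(baseline, n = NULL, z = 1.96, override = NULL) {
  if (!inherits(baseline, "qhws_proportion")) {
    if (is.null(n))
      qhws_stop("qhws_bad_input", "supply a qhws_proportion or count and n")
    baseline <- proportion_estimate(baseline, n, z)
  }
  if (baseline$count == 0L || baseline$count == baseline$n)
    qhws_stop("qhws_domain_error",
              "degenerate baseline (0%% or 100%%): no sampling error to scale a target")
  target <- baseline$percent + z * sqrt(2) * baseline$se
  structure(list(
    baseline_percent = baseline$percent,
    n = baseline$n,
    se = baseline$se,
    target_percent = round_half_up(min(target, 100), 1),
    target_override = override,
    z = z,
    method = "minimal-statistical-significance"
  ), class = "qhws_target")
}

#' @export
print.qhws_target <- function(x, ...) {
  cat(sprintf("baseline %.1f%% (n=%d, SE %.2f) -> 2020 target %.1f%% [%s]\n",
              x$baseline_percent, x$n, x$se, x$target_percent, x$method))
  if (!is.null(x$target_override))
    cat(sprintf("  externally mandated override on record: %.1f%%\n",
                x$target_override))
  invisible(x)
}
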