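#' @title Rubric scoring: from raw responses to benchmark determinations
#'
#' @description
#' Scoring proceeds in three layers. Disclosure elements are resolved to
#' yes/no/NA (page-scoped elements aggregate per-page observations under a
#' configurable pass rule). A reliability criterion is met iff every
#' required element that is applicable (non-NA) scores yes; optional
#' elements never decide a criterion, and NA (conditional, not applicable)
#' elements are excluded from the determination. A usability principle's
#' score is the arithmetic mean of its non-NA 1-4 measure ratings, and the
#' principle is met when that mean reaches the threshold (canonically 3.5,
#' inclusive; compared in integer arithmetic so a boundary mean is never
#' lost to floating point). Site-level benchmarks: HC/HIT-8.1 is met at >= 3
#' of 6 criteria, HC/HIT-8.2 at >= 10 of 19 principles.
#'
#' @name scoring
NULL

ELEMENT_VALUES <- c("yes", "no")

#' Resolve a single disclosure element to yes/no/NA
#'
#' Non-page-scoped elements pass their recorded value through unchanged
#' (including NA, which marks a conditional element that does not apply to
#' the site). Page-scoped elements are assessed on several sampled pages of
#' health content; \code{page_policy} turns the per-page booleans into a
#' single verdict.
#'
#' @param value recorded value: \code{"yes"}, \code{"no"} or \code{NA}.
#' @param element a single element definition from the instrument (a list
#'   with at least \code{element_id} and \code{page_scoped}).
#' @param page_observations logical vector of per-page outcomes for
#'   page-scoped elements, or \code{NULL}.
#' @param page_policy pass rule for page-scoped elements: \code{"all"}
#'   (default; every sampled page must display the item), \code{"any"}, or
#'   \code{"majority"} (strictly more than half).
#' @return \code{"yes"}, \code{"no"} or \code{NA_character_}.
#' @examples
#' el <- list(element_id = "date_created", page_scoped = TRUE)
#' score_element(NA, el, page_observations = c(TRUE, TRUE, TRUE))   # "yes"
#' score_element(NA, el, page_observations = c(TRUE, FALSE, TRUE))  # "no"
#' @export
score_element <- function(value, element, page_observations = NULL,
                          page_policy = c("all", "any", "majority")) {
  page_policy <- match.arg(page_policy)
  if (!is.na(value) && !value %in% ELEMENT_VALUES)
    qhws_stop("qhws_bad_value",
              "element '%s': value must be yes/no/NA, got '%s'",
              element$element_id, value)
  if (!isTRUE(element$page_scoped)) return(as.character(value))
  if (length(page_observations)) {
    ok <- switch(page_policy,
      all = all(page_observations),
      any = any(page_observations),
      majority = sum(page_observations) * 2L > length(page_observations))
    return(if (ok) "yes" else "no")
  }
  if (is.na(value))
    qhws_stop("qhws_missing_data",
              "page-scoped element '%s' has neither a value nor page observations",
              element$element_id)
  as.character(value)
}

#' Determine whether a reliability criterion is met
#'
#' True iff every required element of the criterion that is applicable
#' (non-NA) scores yes. Optional elements are ignored entirely; a required
#' element recorded NA (conditional item that does not apply) is excluded
#' from the determination rather than counted against the site.
#'
#' @param criterion a criterion definition from the instrument.
#' @param element_results named character vector (or list) mapping
#'   \code{element_id} to \code{"yes"}/\code{"no"}/\code{NA}.
#' @return logical scalar.
#' @export
score_criterion <- function(criterion, element_results) {
  element_results <- unlist(element_results)
  for (el in criterion$elements) {
    if (!el$required) next
    if (!el$element_id %in% names(element_results))
      qhws_stop("qhws_missing_data",
                "criterion '%s': no result for required element '%s'",
                criterion$criterion_id, el$element_id)
    v <- element_results[[el$element_id]]
    if (is.na(v)) next        # conditional / not applicable: excluded
    if (v != "yes") return(FALSE)
  }
  TRUE
}

#' Average rating for a usability principle
#'
#' @param ratings integer ratings in 1..4, possibly with NA (unassessed
#'   measures).
#' @return arithmetic mean of the non-NA ratings, or \code{NA_real_} when
#'   all are NA.
#' @examples
#' principle_score(c(3, 4))       # 3.5
#' principle_score(c(2, NA, 4))   # 3
#' @export
principle_score <- function(ratings) {
  ratings <- as.numeric(ratings)
  ok <- !is.na(ratings)
  if (any(ratings[ok] < 1 | ratings[ok] > 4 | ratings[ok] != floor(ratings[ok])))
    qhws_stop("qhws_bad_value", "ratings must be integers in [1, 4]")
  if (!any(ok)) return(NA_real_)
  mean(ratings[ok])
}

#' Is a usability principle met?
#'
#' Met iff the principle's mean score is non-NA and at least the threshold
#' (inclusive: a mean of exactly 3.5 meets the canonical benchmark). An
#' unscorable (all-NA) principle counts as not met for the site's 10-of-19
#' benchmark; compliance estimation drops such sites from the principle's
#' denominator instead (see [compliance_table()]).
#'
#' When the raw ratings are supplied the comparison is done on integers
#' (\code{100 * sum} vs \code{round(100 * threshold) * m}), so boundary
#' means can never be misclassified by floating-point representation.
#'
#' @param score mean score from [principle_score()], or NA.
#' @param threshold met threshold (canonical 3.5).
#' @param ratings optional raw integer ratings; when given, \code{score} is
#'   ignored and the exact integer comparison is used.
#' @return logical scalar.
#' @export
principle_met <- function(score, threshold = 3.5, ratings = NULL) {
  if (!is.null(ratings)) {
    ratings <- ratings[!is.na(ratings)]
    if (!length(ratings)) return(FALSE)
    return(100L * sum(as.integer(ratings)) >=
             as.integer(round(100 * threshold)) * length(ratings))
  }
  !is.na(score) && score >= threshold
}

# internal: resolve all element results for one site/rater from long-form rows
resolve_site_elements <- function(rows, instrument, page_policy) {
  edef <- instrument_elements(instrument)
  out <- rep(NA_character_, nrow(edef))
  names(out) <- edef$element_id
  idx <- match(rows$item_id, edef$element_id)
  if (anyNA(idx))
    qhws_stop("qhws_unknown_item", "unknown element id(s): %s",
              paste(unique(rows$item_id[is.na(idx)]), collapse = ", "))
  for (k in seq_len(nrow(rows))) {
    i <- idx[k]
    el <- list(element_id = edef$element_id[i],
               page_scoped = edef$page_scoped[i])
    obs <- parse_page_obs(rows$page_obs[k])
    out[i] <- score_element(rows$value[k], el, obs, page_policy)
  }
  out
}

parse_page_obs <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x) || !nzchar(x)) return(NULL)
  bits <- strsplit(x, "/", fixed = TRUE)[[1]]
  if (!all(bits %in% c("0", "1")))
    qhws_stop("qhws_bad_value", "page_obs must be slash-separated 0/1, got '%s'", x)
  bits == "1"
}

#' Build a per-site scorecard
#'
#' Aggregates one site's element results and measure ratings into criterion
#' and principle outcomes and the two Healthy People benchmark booleans.
#'
#' @param element_results named character vector of yes/no/NA keyed by
#'   \code{element_id}, already resolved (see [score_element()]); must cover
#'   every required element.
#' @param ratings named integer vector (values 1..4 or NA) keyed by
#'   \code{measure_id}; measures absent from the vector count as NA.
#' @param instrument a \code{qhws_instrument}.
#' @param site_id site identifier carried into the result.
#' @return a one-row data.frame of class \code{qhws_scorecard}: site_id,
#'   one logical column per criterion (\code{crit_<id>}),
#'   \code{criteria_met_count}, \code{reliability_benchmark_met},
#'   \code{principles_met_count}, \code{usability_benchmark_met}, plus an
#'   attribute \code{principle_scores} (named numeric).
#' @export
build_scorecard <- function(element_results, ratings, instrument,
                            site_id = "site") {
  crit_met <- vapply(instrument$criteria, function(cr) {
    tryCatch(score_criterion(cr, element_results),
             qhws_missing_data = function(e)
               qhws_stop("qhws_missing_data", "site '%s': %s",
                         site_id, conditionMessage(e)))
  }, logical(1))
  names(crit_met) <- vapply(instrument$criteria, `[[`, character(1),
                            "criterion_id")

  bad <- ratings[!is.na(ratings) & (ratings < 1 | ratings > 4)]
  if (length(bad))
    qhws_stop("qhws_bad_value",
              "site '%s': rating value(s) outside [1, 4]: %s",
              site_id, paste(unique(bad), collapse = ", "))

  pscores <- numeric(0)
  pmet <- logical(0)
  for (p in instrument$principles) {
    mids <- vapply(p$measures, `[[`, character(1), "measure_id")
    vals <- ratings[match(mids, names(ratings))]
    sc <- principle_score(vals)
    pscores[as.character(p$principle_id)] <- sc
    pmet[as.character(p$principle_id)] <-
      principle_met(sc, p$met_threshold, ratings = vals)
  }

  out <- data.frame(site_id = site_id, stringsAsFactors = FALSE)
  for (nm in names(crit_met)) out[[paste0("crit_", nm)]] <- crit_met[[nm]]
  out$criteria_met_count <- sum(crit_met)
  out$reliability_benchmark_met <-
    out$criteria_met_count >= instrument$reliability_benchmark_min
  out$principles_met_count <- sum(pmet)
  out$usability_benchmark_met <-
    out$principles_met_count >= instrument$usability_benchmark_min
  attr(out, "principle_scores") <- pscores
  attr(out, "principles_met") <- pmet
  class(out) <- c("qhws_scorecard", "data.frame")
  out
}

#' Score a full assessment dataset
#'
#' Applies the instrument to a long-form assessment table and returns
#' site-level scorecards together with the intermediate element results and
#' principle scores needed for compliance estimation.
#'
#' @param assessments data.frame in the long assessment dialect: columns
#'   \code{site_id}, \code{rater_id}, \code{item_id}, \code{item_kind}
#'   (\code{"element"} or \code{"measure"}), \code{value} (yes/no or 1-4;
#'   NA allowed) and optionally \code{page_obs} (slash-separated 0/1).
#' @param instrument a \code{qhws_instrument} (default canonical).
#' @param rater which rater's responses to score; default the first rater
#'   appearing in the data.
#' @param page_policy pass rule for page-scoped elements (see
#'   [score_element()]).
#' @return object of class \code{qhws_scores}: a list with
#'   \describe{
#'     \item{scorecards}{one row per site (see [build_scorecard()])}
#'     \item{element_results}{long data.frame site_id, criterion_id,
#'       element_id, result (yes/no/NA)}
#'     \item{principle_scores}{long data.frame site_id, principle_id, score,
#'       met}
#'   }
#' @export
score_dataset <- function(assessments, instrument = load_instrument(),
                          rater = NULL,
                          page_policy = c("all", "any", "majority")) {
  page_policy <- match.arg(page_policy)
  validate_assessments(assessments, instrument)
  if (is.null(rater)) rater <- assessments$rater_id[1]
  a <- assessments[assessments$rater_id == rater, , drop = FALSE]
  if (nrow(a) == 0L)
    qhws_stop("qhws_bad_input", "no rows for rater '%s'", rater)
  if (is.null(a$page_obs)) a$page_obs <- NA_character_

  edef <- instrument_elements(instrument)
  mdef <- instrument_measures(instrument)
  sites <- unique(a$site_id)

  cards <- vector("list", length(sites))
  eres_rows <- vector("list", length(sites))
  pres_rows <- vector("list", length(sites))
  for (i in seq_along(sites)) {
    s <- sites[i]
    rows <- a[a$site_id == s, , drop = FALSE]
    el_rows <- rows[rows$item_kind == "element", , drop = FALSE]
    me_rows <- rows[rows$item_kind == "measure", , drop = FALSE]
    eresults <- resolve_site_elements(el_rows, instrument, page_policy)
    bad <- setdiff(me_rows$item_id, mdef$measure_id)
    if (length(bad))
      qhws_stop("qhws_unknown_item", "unknown measure id(s): %s",
                paste(unique(bad), collapse = ", "))
    ratings <- suppressWarnings(as.integer(me_rows$value))
    if (any(!is.na(me_rows$value) & is.na(ratings)))
      qhws_stop("qhws_bad_value", "site '%s': non-integer rating value", s)
    names(ratings) <- me_rows$item_id
    card <- build_scorecard(eresults, ratings, instrument, site_id = s)
    eres_rows[[i]] <- data.frame(
      site_id = s, criterion_id = edef$criterion_id,
      element_id = edef$element_id, result = unname(eresults),
      stringsAsFactors = FALSE)
    ps <- attr(card, "principle_scores")
    pres_rows[[i]] <- data.frame(
      site_id = s, principle_id = as.integer(names(ps)),
      score = unname(ps), met = unname(attr(card, "principles_met")),
      stringsAsFactors = FALSE)
    cards[[i]] <- card
  }
  scorecards <- do.call(rbind, lapply(cards, function(x) {
    attributes(x)[c("principle_scores", "principles_met")] <- NULL
    as.data.frame(x)
  }))
  structure(list(
    scorecards = scorecards,
    element_results = do.call(rbind, eres_rows),
    principle_scores = do.call(rbind, pres_rows),
    rater = rater,
    instrument_version = instrument$version
  ), class = "qhws_scores")
}

validate_assessments <- function(assessments, instrument) {
  needed <- c("site_id", "rater_id", "item_id", "item_kind", "value")
  missing_cols <- setdiff(needed, names(assessments))
  if (length(missing_cols))
    qhws_stop("qhws_bad_input", "assessments missing column(s): %s",
              paste(missing_cols, collapse = ", "))
  if (!all(assessments$item_kind %in% c("element", "measure")))
    qhws_stop("qhws_bad_input", "item_kind must be 'element' or 'measure'")
  mv <- assessments$value[assessments$item_kind == "measure"]
  mv <- mv[!is.na(mv)]
  mvn <- suppressWarnings(as.numeric(mv))
  if (any(is.na(mvn)) || any(mvn < 1 | mvn > 4 | mvn != floor(mvn)))
    qhws_stop("qhws_bad_value",
              "measure ratings must be integers in [1, 4]; offending value(s): %s",
              paste(unique(mv[is.na(mvn) | mvn < 1 | mvn > 4 | mvn != floor(mvn)]),
                    collapse = ", "))
  ev <- assessments$value[assessments$item_kind == "element"]
  ev <- ev[!is.na(ev)]
  if (!all(ev %in% ELEMENT_VALUES))
    qhws_stop("qhws_bad_value", "element values must be yes/no/NA")
  invisible(assessments)
}

#' @export
print.qhws_scores <- function(x, ...) {
  sc <- x$scorecards
  cat(sprintf(
    paste0("<qhws_scores: %d sites, rater '%s'>\n",
           "  HC/HIT-8.1 reliability benchmark met: %d (%.1f%%)\n",
           "  HC/HIT-8.2 usability benchmark met:   %d (%.1f%%)\n"),
    nrow(sc), x$rater,
    sum(sc$reliability_benchmark_met),
    100 * mean(sc$reliability_benchmark_met),
    sum(sc$usability_benchmark_met),
    100 * mean(sc$usability_benchmark_met)))
  invisible(x)
}
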