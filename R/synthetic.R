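#' @title Synthetic assessment generator
#'
#' @description
#' The raw per-website review data behind the published compliance tables
#' were never deposited, so the pipeline is exercised on seeded synthetic
#' assessments with the statistical structure the analysis assumes:
#' \itemize{
#'   \item Binary disclosure outcomes follow a one-factor Gaussian threshold
#'     model. Each site draws a latent quality factor; an element complies
#'     when \eqn{\sqrt{\lambda} z_{site} + \sqrt{1-\lambda}\,\varepsilon}
#'     falls below the quantile of its configured marginal, so marginal
#'     compliance probabilities are preserved exactly while
#'     \code{latent_correlation} \eqn{\lambda} couples elements within a
#'     site (latent-scale correlation, one knob).
#'   \item Not-applicable items are imposed per element with probability
#'     \code{na_probability} (e.g. the advertising-differentiation item on
#'     ad-free sites).
#'   \item Ordinal 1-4 ratings come from a latent-normal cutpoint model: a
#'     site-by-principle quality score \eqn{N(\mu_p, \sigma_p)} plus
#'     measure-level noise, discretised at \code{rating_cutpoints}.
#'   \item A second rater reproduces each first-rater value with probability
#'     \code{rater_agreement}, otherwise resamples independently from the
#'     item's marginal distribution — so chance agreement matches the
#'     kappa chance model and the expected kappa equals
#'     \code{rater_agreement} analytically.
#' }
#'
#' @name synthetic
NULL

#' Default element compliance marginals
#'
#' Published element-level compliance rates for the 12 required disclosure
#' elements (percent compliant of assessable sites); the two optional
#' elements, whose rates were never published, default to 0.5.
#'
#' @return named numeric vector of compliance probabilities keyed by
#'   element_id.
#' @export
default_element_marginals <- function() {
  c(name = 0.93, street_address = 0.83, funding_sources = 0.44,
    purpose_mission = 0.79, uses_limitations = 0.82,
    commercial_association = 0.71,
    identify_advertising = 28 / 60, editorial_policy = 0.39,
    authorship = 0.38,
    privacy_policy = 0.96, personal_info_protection = 0.83,
    feedback_mechanism = 0.90, user_info_use = 0.5,
    date_created = 0.25, date_reviewed = 0.28, copyright_date = 0.5)
}

#' Generator parameters for synthetic assessments
#'
#' Defaults emulate the study conditions: 100 sites, element marginals at
#' the published compliance rates, the advertising item not applicable on
#' 40% of sites, sponsor mix 48/36/16 for-profit/nonprofit/government.
#' Where no value was ever published the defaults are documented
#' conventions: latent correlation 0.3, principle quality mean 3.4 / sd 0.5
#' on the rating scale, measure noise sd 0.5, cutpoints 1.5/2.5/3.5, rater
#' agreement 0.9.
#'
#' @param n_sites number of websites to simulate.
#' @param element_marginals named probability vector keyed by element_id.
#' @param na_probability named probability vector keyed by element_id
#'   (probability the element is not applicable); elements not named
#'   default to 0.
#' @param latent_correlation within-site coupling of element outcomes on
#'   the latent scale, in [0, 1).
#' @param principle_quality_mean scalar or length-19 vector: latent site
#'   quality mean per principle, on the rating scale.
#' @param principle_quality_sd scalar or length-19 vector: sd of the latent
#'   site-by-principle quality.
#' @param rating_noise_sd sd of measure-level noise around the principle
#'   quality score.
#' @param rating_cutpoints 3 strictly increasing thresholds discretising the
#'   latent score into ratings 1-4.
#' @param rater_agreement probability in (0, 1] that the second rater
#'   reproduces the first rater's value on an item.
#' @param sponsor_mix named probabilities over for-profit, nonprofit,
#'   government (must sum to 1).
#' @param seed RNG seed recorded with every generated dataset.
#' @param instrument instrument the ids refer to (canonical default).
#' @return validated list of class \code{qhws_generator_params}.
#' @export
generator_params <- function(n_sites = 100L,
                             element_marginals = default_element_marginals(),
                             na_probability = c(identify_advertising = 0.40),
                             latent_correlation = 0.3,
                             principle_quality_mean = 3.4,
                             principle_quality_sd = 0.5,
                             rating_noise_sd = 0.5,
                             rating_cutpoints = c(1.5, 2.5, 3.5),
                             rater_agreement = 0.9,
                             sponsor_mix = c("for-profit" = 0.48,
                                             "nonprofit" = 0.36,
                                             "government" = 0.16),
                             seed = 1L,
                             instrument = load_instrument()) {
  n_principles <- length(instrument$principles)
  pq_mean <- rep_len(principle_quality_mean, n_principles)
  pq_sd <- rep_len(principle_quality_sd, n_principles)
  params <- structure(list(
    n_sites = as.integer(n_sites),
    element_marginals = element_marginals,
    na_probability = na_probability,
    latent_correlation = latent_correlation,
    principle_quality_mean = pq_mean,
    principle_quality_sd = pq_sd,
    rating_noise_sd = rating_noise_sd,
    rating_cutpoints = rating_cutpoints,
    rater_agreement = rater_agreement,
    sponsor_mix = sponsor_mix,
    seed = as.integer(seed)
  ), class = "qhws_generator_params")
  validate_generator_params(params, instrument)
  params
}

validate_generator_params <- function(params, instrument = load_instrument()) {
  p <- params
  if (is.na(p$n_sites) || p$n_sites < 0)
    qhws_stop("qhws_invalid_params", "n_sites must be a nonnegative integer")
  edef <- instrument_elements(instrument)
  if (!all(names(p$element_marginals) %in% edef$element_id))
    qhws_stop("qhws_invalid_params", "element_marginals names unknown: %s",
              paste(setdiff(names(p$element_marginals), edef$element_id),
                    collapse = ", "))
  missing_el <- setdiff(edef$element_id, names(p$element_marginals))
  if (length(missing_el))
    qhws_stop("qhws_invalid_params", "element_marginals missing element(s): %s",
              paste(missing_el, collapse = ", "))
  if (!is_prob(p$element_marginals))
    qhws_stop("qhws_invalid_params", "element_marginals must lie in [0, 1]")
  if (length(p$na_probability) && (!is_prob(p$na_probability) ||
      !all(names(p$na_probability) %in% edef$element_id)))
    qhws_stop("qhws_invalid_params", "na_probability invalid")
  if (!is.numeric(p$latent_correlation) || p$latent_correlation < 0 ||
      p$latent_correlation >= 1)
    qhws_stop("qhws_invalid_params", "latent_correlation must be in [0, 1)")
  if (any(p$principle_quality_sd <= 0) || p$rating_noise_sd <= 0)
    qhws_stop("qhws_invalid_params", "latent sds must be positive")
  if (length(p$rating_cutpoints) != 3L || any(diff(p$rating_cutpoints) <= 0))
    qhws_stop("qhws_invalid_params",
              "rating_cutpoints must be 3 strictly increasing values")
  if (!is.numeric(p$rater_agreement) || p$rater_agreement <= 0 ||
      p$rater_agreement > 1)
    qhws_stop("qhws_invalid_params", "rater_agreement must be in (0, 1]")
  if (!is_prob(p$sponsor_mix) || abs(sum(p$sponsor_mix) - 1) > 1e-8)
    qhws_stop("qhws_invalid_params", "sponsor_mix must sum to 1")
  invisible(params)
}

# marginal distribution of a rating for principle p under the latent model:
# latent ~ N(mu_p, sqrt(sd_p^2 + noise^2)), discretised at the cutpoints
rating_marginal <- function(mu, sd_total, cutpoints) {
  cdf <- stats::pnorm(cutpoints, mean = mu, sd = sd_total)
  diff(c(0, cdf, 1))
}

#' Generate a single-rater synthetic assessment dataset
#'
#' Draws per-site disclosure outcomes and usability ratings under the
#' latent-factor model described in \link{synthetic}. Deterministic for a
#' fixed seed (the seed lives in \code{params}).
#'
#' @param params a \code{qhws_generator_params}.
#' @param instrument instrument defining the item ids (canonical default).
#' @param rater_id rater label for the generated rows.
#' @return list of class \code{qhws_assessment_set}:
#'   \describe{
#'     \item{assessments}{long data.frame (site_id, rater_id, item_id,
#'       item_kind, value, page_obs) in the dialect [score_dataset()] reads}
#'     \item{sites}{site metadata (site_id, url, sponsor_type,
#'       health_item_count, exclusion_flags)}
#'     \item{params, seed}{generation record}
#'   }
#' @export
generate_dataset <- function(params = generator_params(),
                             instrument = load_instrument(),
                             rater_id = "r1") {
  validate_generator_params(params, instrument)
  set.seed(params$seed)
  out <- generate_rater_a(params, instrument, rater_id)
  structure(list(assessments = out$assessments, sites = out$sites,
                 params = params, seed = params$seed),
            class = "qhws_assessment_set")
}

# core draw for rater A; separated so the two-rater generator shares one
# RNG stream layout with the single-rater one
generate_rater_a <- function(params, instrument, rater_id) {
  edef <- instrument_elements(instrument)
  mdef <- instrument_measures(instrument)
  n <- params$n_sites
  site_ids <- sprintf("site%04d", seq_len(n))

  sponsor <- if (n > 0)
    sample(names(params$sponsor_mix), n, replace = TRUE,
           prob = params$sponsor_mix) else character(0)
  sites <- data.frame(
    site_id = site_ids,
    url = sprintf("https://example.org/%s", site_ids),
    sponsor_type = sponsor,
    health_item_count = if (n > 0) 3L + stats::rpois(n, 4) else integer(0),
    exclusion_flags = rep("", n),
    stringsAsFactors = FALSE)

  lambda <- params$latent_correlation
  ne <- nrow(edef)
  nm <- nrow(mdef)
  pq_mu <- params$principle_quality_mean
  pq_sd <- params$principle_quality_sd
  pid_of_measure <- match(mdef$principle_id,
                          vapply(instrument$principles, `[[`, integer(1),
                                 "principle_id"))

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    z_site <- stats::rnorm(1)
    eps <- stats::rnorm(ne)
    u <- sqrt(lambda) * z_site + sqrt(1 - lambda) * eps
    p_el <- params$element_marginals[edef$element_id]
    comply <- u <= stats::qnorm(p_el)
    na_p <- params$na_probability[edef$element_id]
    na_p[is.na(na_p)] <- 0
    is_na <- stats::runif(ne) < na_p
    el_value <- ifelse(is_na, NA_character_, ifelse(comply, "yes", "no"))

    s_p <- stats::rnorm(length(pq_mu), mean = pq_mu, sd = pq_sd)
    lat <- s_p[pid_of_measure] + stats::rnorm(nm, sd = params$rating_noise_sd)
    rating <- 1L + rowSums(outer(lat, params$rating_cutpoints, `>`))

    rows[[i]] <- data.frame(
      site_id = site_ids[i],
      rater_id = rater_id,
      item_id = c(edef$element_id, mdef$measure_id),
      item_kind = c(rep("element", ne), rep("measure", nm)),
      value = c(el_value, as.character(rating)),
      page_obs = NA_character_,
      stringsAsFactors = FALSE)
  }
  assessments <- if (n > 0) do.call(rbind, rows) else
    data.frame(site_id = character(0), rater_id = character(0),
               item_id = character(0), item_kind = character(0),
               value = character(0), page_obs = character(0),
               stringsAsFactors = FALSE)
  list(assessments = assessments, sites = sites)
}

#' Generate a two-rater synthetic assessment dataset
#'
#' Rater A is drawn as in [generate_dataset()]; rater B reproduces each of
#' A's item values with probability \code{rater_agreement} and otherwise
#' resamples independently from the item's marginal distribution (the
#' configured Bernoulli marginal for disclosure elements; the latent-model
#' rating marginal for measures). Not-applicable items stay NA for both
#' raters, applicability being a site property. Under this scheme the
#' expected Cohen's kappa on the binary items equals \code{rater_agreement}
#' exactly.
#'
#' @inheritParams generate_dataset
#' @param rater_ids labels for the two raters.
#' @return a \code{qhws_assessment_set} whose \code{assessments} contain
#'   both raters' rows.
#' @export
generate_two_rater <- function(params = generator_params(),
                               instrument = load_instrument(),
                               rater_ids = c("r1", "r2")) {
  validate_generator_params(params, instrument)
  stopifnot(length(rater_ids) == 2L)
  set.seed(params$seed)
  a <- generate_rater_a(params, instrument, rater_ids[1])
  aa <- a$assessments
  n_rows <- nrow(aa)
  if (n_rows == 0L)
    return(structure(list(assessments = aa, sites = a$sites, params = params,
                          seed = params$seed), class = "qhws_assessment_set"))

  edef <- instrument_elements(instrument)
  mdef <- instrument_measures(instrument)
  pid_of_measure <- match(mdef$principle_id,
                          vapply(instrument$principles, `[[`, integer(1),
                                 "principle_id"))
  sd_total <- sqrt(params$principle_quality_sd^2 + params$rating_noise_sd^2)
  rating_p <- lapply(seq_along(params$principle_quality_mean), function(j)
    rating_marginal(params$principle_quality_mean[j], sd_total[j],
                    params$rating_cutpoints))

  copy <- stats::runif(n_rows) < params$rater_agreement
  b_value <- aa$value
  redo <- which(!copy & !is.na(aa$value))
  for (k in redo) {
    if (aa$item_kind[k] == "element") {
      p <- params$element_marginals[[aa$item_id[k]]]
      b_value[k] <- if (stats::runif(1) < p) "yes" else "no"
    } else {
      j <- pid_of_measure[match(aa$item_id[k], mdef$measure_id)]
      b_value[k] <- as.character(sample.int(4L, 1L, prob = rating_p[[j]]))
    }
  }
  bb <- aa
  bb$rater_id <- rater_ids[2]
  bb$value <- b_value
  structure(list(assessments = rbind(aa, bb), sites = a$sites,
                 params = params, seed = params$seed),
            class = "qhws_assessment_set")
}

#' @export
print.qhws_assessment_set <- function(x, ...) {
  cat(sprintf("<qhws_assessment_set: %d sites, %d raters, %d rows (seed %d)>\n",
              length(unique(x$assessments$site_id)),
              length(unique(x$assessments$rater_id)),
              nrow(x$assessments), x$seed))
  invisible(x)
}
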