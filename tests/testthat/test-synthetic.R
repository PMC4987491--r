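test_that("generator is deterministic under a fixed seed", {
  p <- generator_params(n_sites = 15, seed = 101)
  d1 <- generate_dataset(p)
  d2 <- generate_dataset(p)
  expect_identical(d1$assessments, d2$assessments)
  expect_identical(d1$sites, d2$sites)
  d3 <- generate_dataset(generator_params(n_sites = 15, seed = 102))
  expect_false(identical(d1$assessments$value, d3$assessments$value))
})

test_that("degenerate parameters produce the forced extremes", {
  # all marginals 1, nothing NA: every site meets all 6 criteria
  marg <- default_element_marginals()
  marg[] <- 1
  p <- generator_params(n_sites = 8, element_marginals = marg,
                        na_probability = c(identify_advertising = 0),
                        seed = 3)
  scores <- score_dataset(generate_dataset(p)$assessments)
  expect_true(all(scores$scorecards$criteria_met_count == 6))

  # zero sites: header-only dataset
  p0 <- generator_params(n_sites = 0, seed = 1)
  d0 <- generate_dataset(p0)
  expect_equal(nrow(d0$assessments), 0L)
  expect_equal(names(d0$assessments),
               c("site_id", "rater_id", "item_id", "item_kind", "value",
                 "page_obs"))
})

test_that("zero latent correlation gives independent element outcomes", {
  marg <- default_element_marginals()
  marg[] <- 0.5
  p <- generator_params(n_sites = 1500,
                        element_marginals = marg,
                        na_probability = c(identify_advertising = 0),
                        latent_correlation = 0, seed = 17)
  a <- generate_dataset(p)$assessments
  el <- a[a$item_kind == "element" & a$item_id %in% c("name", "privacy_policy"), ]
  y <- split(el$value == "yes", el$item_id)  # both ordered by site
  r <- stats::cor(as.integer(y$name), as.integer(y$privacy_policy))
  expect_lt(abs(r), 3 / sqrt(length(y$name)))  # ~3 MC SEs of zero
})

test_that("positive latent correlation couples elements within a site", {
  marg <- default_element_marginals()
  marg[] <- 0.5
  p <- generator_params(n_sites = 1200, element_marginals = marg,
                        na_probability = c(identify_advertising = 0),
                        latent_correlation = 0.8, seed = 19)
  a <- generate_dataset(p)$assessments
  el <- a[a$item_kind == "element" & a$item_id %in% c("name", "privacy_policy"), ]
  y <- split(el$value == "yes", el$item_id)
  expect_gt(stats::cor(as.integer(y$name), as.integer(y$privacy_policy)), 0.3)
})

test_that("calibration is monotone in the configured parameters", {
  rate_for <- function(marg_val) {
    marg <- default_element_marginals()
    marg["funding_sources"] <- marg_val
    p <- generator_params(n_sites = 400, element_marginals = marg, seed = 23)
    a <- generate_dataset(p)$assessments
    mean(a$value[a$item_id == "funding_sources"] == "yes", na.rm = TRUE)
  }
  expect_gt(rate_for(0.9), rate_for(0.3))

  met_rate_for <- function(mu) {
    p <- generator_params(n_sites = 300, principle_quality_mean = mu,
                          seed = 29)
    s <- score_dataset(generate_dataset(p)$assessments)
    mean(s$principle_scores$met[s$principle_scores$principle_id == 1])
  }
  expect_gt(met_rate_for(3.8), met_rate_for(2.8))
})

test_that("element compliance concentrates on the configured marginals", {
  p <- generator_params(n_sites = 800, seed = 37)
  a <- generate_dataset(p)$assessments
  marg <- p$element_marginals
  for (eid in c("name", "funding_sources", "date_created")) {
    v <- a$value[a$item_id == eid]
    obs <- mean(v == "yes", na.rm = TRUE)
    se <- sqrt(marg[[eid]] * (1 - marg[[eid]]) / sum(!is.na(v)))
    expect_lt(abs(obs - marg[[eid]]), 3 * se)
  }
  # NA imposed at the configured rate for the conditional element
  adv <- a$value[a$item_id == "identify_advertising"]
  expect_lt(abs(mean(is.na(adv)) - 0.40), 3 * sqrt(0.4 * 0.6 / length(adv)))
})

test_that("two-rater data reach kappa 1 at full agreement", {
  p <- generator_params(n_sites = 30, rater_agreement = 1, seed = 41)
  set <- generate_two_rater(p)
  a <- set$assessments
  r1 <- a[a$rater_id == "r1" & a$item_kind == "element", ]
  r2 <- a[a$rater_id == "r2" & a$item_kind == "element", ]
  expect_identical(r1$value, r2$value)
  keep <- !is.na(r1$value)
  expect_equal(cohens_kappa(r1$value[keep], r2$value[keep])$value, 1)
})

test_that("two-rater kappa matches its closed-form expectation", {
  # B copies A with probability a, else resamples the marginal; the
  # expected kappa is then exactly a
  marg <- default_element_marginals()
  marg[] <- 0.6
  p <- generator_params(n_sites = 60, element_marginals = marg,
                        na_probability = c(identify_advertising = 0),
                        rater_agreement = 0.8, seed = 43)
  set <- generate_two_rater(p)  # 60 sites x 16 elements = 960 item pairs
  a <- set$assessments
  r1 <- a[a$rater_id == "r1" & a$item_kind == "element", ]
  r2 <- a[a$rater_id == "r2" & a$item_kind == "element", ]
  k <- cohens_kappa(r1$value, r2$value)$value
  expect_lt(abs(k - 0.8), 0.05)
})

test_that("invalid generator parameters are rejected", {
  expect_error(generator_params(latent_correlation = 1),
               class = "qhws_invalid_params")
  expect_error(generator_params(rater_agreement = 0),
               class = "qhws_invalid_params")
  expect_error(generator_params(rating_cutpoints = c(3, 2, 1)),
               class = "qhws_invalid_params")
  expect_error(generator_params(sponsor_mix = c("for-profit" = 0.9,
                                                "nonprofit" = 0.9,
                                                "government" = 0.2)),
               class = "qhws_invalid_params")
  marg <- default_element_marginals()
  marg <- marg[-1]
  expect_error(generator_params(element_marginals = marg),
               class = "qhws_invalid_params")
})
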