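test_that("proportion estimates reproduce every published baseline row", {
  rows <- published_baseline_rows()
  expect_equal(nrow(rows), 39L)  # 20 reliability + 19 usability rows
  for (i in seq_len(nrow(rows))) {
    p <- presented(proportion_estimate(rows$count[i], rows$n[i]))
    lab <- paste(rows$table[i], rows$id[i])
    expect_equal(p[["percent"]], rows$percent[i], info = lab)
    expect_equal(p[["se"]], rows$se[i], info = lab)
    expect_equal(p[["ci_low"]], rows$ci_low[i], info = lab)
    expect_equal(p[["ci_high"]], rows$ci_high[i], info = lab)
  }
})

test_that("proportion_estimate enforces its domain and boundary behaviour", {
  expect_error(proportion_estimate(5, 0), class = "qhws_domain_error")
  expect_error(proportion_estimate(11, 10), class = "qhws_domain_error")
  expect_error(proportion_estimate(-1, 10), class = "qhws_domain_error")
  # SE is zero iff count is 0 or n
  expect_equal(proportion_estimate(0, 50)$se, 0)
  expect_equal(proportion_estimate(50, 50)$se, 0)
  expect_gt(proportion_estimate(1, 50)$se, 0)
  full <- presented(proportion_estimate(100, 100))
  expect_equal(unname(full), c(100, 0, 100, 100))
  # CI clipped to [0, 100]
  low <- proportion_estimate(1, 100)
  expect_gte(low$ci_low, 0)
})

test_that("SE peaks at count = n/2 and CI width shrinks with n", {
  n <- 100
  ses <- vapply(0:n, function(k) proportion_estimate(k, n)$se, numeric(1))
  expect_equal(which.max(ses) - 1L, 50L)
  widths <- vapply(c(25, 50, 100, 400), function(n) {
    e <- proportion_estimate(round(0.3 * n), n)
    e$ci_high - e$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("compliance table uses per-item applicability denominators", {
  instr <- load_instrument()
  edef <- qhws:::instrument_elements(instr)
  mdef <- qhws:::instrument_measures(instr)
  n <- 10
  rows <- lapply(seq_len(n), function(i) {
    ev <- setNames(rep("yes", nrow(edef)), edef$element_id)
    if (i <= 4) ev["identify_advertising"] <- NA  # ad-free sites
    else if (i <= 6) ev["identify_advertising"] <- "no"
    rv <- setNames(rep(4L, nrow(mdef)), mdef$measure_id)
    if (i == 1) rv[mdef$principle_id == 5] <- NA  # principle unscorable
    site_rows(sprintf("s%02d", i), ev, rv)
  })
  scores <- score_dataset(do.call(rbind, rows), instr)
  tab <- compliance_table(scores, instr)

  adv <- tab[tab$kind == "element" & tab$id == "identify_advertising", ]
  expect_equal(adv$n, 6L)       # 4 NA sites drop out of the denominator
  expect_equal(adv$count, 4L)

  p5 <- tab[tab$kind == "principle" & tab$id == "5", ]
  expect_equal(p5$n, 9L)        # unscorable site dropped
  expect_equal(p5$count, 9L)

  # criterion denominators cover every scored site
  expect_true(all(tab$n[tab$kind == "criterion"] == n))
  # 39 of 99 scorable reproduces the published 39.4% pattern
  expect_equal(presented(proportion_estimate(39, 99))[["percent"]], 39.4)
})

test_that("compliance table rows follow instrument order and flag empty denominators", {
  a <- fixture_with_benchmarks(n = 5, n_rel = 3, n_usa = 2)
  scores <- score_dataset(a)
  tab <- compliance_table(scores)
  crit <- tab$id[tab$kind == "criterion"]
  expect_equal(crit, vapply(load_instrument()$criteria, `[[`, character(1),
                            "criterion_id"))
  expect_equal(tab$id[tab$kind == "principle"], as.character(1:19))

  # all-NA element: row kept, estimate NA, warning raised
  a2 <- a
  a2$value[a2$item_id == "editorial_policy"] <- NA
  scores2 <- score_dataset(a2)
  expect_warning(tab2 <- compliance_table(scores2), "editorial_policy")
  row <- tab2[tab2$id == "editorial_policy", ]
  expect_equal(row$n, 0L)
  expect_true(is.na(row$percent))
})

test_that("met-count distributions sum to n with benchmark tail identities", {
  a <- fixture_with_benchmarks(n = 100, n_rel = 58, n_usa = 42)
  scores <- score_dataset(a)
  dc <- met_count_distribution(scores, "criteria")
  dp <- met_count_distribution(scores, "principles")
  expect_equal(dc$k, 0:6)
  expect_equal(dp$k, 0:19)
  expect_equal(sum(dc$count), 100)
  expect_equal(sum(dp$count), 100)
  expect_equal(sum(dc$count[dc$k >= 3]),
               sum(scores$scorecards$reliability_benchmark_met))
  expect_equal(sum(dp$count[dp$k >= 10]), 42)

  # all-maximal sites put the whole mass at the top
  b <- fixture_with_benchmarks(n = 5, n_rel = 5, n_usa = 5)
  b$value[b$item_kind == "element"] <- "yes"
  b$value[b$item_kind == "measure"] <- "4"
  sb <- score_dataset(b)
  expect_equal(met_count_distribution(sb, "criteria")$count[7], 5L)
  expect_equal(met_count_distribution(sb, "principles")$count[20], 5L)
})

test_that("targets are the minimal statistically significant improvement", {
  expect_equal(set_target(42, 100)$target_percent, 55.7)
  expect_equal(set_target(50, 100)$target_percent, 63.9)
  expect_equal(set_target(58, 100)$target_percent, 71.7)
  t <- set_target(proportion_estimate(42, 100))
  expect_equal(t$method, "minimal-statistical-significance")
  expect_equal(t$baseline_percent, 42)
  expect_error(set_target(0, 100), class = "qhws_domain_error")
  expect_error(set_target(100, 100), class = "qhws_domain_error")
  # strictly increasing in SE at fixed baseline: smaller n, larger target
  t_small <- set_target(21, 50)
  expect_gt(t_small$target_percent, set_target(42, 100)$target_percent)
  expect_gt(t$target_percent, t$baseline_percent)
  # an externally mandated override is recorded, never substituted
  t_ov <- set_target(58, 100, override = 70.5)
  expect_equal(t_ov$target_percent, 71.7)
  expect_equal(t_ov$target_override, 70.5)
})

test_that("Wald coverage is near nominal for moderate p (light check)", {
  set.seed(31)
  n <- 100
  cis <- t(vapply(0:n, function(k) {
    e <- proportion_estimate(k, n)
    c(e$ci_low, e$ci_high)
  }, numeric(2)))
  for (p in c(0.3, 0.5)) {
    draws <- stats::rbinom(2000, n, p)
    cover <- mean(cis[draws + 1, 1] <= 100 * p & 100 * p <= cis[draws + 1, 2])
    expect_gt(cover, 0.90)
    expect_lt(cover, 0.99)
  }
})
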