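test_that("score_element aggregates page observations under each policy", {
  el <- list(element_id = "date_created", page_scoped = TRUE)
  expect_equal(score_element(NA, el, c(TRUE, TRUE, TRUE)), "yes")
  expect_equal(score_element(NA, el, c(TRUE, FALSE, TRUE)), "no")
  expect_equal(score_element(NA, el, c(TRUE, FALSE, TRUE), "any"), "yes")
  expect_equal(score_element(NA, el, c(TRUE, FALSE, TRUE), "majority"), "yes")
  expect_equal(score_element(NA, el, c(TRUE, FALSE, FALSE), "majority"), "no")
  expect_equal(score_element(NA, el, c(FALSE, FALSE, FALSE), "any"), "no")
  # page-scoped with neither value nor observations is unassessable
  expect_error(score_element(NA, el), class = "qhws_missing_data")
  # a plain value is accepted when no pages were sampled separately
  expect_equal(score_element("yes", el), "yes")
})

test_that("score_element passes plain and NA values through", {
  el <- list(element_id = "identify_advertising", page_scoped = FALSE)
  expect_equal(score_element("no", el), "no")
  expect_true(is.na(score_element(NA, el)))  # conditional: not applicable
  expect_error(score_element("maybe", el), class = "qhws_bad_value")
})

test_that("criterion rule: all required non-NA elements must be yes", {
  instr <- load_instrument()
  uf <- instr$criteria[[5]]  # User Feedback
  expect_equal(uf$criterion_id, "UserFeedback")
  # optional 'how user information is used' cannot fail the criterion
  expect_true(score_criterion(uf, c(feedback_mechanism = "yes",
                                    user_info_use = "no")))
  ident <- instr$criteria[[1]]
  expect_false(score_criterion(ident, c(name = "yes", street_address = "yes",
                                        funding_sources = "no")))
  # conditional NA is excluded from the determination
  cd <- instr$criteria[[3]]
  expect_true(score_criterion(cd, c(identify_advertising = NA,
                                    editorial_policy = "yes",
                                    authorship = "yes")))
  expect_error(score_criterion(ident, c(name = "yes")),
               "street_address", class = "qhws_missing_data")
})

test_that("criterion rule matches exhaustive enumeration over {yes,no,NA}^k", {
  # three elements: required, optional, required-conditional
  cr <- list(criterion_id = "X", elements = list(
    list(element_id = "e1", required = TRUE),
    list(element_id = "e2", required = FALSE),
    list(element_id = "e3", required = TRUE)))
  vals <- c("yes", "no", NA)
  grid <- expand.grid(e1 = vals, e2 = vals, e3 = vals,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    res <- c(e1 = grid$e1[i], e2 = grid$e2[i], e3 = grid$e3[i])
    # reference semantics, written out directly
    expected <- !isTRUE(res[["e1"]] == "no") && !isTRUE(res[["e3"]] == "no")
    expect_identical(score_criterion(cr, res), expected,
                     info = paste(res, collapse = "/"))
  }
})

test_that("principle_score averages non-NA ratings", {
  expect_equal(principle_score(c(4, 4, 4)), 4)
  expect_equal(principle_score(c(3, 4)), 3.5)
  expect_equal(principle_score(c(2, NA, 4)), 3)
  expect_true(is.na(principle_score(c(NA, NA))))
  expect_error(principle_score(c(0, 4)), class = "qhws_bad_value")
  expect_error(principle_score(c(2, 5)), class = "qhws_bad_value")
})

test_that("principle_met is inclusive at the threshold and exact on boundaries", {
  expect_true(principle_met(3.5))
  expect_false(principle_met(3.49))
  expect_false(principle_met(NA_real_))
  # integer-ratio comparison: means that are exactly 3.5 from any rating
  # count must be met, one rating point below must not
  for (m in 2:10) {
    if ((7 * m) %% 2 != 0) next
    s <- (7 * m) %/% 2
    ratings <- rep(c(3L, 4L), length.out = m)
    stopifnot(sum(ratings) == s)
    expect_true(principle_met(NA, ratings = ratings))
    below <- ratings; below[1] <- below[1] - 1L
    expect_false(principle_met(NA, ratings = below))
  }
})

test_that("scorecard benchmarks follow the 3-of-6 and 10-of-19 rules", {
  a <- fixture_with_benchmarks(n = 4, n_rel = 2, n_usa = 1)
  scores <- score_dataset(a)
  sc <- scores$scorecards
  expect_equal(sc$criteria_met_count, c(3, 3, 2, 2))
  expect_equal(sc$reliability_benchmark_met, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sc$principles_met_count, c(10, 9, 9, 9))
  expect_equal(sc$usability_benchmark_met, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("maximal input yields a full scorecard", {
  instr <- load_instrument()
  edef <- qhws:::instrument_elements(instr)
  mdef <- qhws:::instrument_measures(instr)
  ev <- setNames(rep("yes", nrow(edef)), edef$element_id)
  rv <- setNames(rep(4L, nrow(mdef)), mdef$measure_id)
  card <- build_scorecard(ev, rv, instr, site_id = "max")
  expect_equal(card$criteria_met_count, 6)
  expect_equal(card$principles_met_count, 19)
  expect_true(card$reliability_benchmark_met)
  expect_true(card$usability_benchmark_met)
})

test_that("scorecards match the first-principles oracle on random small instruments", {
  set.seed(42)
  for (rep in 1:20) {
    instr <- make_small_instrument()
    edef <- qhws:::instrument_elements(instr)
    mdef <- qhws:::instrument_measures(instr)
    for (draw in 1:10) {
      ev <- setNames(sample(c("yes", "no", NA), nrow(edef), replace = TRUE),
                     edef$element_id)
      rv <- setNames(sample(c(1:4, NA), nrow(mdef), replace = TRUE),
                     mdef$measure_id)
      card <- build_scorecard(ev, rv, instr)
      oracle <- oracle_scorecard(as.list(ev), as.list(rv), instr)
      expect_equal(card$criteria_met_count, oracle$criteria_met_count)
      expect_equal(card$principles_met_count, oracle$principles_met_count)
    }
  }
})

test_that("flipping no->yes or raising a rating never lowers met counts", {
  set.seed(7)
  instr <- load_instrument()
  edef <- qhws:::instrument_elements(instr)
  mdef <- qhws:::instrument_measures(instr)
  for (rep in 1:15) {
    ev <- setNames(sample(c("yes", "no", NA), nrow(edef), replace = TRUE,
                          prob = c(.4, .4, .2)), edef$element_id)
    rv <- setNames(sample(c(1:4, NA), nrow(mdef), replace = TRUE),
                   mdef$measure_id)
    base <- build_scorecard(ev, rv, instr)
    nos <- which(!is.na(ev) & ev == "no")
    if (length(nos)) {
      ev2 <- ev; ev2[sample(nos, 1)] <- "yes"
      expect_gte(build_scorecard(ev2, rv, instr)$criteria_met_count,
                 base$criteria_met_count)
    }
    low <- which(!is.na(rv) & rv < 4)
    if (length(low)) {
      rv2 <- rv; j <- sample(low, 1); rv2[j] <- rv2[j] + 1L
      expect_gte(build_scorecard(ev, rv2, instr)$principles_met_count,
                 base$principles_met_count)
    }
  }
})

test_that("scorecards are invariant to response row order", {
  a <- fixture_with_benchmarks(n = 6, n_rel = 3, n_usa = 2)
  set.seed(99)
  shuffled <- a[sample(nrow(a)), ]
  s1 <- score_dataset(a)
  s2 <- score_dataset(shuffled)
  o1 <- s1$scorecards[order(s1$scorecards$site_id), ]
  o2 <- s2$scorecards[order(s2$scorecards$site_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("invalid responses are rejected with context", {
  a <- fixture_with_benchmarks(n = 2, n_rel = 1, n_usa = 1)
  a$value[a$item_kind == "measure"][1] <- "5"
  expect_error(score_dataset(a), class = "qhws_bad_value")
  b <- fixture_with_benchmarks(n = 2, n_rel = 1, n_usa = 1)
  b$item_id[1] <- "no_such_element"
  expect_error(score_dataset(b), "no_such_element",
               class = "qhws_unknown_item")
})
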