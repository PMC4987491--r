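# shared helpers: independent oracles and fixture builders

# closed-form Cohen's kappa straight from 2x2 contingency counts
# (yy = both yes, yn = A yes / B no, ...). Independent of cohens_kappa(),
# which works from rating vectors.
kappa_from_counts <- function(yy, yn, ny, nn) {
  n <- yy + yn + ny + nn
  p_o <- (yy + nn) / n
  p_e <- ((yy + yn) * (yy + ny) + (ny + nn) * (yn + nn)) / n^2
  if (p_e >= 1) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

# expand 2x2 counts into the two rating vectors cohens_kappa() consumes
vectors_from_counts <- function(yy, yn, ny, nn) {
  list(a = c(rep("yes", yy + yn), rep("no", ny + nn)),
       b = c(rep("yes", yy), rep("no", yn), rep("yes", ny), rep("no", nn)))
}

# ICC(A,1) via stats::aov mean squares — an independent route to the
# variance decomposition hand-rolled in icc()
icc_a1_aov <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  subject = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = d))[[1]][["Mean Sq"]]
  ms_s <- ms[1]; ms_r <- ms[2]; ms_e <- ms[3]
  (ms_s - ms_e) / (ms_s + (k - 1) * ms_e + k * (ms_r - ms_e) / n)
}

# IRR results at a chosen value, for exercising gates and categorisation
new_kappa_result <- function(value) qhws:::new_irr_result("kappa", value, 0.80)
new_icc_result <- function(value) qhws:::new_irr_result("icc", value, 0.61)

# tiny random instrument for brute-force scoring equivalence:
# n_crit criteria x up to max_el elements, n_prin principles x up to
# max_me measures, with random required/optional flags
make_small_instrument <- function(n_crit = 2, max_el = 3, n_prin = 2,
                                  max_me = 3) {
  criteria <- lapply(seq_len(n_crit), function(ci) {
    k <- sample(seq_len(max_el), 1)
    req <- sample(c(TRUE, FALSE), k, replace = TRUE)
    req[sample(k, 1)] <- TRUE  # every criterion needs >=1 required element
    list(criterion_id = paste0("C", ci), name = paste0("C", ci),
         elements = lapply(seq_len(k), function(ei)
           list(element_id = sprintf("c%de%d", ci, ei), text = "t",
                required = req[ei], page_scoped = FALSE,
                conditional = FALSE)))
  })
  principles <- lapply(seq_len(n_prin), function(pi) {
    k <- sample(seq_len(max_me), 1)
    list(principle_id = pi, category = "SiteDesign", name = paste0("P", pi),
         measures = lapply(seq_len(k), function(mi)
           list(measure_id = sprintf("p%dm%d", pi, mi), text = "t",
                principle_id = pi, scale_min = 1L, scale_max = 4L)),
         met_threshold = 3.5)
  })
  instr <- structure(list(criteria = criteria, principles = principles,
                          reliability_benchmark_min = 1L,
                          usability_benchmark_min = 1L,
                          version = "test"),
                     class = "qhws_instrument")
  validate_instrument(instr)
  instr
}

# first-principles scorecard evaluator, coded independently of
# build_scorecard: plain loops, criterion rule and threshold rule written
# out from the definitions
oracle_scorecard <- function(element_results, ratings, instr) {
  crit_met <- logical(0)
  for (cr in instr$criteria) {
    met <- TRUE
    for (el in cr$elements) {
      if (!el$required) next
      v <- element_results[[el$element_id]]
      if (is.na(v)) next
      if (v == "no") met <- FALSE
    }
    crit_met[cr$criterion_id] <- met
  }
  prin_met <- logical(0)
  for (p in instr$principles) {
    s <- 0L; m <- 0L
    for (me in p$measures) {
      v <- ratings[[me$measure_id]]
      if (!is.na(v)) { s <- s + as.integer(v); m <- m + 1L }
    }
    # mean >= 3.5  <=>  2*sum >= 7*m, exact in integers
    prin_met[as.character(p$principle_id)] <- m > 0L && 2L * s >= 7L * m
  }
  list(criteria_met_count = sum(crit_met),
       principles_met_count = sum(prin_met),
       crit_met = crit_met, prin_met = prin_met)
}

# long-form assessment rows for one site from named element/rating vectors
site_rows <- function(site_id, element_results, ratings,
                      rater_id = "r1") {
  rbind(
    data.frame(site_id = site_id, rater_id = rater_id,
               item_id = names(element_results), item_kind = "element",
               value = unname(unlist(element_results)),
               page_obs = NA_character_, stringsAsFactors = FALSE),
    data.frame(site_id = site_id, rater_id = rater_id,
               item_id = names(ratings), item_kind = "measure",
               value = as.character(unname(unlist(ratings))),
               page_obs = NA_character_, stringsAsFactors = FALSE))
}

# deterministic assessment table in which exactly `n_rel` of `n` sites meet
# >= 3 reliability criteria and exactly `n_usa` meet >= 10 usability
# principles (canonical instrument)
fixture_with_benchmarks <- function(n = 100, n_rel = 58, n_usa = 42) {
  instr <- load_instrument()
  edef <- qhws:::instrument_elements(instr)
  mdef <- qhws:::instrument_measures(instr)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    # criteria in instrument order; first 3 yes => meets benchmark
    n_crit_met <- if (i <= n_rel) 3L else 2L
    met_crit <- vapply(instr$criteria, `[[`, character(1),
                       "criterion_id")[seq_len(n_crit_met)]
    ev <- ifelse(edef$criterion_id %in% met_crit, "yes", "no")
    names(ev) <- edef$element_id
    n_prin_met <- if (i <= n_usa) 10L else 9L
    pid_met <- seq_len(n_prin_met)
    rv <- ifelse(mdef$principle_id %in% pid_met, 4L, 1L)
    names(rv) <- mdef$measure_id
    rows[[i]] <- site_rows(sprintf("s%03d", i), ev, rv)
  }
  do.call(rbind, rows)
}
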