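#' @title Analysis pipeline
#'
#' @description
#' [run_pipeline()] ties the stages together the way the survey analysis
#' runs end to end: read (or accept) a long-form assessment table, score
#' every site against the instrument, estimate compliance with Wald
#' intervals, tabulate the met-count distributions, compute interrater
#' reliability when a second rater is present, set improvement targets for
#' both objectives, and write the whole bundle as CSV/text files. All
#' numbers in the files are produced by the same module functions a user
#' would call directly; the pipeline adds no arithmetic of its own.
#'
#' @name pipeline
NULL

#' Run the full survey analysis and write a report bundle
#'
#' @param assessments long-form assessment data.frame, a
#'   \code{qhws_assessment_set}, or a path to an assessment CSV.
#' @param output_dir directory for the report bundle (created if absent).
#'   \code{NULL} skips writing and just returns the results.
#' @param instrument a \code{qhws_instrument}, or a path to a YAML
#'   definition, or \code{NULL} for the canonical default.
#' @param z critical value for intervals (default 1.96).
#' @param page_policy pass rule for page-scoped elements.
#' @param icc_form ICC form for the usability IRR (see [icc()]).
#' @param target_z critical value used in target setting (default 1.96).
#' @param rater rater whose responses are scored (default: first in data).
#' @return invisibly, a list with \code{scores}, \code{table}
#'   (compliance table), \code{criteria_distribution},
#'   \code{principles_distribution}, \code{benchmarks} (summary data.frame),
#'   \code{targets} (list of \code{qhws_target}), \code{irr} (list with
#'   \code{kappa} and \code{icc} results, or \code{NULL} for single-rater
#'   data) and \code{files} (paths written).
#'
#' Files written to \code{output_dir}: \code{scorecards.csv},
#' \code{compliance_table.csv}, \code{criteria_distribution.csv},
#' \code{principles_distribution.csv}, \code{benchmark_summary.csv},
#' \code{targets.csv}, and \code{irr_report.txt} when two raters are
#' present. On any failure, files already written by this call are removed.
#' @examples
#' set <- generate_dataset(generator_params(n_sites = 10, seed = 7))
#' res <- run_pipeline(set, output_dir = NULL)
#' res$benchmarks
#' @export
run_pipeline <- function(assessments, output_dir = NULL,
                         instrument = NULL, z = 1.96,
                         page_policy = c("all", "any", "majority"),
                         icc_form = c("absolute", "consistency"),
                         target_z = 1.96, rater = NULL) {
  page_policy <- match.arg(page_policy)
  icc_form <- match.arg(icc_form)

  if (is.character(assessments)) assessments <- read_assessments_csv(assessments)
  if (inherits(assessments, "qhws_assessment_set"))
    assessments <- assessments$assessments
  if (is.null(instrument)) instrument <- load_instrument()
  else if (is.character(instrument)) instrument <- load_instrument(instrument)

  scores <- score_dataset(assessments, instrument, rater = rater,
                          page_policy = page_policy)
  tab <- compliance_table(scores, instrument, z = z)
  dist_c <- met_count_distribution(scores, "criteria")
  dist_p <- met_count_distribution(scores, "principles",
                                   max_count = length(instrument$principles))

  sc <- scores$scorecards
  n_sites <- nrow(sc)
  rel_count <- sum(sc$reliability_benchmark_met)
  usa_count <- sum(sc$usability_benchmark_met)
  rel_est <- proportion_estimate(rel_count, n_sites, z)
  usa_est <- proportion_estimate(usa_count, n_sites, z)
  benchmarks <- data.frame(
    objective = c("HC/HIT-8.1", "HC/HIT-8.2"),
    rule = c(sprintf(">=%d of %d reliability criteria",
                     instrument$reliability_benchmark_min,
                     length(instrument$criteria)),
             sprintf(">=%d of %d usability principles",
                     instrument$usability_benchmark_min,
                     length(instrument$principles))),
    count = c(rel_count, usa_count),
    n = n_sites,
    percent = c(presented(rel_est)[["percent"]], presented(usa_est)[["percent"]]),
    se = c(presented(rel_est)[["se"]], presented(usa_est)[["se"]]),
    ci_low = c(presented(rel_est)[["ci_low"]], presented(usa_est)[["ci_low"]]),
    ci_high = c(presented(rel_est)[["ci_high"]], presented(usa_est)[["ci_high"]]),
    stringsAsFactors = FALSE)

  targets <- list()
  for (i in 1:2) {
    est <- if (i == 1) rel_est else usa_est
    targets[[benchmarks$objective[i]]] <-
      if (est$count > 0 && est$count < est$n)
        set_target(est, z = target_z) else NULL
  }

  irr_res <- NULL
  raters <- unique(assessments$rater_id)
  if (length(raters) >= 2L)
    irr_res <- pipeline_irr(assessments, raters[1:2], icc_form)

  files <- character(0)
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir))
      dir.create(output_dir, recursive = TRUE)
    written <- character(0)
    emit <- function(fn, name) {
      path <- file.path(output_dir, name)
      fn(path)
      written <<- c(written, path)
    }
    tryCatch({
      emit(function(p) write_scorecards_csv(scores, p), "scorecards.csv")
      emit(function(p) write_csv_qhws(tab, p), "compliance_table.csv")
      emit(function(p) write_csv_qhws(dist_c, p), "criteria_distribution.csv")
      emit(function(p) write_csv_qhws(dist_p, p), "principles_distribution.csv")
      emit(function(p) write_csv_qhws(benchmarks, p), "benchmark_summary.csv")
      tdf <- do.call(rbind, lapply(names(targets), function(nm) {
        t <- targets[[nm]]
        if (is.null(t)) return(NULL)
        data.frame(objective = nm, baseline_percent = t$baseline_percent,
                   n = t$n, se = t$se, target_percent = t$target_percent,
                   method = t$method, stringsAsFactors = FALSE)
      }))
      if (!is.null(tdf)) emit(function(p) write_csv_qhws(tdf, p), "targets.csv")
      if (!is.null(irr_res))
        emit(function(p) {
          con <- file(p, "w")
          on.exit(close(con))
          sink(con); on.exit(sink(), add = TRUE, after = FALSE)
          cat("Interrater reliability report\n")
          cat("=============================\n\n")
          cat("HC/HIT-8.1 (nominal disclosure items, Cohen's kappa):\n")
          print(irr_res$kappa)
          cat(sprintf("  gate: %s\n\n",
                      if (irr_gate("HC/HIT-8.1", irr_res$kappa)) "PASS" else "FAIL"))
          cat("HC/HIT-8.2 (ordinal usability ratings, ICC):\n")
          print(irr_res$icc)
          cat(sprintf("  gate: %s\n",
                      if (irr_gate("HC/HIT-8.2", irr_res$icc)) "PASS" else "FAIL"))
        }, "irr_report.txt")
      files <- written
    }, error = function(e) {
      unlink(written)
      stop(e)
    })
  }

  invisible(list(scores = scores, table = tab,
                 criteria_distribution = dist_c,
                 principles_distribution = dist_p,
                 benchmarks = benchmarks, targets = targets,
                 irr = irr_res, files = files))
}

# pair the two raters on co-rated items: kappa over binary element
# responses, ICC over ordinal measure ratings (items as subjects)
pipeline_irr <- function(assessments, raters, icc_form = "absolute") {
  a <- assessments[assessments$rater_id == raters[1], , drop = FALSE]
  b <- assessments[assessments$rater_id == raters[2], , drop = FALSE]
  key <- function(df) paste(df$site_id, df$item_id, sep = "\r")
  common <- intersect(key(a), key(b))
  a <- a[match(common, key(a)), , drop = FALSE]
  b <- b[match(common, key(b)), , drop = FALSE]

  el <- a$item_kind == "element"
  kappa_res <- cohens_kappa(a$value[el], b$value[el], threshold = 0.80)
  m <- cbind(as.numeric(a$value[!el]), as.numeric(b$value[!el]))
  icc_res <- icc(m, threshold = 0.61, form = icc_form)
  list(kappa = kappa_res, icc = icc_res)
}

#' Simulate an assessment dataset and write it to disk
#'
#' Thin wrapper over [generate_dataset()] / [generate_two_rater()] that
#' writes the assessment CSV, the site metadata CSV and a YAML metadata
#' record (generator parameters, seed, package version). Identical
#' parameters (including seed) produce byte-identical files.
#'
#' @param params a \code{qhws_generator_params}.
#' @param output_dir directory to write into (created if absent);
#'   \code{NULL} skips writing.
#' @param two_rater generate a second rater (default FALSE).
#' @param instrument instrument definition (canonical default).
#' @return invisibly, the \code{qhws_assessment_set}, with a \code{files}
#'   attribute listing paths written.
#' @export
simulate_assessments <- function(params = generator_params(),
                                 output_dir = NULL, two_rater = FALSE,
                                 instrument = load_instrument()) {
  set <- if (two_rater) generate_two_rater(params, instrument)
         else generate_dataset(params, instrument)
  files <- character(0)
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    f1 <- file.path(output_dir, "assessments.csv")
    f2 <- file.path(output_dir, "sites.csv")
    f3 <- file.path(output_dir, "metadata.yaml")
    write_assessments_csv(set, f1)
    write_sites_csv(set$sites, f2)
    meta <- unclass(params)
    meta$element_marginals <- as.list(meta$element_marginals)
    meta$na_probability <- as.list(meta$na_probability)
    meta$sponsor_mix <- as.list(meta$sponsor_mix)
    yaml::write_yaml(list(generator = meta, seed = params$seed,
                          two_rater = two_rater,
                          package_version =
                            as.character(utils::packageVersion("qhws"))), f3)
    files <- c(f1, f2, f3)
  }
  attr(set, "files") <- files
  invisible(set)
}
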