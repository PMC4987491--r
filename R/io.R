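#' @title CSV dialects
#'
#' @description
#' All interchange formats are plain CSV. NA is canonically encoded as an
#' empty field; the literal string \code{NA} is accepted on read. Every
#' writer/reader pair round-trips losslessly.
#'
#' Dialects:
#' \itemize{
#'   \item assessments (long form): \code{site_id,rater_id,item_id,item_kind,value,page_obs}
#'     with \code{item_kind} in \{element, measure\} and \code{page_obs} a
#'     slash-separated 0/1 string for page-scoped elements.
#'   \item sites: \code{site_id,url,sponsor_type,health_item_count,exclusion_flags}
#'     (semicolon-joined flags, empty for none).
#'   \item IRR pairs: \code{item_id,site_id,rater_a,rater_b}.
#'   \item scorecards out: \code{site_id,criteria_met_count,reliability_met,principles_met_count,usability_met}.
#'   \item compliance table out: \code{kind,id,label,n,count,percent,se,ci_low,ci_high}
#'     at full precision plus the rounded presentation columns.
#'   \item histogram out: \code{k,count}.
#' }
#'
#' @name qhws_io
NULL

read_csv_qhws <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                  colClasses = "character", check.names = FALSE)
}

write_csv_qhws <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a long-form assessment CSV
#'
#' @param path CSV with header
#'   \code{site_id,rater_id,item_id,item_kind,value,page_obs} (page_obs
#'   optional). Malformed rows raise an error naming the file and line.
#' @return data.frame in the assessment dialect.
#' @export
read_assessments_csv <- function(path) {
  df <- read_csv_qhws(path)
  needed <- c("site_id", "rater_id", "item_id", "item_kind", "value")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    qhws_stop("qhws_bad_input", "%s: missing column(s) %s", path,
              paste(missing_cols, collapse = ", "))
  if (is.null(df$page_obs)) df$page_obs <- NA_character_
  bad <- which(!df$item_kind %in% c("element", "measure"))
  if (length(bad))
    qhws_stop("qhws_bad_input",
              "%s line %d: item_kind must be 'element' or 'measure', got '%s'",
              path, bad[1] + 1L, df$item_kind[bad[1]])
  df
}

#' Write a long-form assessment CSV
#'
#' @param assessments assessment data.frame (or a
#'   \code{qhws_assessment_set}, whose \code{assessments} component is
#'   written).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_assessments_csv <- function(assessments, path) {
  if (inherits(assessments, "qhws_assessment_set"))
    assessments <- assessments$assessments
  write_csv_qhws(assessments, path)
}

#' Read site metadata CSV
#'
#' @param path CSV with header
#'   \code{site_id,url,sponsor_type,health_item_count,exclusion_flags}.
#' @return data.frame ready for [eligibility_filter()].
#' @export
read_sites_csv <- function(path) {
  df <- read_csv_qhws(path)
  needed <- c("site_id", "url", "sponsor_type", "health_item_count",
              "exclusion_flags")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    qhws_stop("qhws_bad_input", "%s: missing column(s) %s", path,
              paste(missing_cols, collapse = ", "))
  df$health_item_count <- as.integer(df$health_item_count)
  df$exclusion_flags[is.na(df$exclusion_flags)] <- ""
  df
}

#' @rdname read_sites_csv
#' @param sites site metadata data.frame.
#' @export
write_sites_csv <- function(sites, path) {
  write_csv_qhws(sites, path)
}

#' Read a two-rater IRR pair CSV
#'
#' @param path CSV with header \code{item_id,site_id,rater_a,rater_b}.
#' @return data.frame with those columns.
#' @export
read_irr_csv <- function(path) {
  df <- read_csv_qhws(path)
  needed <- c("item_id", "site_id", "rater_a", "rater_b")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    qhws_stop("qhws_bad_input", "%s: missing column(s) %s", path,
              paste(missing_cols, collapse = ", "))
  df
}

#' Write scorecards to CSV
#'
#' @param scorecards scorecards data.frame from [score_dataset()] (or a
#'   \code{qhws_scores} object).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_scorecards_csv <- function(scorecards, path) {
  if (inherits(scorecards, "qhws_scores")) scorecards <- scorecards$scorecards
  out <- data.frame(
    site_id = scorecards$site_id,
    criteria_met_count = scorecards$criteria_met_count,
    reliability_met = scorecards$reliability_benchmark_met,
    principles_met_count = scorecards$principles_met_count,
    usability_met = scorecards$usability_benchmark_met,
    stringsAsFactors = FALSE)
  write_csv_qhws(out, path)
}
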