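#' Exclusion-reason vocabulary for sample eligibility
#'
#' The closed set of reasons a candidate website is excluded from the
#' sample, in the order they are checked (reason reporting is deterministic:
#' the first matching flag wins). The final reason,
#' \code{insufficient-health-content}, is applied to sites with fewer than
#' three items of health information and is never supplied as a flag.
#'
#' @return character vector of valid exclusion flags (not including
#'   \code{insufficient-health-content}).
#' @export
exclusion_vocabulary <- function() {
  c("not-about-humans",
    "foreign-owned",
    "professional-development",
    "product-sales-only",
    "laboratory-services-platform",
    "login-required",
    "beauty-cosmetic",
    "health-education-program",
    "fitness-industry",
    "pharmacy-price-comparison",
    "social-forum")
}

#' Filter candidate websites for sample eligibility
#'
#' A site enters the sample iff it carries at least 3 items of health
#' information (\code{health_item_count >= 3}) and none of the enumerated
#' exclusion flags. Excluded sites are reported with a single reason: the
#' first matching flag in the order of [exclusion_vocabulary()], or
#' \code{insufficient-health-content} when only the item-count rule fails.
#'
#' @param sites data.frame with columns \code{site_id}, \code{health_item_count}
#'   and \code{exclusion_flags} (character; semicolon-separated flags, empty
#'   or \code{NA} for none). Extra columns (url, sponsor_type, ...) pass
#'   through untouched.
#' @param min_health_items inclusion threshold (default 3).
#' @return list with data.frames \code{included} (same columns as input) and
#'   \code{excluded} (input columns plus \code{reason}). Together they
#'   partition the input.
#' @examples
#' sites <- data.frame(
#'   site_id = c("a", "b", "c"),
#'   health_item_count = c(5, 4, 2),
#'   exclusion_flags = c("", "login-required", ""))
#' eligibility_filter(sites)
#' @export
eligibility_filter <- function(sites, min_health_items = 3L) {
  stopifnot(is.data.frame(sites))
  needed <- c("site_id", "health_item_count", "exclusion_flags")
  missing_cols <- setdiff(needed, names(sites))
  if (length(missing_cols))
    qhws_stop("qhws_bad_input", "sites is missing column(s): %s",
              paste(missing_cols, collapse = ", "))
  if (nrow(sites) == 0L) {
    excluded <- sites
    excluded$reason <- character(0)
    return(list(included = sites, excluded = excluded))
  }
  if (anyNA(sites$health_item_count))
    qhws_stop("qhws_bad_input", "health_item_count has missing values")

  vocab <- exclusion_vocabulary()
  flags <- strsplit(ifelse(is.na(sites$exclusion_flags), "",
                           sites$exclusion_flags), ";", fixed = TRUE)
  flags <- lapply(flags, function(f) f[nzchar(trimws(f))])
  unknown <- setdiff(unlist(flags), vocab)
  if (length(unknown))
    qhws_stop("qhws_bad_input", "unknown exclusion flag(s): %s",
              paste(unique(unknown), collapse = ", "))

  reason <- vapply(seq_len(nrow(sites)), function(i) {
    hit <- vocab[vocab %in% flags[[i]]]
    if (length(hit)) return(hit[1])
    if (sites$health_item_count[i] < min_health_items)
      return("insufficient-health-content")
    NA_character_
  }, character(1))

  keep <- is.na(reason)
  included <- sites[keep, , drop = FALSE]
  excluded <- sites[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  rownames(included) <- NULL
  rownames(excluded) <- NULL
  list(included = included, excluded = excluded)
}
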