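#' @title Survey instrument definition
#'
#' @description
#' The National Quality Health Website Survey instrument combines two
#' Healthy People 2020 measurement tools: a disclosure-based information
#' reliability rubric (objective HC/HIT-8.1: 6 criteria, each a list of
#' yes/no disclosure elements) and a usability rubric (objective HC/HIT-8.2:
#' 19 established usability principles in 3 categories, scored as the mean
#' of 59 task-based measures rated 1-4). The instrument is plain data:
#' everything downstream -- scoring, estimation, simulation -- is driven by
#' the definition returned here, so alternative rubrics can be loaded from
#' a YAML config without touching any scoring code.
#'
#' Element attributes:
#' \itemize{
#'   \item \code{required}: optional elements (marked as such in the
#'     instrument) never determine whether a criterion is met.
#'   \item \code{page_scoped}: assessed per sampled page of health content;
#'     a per-page pass rule (\code{page_policy}) aggregates them.
#'   \item \code{conditional}: applicability depends on site features (for
#'     example, differentiating advertising on a site that carries no
#'     advertising); expressed in the data as \code{NA} responses, which
#'     drop the site from that element's denominator.
#' }
#'
#' @name instrument
NULL

# canonical reliability rubric: 6 criteria, elements in instrument order
canonical_criteria <- function() {
  el <- function(id, text, required = TRUE, page_scoped = FALSE,
                 conditional = FALSE) {
    list(element_id = id, text = text, required = required,
         page_scoped = page_scoped, conditional = conditional)
  }
  list(
    list(criterion_id = "Identity", name = "Identity", elements = list(
      el("name", "Name of person or organization responsible for website"),
      el("street_address",
         "Street address for person or organization responsible for website"),
      el("funding_sources", "Identified source of funding for website")
    )),
    list(criterion_id = "Purpose", name = "Purpose", elements = list(
      el("purpose_mission", "Statement of purpose or mission for website"),
      el("uses_limitations", "Uses and limitations of services provided"),
      el("commercial_association",
         "Association with commercial products or services")
    )),
    list(criterion_id = "ContentDevelopment", name = "Content Development",
         elements = list(
      el("identify_advertising",
         "Differentiation of advertising from nonadvertising content",
         conditional = TRUE),
      el("editorial_policy",
         "Medical, editorial, or quality review practices or policies"),
      el("authorship", "Authorship of health content", page_scoped = TRUE)
    )),
    list(criterion_id = "Privacy", name = "Privacy", elements = list(
      el("privacy_policy", "Privacy policy"),
      el("personal_info_protection", "How personal information is protected")
    )),
    list(criterion_id = "UserFeedback", name = "User Feedback", elements = list(
      el("feedback_mechanism", "Feedback form or mechanism"),
      el("user_info_use", "How information from users is used",
         required = FALSE)
    )),
    list(criterion_id = "ContentUpdating", name = "Content Updating",
         elements = list(
      el("date_created", "Date content created", page_scoped = TRUE),
      el("date_reviewed",
         "Date content reviewed, updated, modified, or revised",
         page_scoped = TRUE),
      el("copyright_date", "Copyright date", required = FALSE)
    ))
  )
}

# canonical usability rubric: 19 principles in 3 categories.
# The individual task texts of the 59 measures are not part of the public
# record; measures are generated as placeholders from a per-principle
# allocation table (configurable; totals 59).
canonical_principles <- function(measure_allocation = NULL) {
  names19 <- c(
    "Use conventional interaction elements",
    "Make it obvious what is clickable and what is not",
    "Minimize vertical scrolling",
    "Ensure that the Back button behaves predictably",
    "Provide clear feedback signals for actions",
    "Ensure site is accessible for users with disabilities and uses elements of 508 compliance",
    "Provide a simplified user experience",
    "Incorporate multimedia",
    "Offer a functional home page",
    "Present a clear visual hierarchy",
    "Provide easy search functionality",
    "Clearly label content categories",
    "Make pages easy to skim or scan",
    "Make elements on the page easy to read",
    "Visually group related topics",
    "Make sure text and background colors contrast",
    "Focus the writing on audience and purpose",
    "Use the users' language; minimize jargon and technical terms",
    "Allow for interaction with the content"
  )
  categories <- rep(c("SiteDesign", "InformationArchitecture", "ContentDesign"),
                    times = c(9, 7, 3))
  if (is.null(measure_allocation)) {
    # 59 task-based measures over 19 principles; the first principle of each
    # of the two larger categories carries one extra measure
    measure_allocation <- rep(3L, 19L)
    measure_allocation[c(1L, 10L)] <- 4L
  }
  stopifnot(length(measure_allocation) == 19L)
  lapply(seq_len(19L), function(i) {
    measures <- lapply(seq_len(measure_allocation[i]), function(j) {
      list(measure_id = sprintf("m%02d_%d", i, j),
           text = sprintf("Task-based measure %d for principle %d", j, i),
           principle_id = i, scale_min = 1L, scale_max = 4L)
    })
    list(principle_id = i, category = categories[i], name = names19[i],
         measures = measures, met_threshold = 3.5)
  })
}

#' Load a survey instrument definition
#'
#' With no source, returns the canonical National Quality Health Website
#' Survey instrument: 6 information reliability criteria (16 disclosure
#' elements) and 19 usability principles holding 59 task-based measures,
#' with benchmark minima of 3 criteria and 10 principles. A YAML file
#' produced by [write_instrument()] round-trips losslessly.
#'
#' @param source path to a YAML instrument definition, or \code{NULL} for
#'   the canonical default.
#' @param measure_allocation optional integer vector of length 19 giving the
#'   number of measures per principle in the default instrument (must sum to
#'   a positive total; canonical allocation sums to 59). Ignored when
#'   \code{source} is given.
#' @return an object of class \code{qhws_instrument}: a list with
#'   \code{criteria}, \code{principles}, \code{reliability_benchmark_min},
#'   \code{usability_benchmark_min} and \code{version}.
#' @examples
#' instr <- load_instrument()
#' length(instr$criteria)    # 6
#' length(instr$principles)  # 19
#' sum(vapply(instr$principles, function(p) length(p$measures), integer(1)))
#' @export
load_instrument <- function(source = NULL, measure_allocation = NULL) {
  if (is.null(source)) {
    instr <- list(
      criteria = canonical_criteria(),
      principles = canonical_principles(measure_allocation),
      reliability_benchmark_min = 3L,
      usability_benchmark_min = 10L,
      version = "hp2020-canonical-1.0"
    )
  } else {
    raw <- yaml::read_yaml(source)
    instr <- raw
    instr$reliability_benchmark_min <- as.integer(raw$reliability_benchmark_min)
    instr$usability_benchmark_min <- as.integer(raw$usability_benchmark_min)
    instr$principles <- lapply(raw$principles, function(p) {
      p$principle_id <- as.integer(p$principle_id)
      p$measures <- lapply(p$measures, function(m) {
        m$principle_id <- as.integer(m$principle_id)
        m$scale_min <- as.integer(m$scale_min)
        m$scale_max <- as.integer(m$scale_max)
        m
      })
      p
    })
  }
  class(instr) <- "qhws_instrument"
  validate_instrument(instr)
  instr
}

#' Serialise an instrument definition to YAML
#'
#' @param instrument a \code{qhws_instrument}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_instrument <- function(instrument, path) {
  validate_instrument(instrument)
  x <- unclass(instrument)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Validate an instrument definition
#'
#' Checks id uniqueness, non-empty criteria and principles, at least one
#' required element per criterion, rating scale bounds, and benchmark minima
#' within range. Called by [load_instrument()]; exported so hand-built
#' definitions can be checked too.
#'
#' @param instrument a \code{qhws_instrument}.
#' @return \code{instrument}, invisibly, if valid; otherwise an error of
#'   class \code{qhws_invalid_instrument} naming the offending id.
#' @export
validate_instrument <- function(instrument) {
  crit <- instrument$criteria
  prin <- instrument$principles
  if (length(crit) == 0L)
    qhws_stop("qhws_invalid_instrument", "instrument has no criteria")
  if (length(prin) == 0L)
    qhws_stop("qhws_invalid_instrument", "instrument has no principles")
  cids <- vapply(crit, `[[`, character(1), "criterion_id")
  if (anyDuplicated(cids))
    qhws_stop("qhws_invalid_instrument", "duplicate criterion_id: %s",
              cids[duplicated(cids)][1])
  for (cr in crit) {
    if (length(cr$elements) == 0L)
      qhws_stop("qhws_invalid_instrument",
                "criterion '%s' has no elements", cr$criterion_id)
    req <- vapply(cr$elements, `[[`, logical(1), "required")
    if (!any(req))
      qhws_stop("qhws_invalid_instrument",
                "criterion '%s' has no required element", cr$criterion_id)
  }
  eids <- unlist(lapply(crit, function(cr)
    vapply(cr$elements, `[[`, character(1), "element_id")))
  if (anyDuplicated(eids))
    qhws_stop("qhws_invalid_instrument", "duplicate element_id: %s",
              eids[duplicated(eids)][1])
  pids <- vapply(prin, `[[`, integer(1), "principle_id")
  if (anyDuplicated(pids))
    qhws_stop("qhws_invalid_instrument", "duplicate principle_id: %d",
              pids[duplicated(pids)][1])
  for (p in prin) {
    if (length(p$measures) == 0L)
      qhws_stop("qhws_invalid_instrument",
                "principle %d ('%s') has no measures", p$principle_id, p$name)
    if (!is.numeric(p$met_threshold) || p$met_threshold < p$measures[[1]]$scale_min ||
        p$met_threshold > p$measures[[1]]$scale_max)
      qhws_stop("qhws_invalid_instrument",
                "principle %d met_threshold outside rating scale",
                p$principle_id)
  }
  mids <- unlist(lapply(prin, function(p)
    vapply(p$measures, `[[`, character(1), "measure_id")))
  if (anyDuplicated(mids))
    qhws_stop("qhws_invalid_instrument", "duplicate measure_id: %s",
              mids[duplicated(mids)][1])
  rb <- instrument$reliability_benchmark_min
  ub <- instrument$usability_benchmark_min
  if (!is.numeric(rb) || rb < 0 || rb > length(crit))
    qhws_stop("qhws_invalid_instrument",
              "reliability_benchmark_min %s outside [0, %d]", rb, length(crit))
  if (!is.numeric(ub) || ub < 0 || ub > length(prin))
    qhws_stop("qhws_invalid_instrument",
              "usability_benchmark_min %s outside [0, %d]", ub, length(prin))
  invisible(instrument)
}

#' @export
print.qhws_instrument <- function(x, ...) {
  ne <- sum(vapply(x$criteria, function(cr) length(cr$elements), integer(1)))
  nm <- sum(vapply(x$principles, function(p) length(p$measures), integer(1)))
  cat(sprintf(
    paste0("<qhws_instrument %s>\n",
           "  %d reliability criteria (%d disclosure elements), benchmark >= %d\n",
           "  %d usability principles (%d measures, rated 1-4), benchmark >= %d\n"),
    x$version, length(x$criteria), ne, x$reliability_benchmark_min,
    length(x$principles), nm, x$usability_benchmark_min))
  invisible(x)
}

# internal lookup helpers -----------------------------------------------

instrument_elements <- function(instrument) {
  rows <- lapply(instrument$criteria, function(cr) {
    data.frame(
      criterion_id = cr$criterion_id,
      element_id = vapply(cr$elements, `[[`, character(1), "element_id"),
      required = vapply(cr$elements, `[[`, logical(1), "required"),
      page_scoped = vapply(cr$elements, `[[`, logical(1), "page_scoped"),
      conditional = vapply(cr$elements, `[[`, logical(1), "conditional"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

instrument_measures <- function(instrument) {
  rows <- lapply(instrument$principles, function(p) {
    data.frame(
      principle_id = p$principle_id,
      measure_id = vapply(p$measures, `[[`, character(1), "measure_id"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
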