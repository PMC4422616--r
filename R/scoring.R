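#' @title Case studies, metric scores and threshold scoring
#' @name scoring
NULL

#' Construct a case study
#'
#' A case study is one fishery scored at a base year: metadata plus a score
#' sheet of metric levels (integer 1--5 or `NA` for missing) and score-quality
#' ratings (`"A"` highly confident the score is correct; `"B"` highly
#' confident the true score is within one bin; `"C"` educated guess; `NA`
#' unrated). A missing level may not carry a quality rating.
#'
#' @param case_id Short unique identifier.
#' @param fishery_name Human-readable fishery name.
#' @param country Country of the fishery.
#' @param base_year Calendar year of scoring.
#' @param development_status `"developed"` or `"developing"`.
#' @param scores Data frame with columns `metric_id`, `level`, `quality`.
#' @return An object of class `fpi_case`.
#' @examples
#' cs <- case_study("demo", "Demo fishery", "Norway", 2013, "developed",
#'                  data.frame(metric_id = "crew_earnings_vs_regional",
#'                             level = 4, quality = "A"))
#' @export
case_study <- function(case_id, fishery_name, country, base_year,
                       development_status = c("developed", "developing"),
                       scores = NULL) {
  development_status <- match.arg(development_status)
  if (is.null(scores)) {
    scores <- data.frame(metric_id = character(), level = integer(),
                         quality = character(), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(scores),
            all(c("metric_id", "level", "quality") %in% names(scores)))
  scores <- data.frame(metric_id = as.character(scores$metric_id),
                       level = as.integer(scores$level),
                       quality = as.character(scores$quality),
                       stringsAsFactors = FALSE)
  bad_level <- !is.na(scores$level) & !(scores$level %in% 1:5)
  if (any(bad_level)) {
    stop("levels outside 1..5 for metric(s): ",
         paste(scores$metric_id[bad_level], collapse = ", "), call. = FALSE)
  }
  bad_q <- !is.na(scores$quality) & !(scores$quality %in% c("A", "B", "C"))
  if (any(bad_q)) {
    stop("quality ratings outside {A,B,C} for metric(s): ",
         paste(scores$metric_id[bad_q], collapse = ", "), call. = FALSE)
  }
  orphan_q <- is.na(scores$level) & !is.na(scores$quality)
  if (any(orphan_q)) {
    stop("a missing level may not carry a quality rating: ",
         paste(scores$metric_id[orphan_q], collapse = ", "), call. = FALSE)
  }
  structure(
    list(case_id = as.character(case_id),
         fishery_name = as.character(fishery_name),
         country = as.character(country),
         base_year = as.integer(base_year),
         development_status = development_status,
         scores = scores),
    class = "fpi_case")
}

#' @export
print.fpi_case <- function(x, ...) {
  cat("FPI case study '", x$case_id, "': ", x$fishery_name, " (",
      x$country, ", ", x$base_year, ", ", x$development_status, ")\n", sep = "")
  cat("  scored metrics: ", sum(!is.na(x$scores$level)), " of ",
      nrow(x$scores), " listed\n", sep = "")
  invisible(x)
}

#' Validate a case study against a schema
#'
#' Reports unknown metric ids, out-of-range levels, duplicate score rows, and
#' quality ratings attached to missing levels. Violations are data, not
#' exceptions. Scored coverage per instrument side is attached as attribute
#' `coverage` (named vector, scored metrics / schema metrics).
#'
#' @param case An `fpi_case`.
#' @param s An `fpi_schema`.
#' @return An `fpi_validation` data frame with attribute `coverage`.
#' @export
validate_case <- function(case, s) {
  stopifnot(inherits(case, "fpi_case"), inherits(s, "fpi_schema"))
  v <- list()
  add <- function(...) v[[length(v) + 1L]] <<- .violation(...)
  sc <- case$scores
  unknown <- setdiff(sc$metric_id, s$metrics$metric_id)
  for (id in unknown) add("unknown_metric", id,
                          paste0("metric '", id, "' not in schema"))
  dup <- unique(sc$metric_id[duplicated(sc$metric_id)])
  for (id in dup) add("duplicate_score", id,
                      paste0("metric '", id, "' scored more than once"))
  bad <- sc$metric_id[!is.na(sc$level) & !(sc$level %in% 1:5)]
  for (id in bad) add("level_out_of_range", id,
                      paste0("metric '", id, "' level outside 1..5"))
  orphan <- sc$metric_id[is.na(sc$level) & !is.na(sc$quality)]
  for (id in orphan) add("quality_without_level", id,
                         paste0("metric '", id, "' has quality but missing level"))
  out <- .finish_validation(v)
  scored <- sc$metric_id[!is.na(sc$level)]
  cov <- vapply(c(output = "output", input = "input"), function(side) {
    ids <- s$metrics$metric_id[s$metrics$side == side]
    if (length(ids) == 0L) return(NA_real_)
    length(intersect(scored, ids)) / length(ids)
  }, numeric(1))
  attr(out, "coverage") <- cov
  out
}

# ---- threshold rules -------------------------------------------------------

#' Construct a threshold scoring rule
#'
#' A threshold rule maps a measured quantity (e.g. the ratio of crew annual
#' earnings to the regional average) onto the 1--5 metric scale through four
#' ordered interior breakpoints. The boundary convention is explicit: element
#' `i` of `boundary_to_upper` states whether a value exactly equal to
#' `breakpoints[i]` falls into the upper of the two adjacent level bands. The
#' packaged rules put each edge in the band closer to the scale midpoint, so
#' the level-3 band is closed and the extreme bands are open.
#'
#' @param metric_id Metric the rule scores.
#' @param breakpoints Strictly increasing numeric vector of length 4.
#' @param boundary_to_upper Logical vector of length 4 (see above).
#' @param domain_min Lower bound of the measurement domain (default 0 for
#'   ratio-type rules).
#' @param direction `"benefit"` (higher measurement, higher level) is the only
#'   packaged direction; `"cost"` reverses the level order.
#' @param name,variable,units Descriptive fields.
#' @return An object of class `fpi_threshold_rule`.
#' @export
threshold_rule <- function(metric_id, breakpoints, boundary_to_upper,
                           domain_min = 0, direction = c("benefit", "cost"),
                           name = metric_id, variable = "", units = "") {
  direction <- match.arg(direction)
  breakpoints <- as.numeric(breakpoints)
  boundary_to_upper <- as.logical(boundary_to_upper)
  if (length(breakpoints) != 4L || any(!is.finite(breakpoints)) ||
      any(diff(breakpoints) <= 0)) {
    stop("breakpoints must be 4 finite strictly increasing values", call. = FALSE)
  }
  if (length(boundary_to_upper) != 4L || anyNA(boundary_to_upper)) {
    stop("boundary_to_upper must be 4 non-missing logicals", call. = FALSE)
  }
  structure(
    list(metric_id = metric_id, name = name, variable = variable, units = units,
         domain_min = as.numeric(domain_min), direction = direction,
         breakpoints = breakpoints, boundary_to_upper = boundary_to_upper),
    class = "fpi_threshold_rule")
}

#' Load packaged threshold rules
#'
#' @param path YAML rules file; defaults to the packaged set, which includes
#'   the Crew Earnings Compared to Regional Average Earnings rule.
#' @return Named list of `fpi_threshold_rule`, keyed by metric id.
#' @examples
#' rules <- load_threshold_rules()
#' score_from_thresholds(1.6, rules$crew_earnings_vs_regional)
#' @export
load_threshold_rules <- function(path = system.file("extdata", "threshold_rules.yaml",
                                                    package = "fpitools",
                                                    mustWork = TRUE)) {
  raw <- yaml::read_yaml(path)
  rules <- lapply(raw$rules, function(r) {
    threshold_rule(metric_id = r$metric_id,
                   breakpoints = unlist(r$breakpoints),
                   boundary_to_upper = unlist(r$boundary_to_upper),
                   domain_min = r$domain_min %||% 0,
                   direction = r$direction %||% "benefit",
                   name = r$name %||% r$metric_id,
                   variable = r$variable %||% "", units = r$units %||% "")
  })
  stats::setNames(rules, vapply(rules, `[[`, character(1), "metric_id"))
}

#' Score a measurement through a threshold rule
#'
#' Deterministically assigns the unique level whose interval contains the
#' measured value under the rule's boundary convention. Monotone
#' non-decreasing in the value for benefit-type rules.
#'
#' @param value Numeric vector of measurements in the rule's units; must be
#'   finite and at least the rule's domain minimum.
#' @param rule An `fpi_threshold_rule`.
#' @return Integer vector of levels in 1..5.
#' @examples
#' rule <- load_threshold_rules()$crew_earnings_vs_regional
#' score_from_thresholds(c(1.60, 1.00, 0.40), rule)  # 5 3 1
#' @export
score_from_thresholds <- function(value, rule) {
  stopifnot(inherits(rule, "fpi_threshold_rule"))
  value <- as.numeric(value)
  if (anyNA(value) || any(!is.finite(value))) {
    stop("value must be finite and non-missing", call. = FALSE)
  }
  if (any(value < rule$domain_min)) {
    stop("value below the rule's domain minimum (", rule$domain_min, ")",
         call. = FALSE)
  }
  lev <- vapply(value, function(x) {
    band <- 1L
    for (k in seq_along(rule$breakpoints)) {
      bp <- rule$breakpoints[k]
      if (x > bp || (x == bp && rule$boundary_to_upper[k])) band <- k + 1L
    }
    band
  }, integer(1))
  if (rule$direction == "cost") lev <- 6L - lev
  lev
}

#' @export
print.fpi_threshold_rule <- function(x, ...) {
  cat("Threshold rule for '", x$metric_id, "' (", x$direction, ")\n", sep = "")
  cat("  breakpoints:", paste(x$breakpoints, collapse = ", "), "\n")
  invisible(x)
}
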