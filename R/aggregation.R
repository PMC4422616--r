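#' @title Dimension and indicator aggregation
#'
#' @description Metric levels roll up to dimension scores as (quality-)
#' weighted means of the non-missing levels, and dimension scores roll up to
#' indicator scores. Under uniform quality weights the aggregates are exactly
#' the unweighted means.
#'
#' @name aggregation
NULL

#' Construct a weighting scheme
#'
#' @param quality_weights Named non-negative weights for quality ratings
#'   `A`, `B`, `C`. The defaults (1.0, 0.6, 0.3) down-weight less confident
#'   scores; setting all three equal reproduces unweighted aggregation
#'   exactly.
#' @param indicator_method `"dimension_mean"` (default): an indicator score is
#'   the unweighted mean of its non-missing dimension scores, so each
#'   dimension contributes equally regardless of how many metrics it holds.
#'   `"metric_mean"`: the weighted mean over all the indicator's metrics
#'   directly.
#' @param min_coverage Fraction of a dimension's metrics that must be scored
#'   for the dimension score to be unflagged; below it the score is still
#'   computed but flagged (never silently dropped).
#' @param unrated_weight Weight for a scored metric with no quality rating.
#' @return An object of class `fpi_weights`.
#' @export
weighting_scheme <- function(quality_weights = c(A = 1.0, B = 0.6, C = 0.3),
                             indicator_method = c("dimension_mean", "metric_mean"),
                             min_coverage = 0.5, unrated_weight = 1.0) {
  indicator_method <- match.arg(indicator_method)
  qw <- quality_weights[c("A", "B", "C")]
  if (anyNA(qw) || any(!is.finite(qw)) || any(qw < 0) || all(qw == 0)) {
    stop("quality_weights must be named finite non-negative weights for A, B, C, ",
         "not all zero", call. = FALSE)
  }
  stopifnot(is.numeric(min_coverage), min_coverage >= 0, min_coverage <= 1,
            is.numeric(unrated_weight), unrated_weight >= 0)
  structure(list(quality_weights = qw, indicator_method = indicator_method,
                 min_coverage = min_coverage,
                 unrated_weight = as.numeric(unrated_weight)),
            class = "fpi_weights")
}

#' Uniform (unweighted) scheme
#' @param ... Passed to [weighting_scheme()].
#' @return An `fpi_weights` with A = B = C = 1.
#' @export
uniform_weights <- function(...) {
  weighting_scheme(quality_weights = c(A = 1, B = 1, C = 1), ...)
}

# weighted mean of levels given qualities; returns NA when nothing scored
.weighted_level_mean <- function(levels, qualities, w) {
  keep <- !is.na(levels)
  if (!any(keep)) return(NA_real_)
  lv <- levels[keep]
  wt <- ifelse(is.na(qualities[keep]), w$unrated_weight,
               unname(w$quality_weights[qualities[keep]]))
  if (sum(wt) == 0) return(NA_real_)
  # a weighted mean of levels is contained in [1, 5]; clamp floating-point noise
  min(5, max(1, sum(lv * wt) / sum(wt)))
}

.dimension_column <- function(partitioning) {
  switch(partitioning, tbl = "tbl_dimension", sector = "sector_dimension",
         input = "component_dimension",
         stop("unknown partitioning '", partitioning, "'", call. = FALSE))
}

.partitioning_of_dimension <- function(s, dim) {
  p <- s$dimensions$partitioning[s$dimensions$dimension_id == dim]
  if (length(p) != 1L) stop("unknown dimension '", dim, "'", call. = FALSE)
  p
}

#' Dimension score for one case
#'
#' Weighted mean of the case's non-missing metric levels in the dimension,
#' with weights given by the quality ratings. `NA` when no metric in the
#' dimension is scored. The result carries attributes `coverage` (scored /
#' total metrics in the dimension) and `flagged` (`TRUE` when coverage falls
#' below the scheme's `min_coverage`).
#'
#' @param case An `fpi_case`.
#' @param dim A dimension id (any partitioning).
#' @param s An `fpi_schema`.
#' @param w An `fpi_weights`; default uniform.
#' @return Numeric score in `[1, 5]` or `NA`, with attributes.
#' @examples
#' s <- fpi_schema()
#' cs <- case_study("d", "Demo", "X", 2014, "developed",
#'                  data.frame(metric_id = c("crew_earnings_vs_regional",
#'                                           "crew_opportunity_cost"),
#'                             level = c(3, 5), quality = c("A", "A")))
#' dimension_score(cs, "labor_returns", s)  # 4
#' @export
dimension_score <- function(case, dim, s, w = uniform_weights()) {
  stopifnot(inherits(case, "fpi_case"), inherits(s, "fpi_schema"),
            inherits(w, "fpi_weights"))
  part <- .partitioning_of_dimension(s, dim)
  col <- .dimension_column(part)
  ids <- s$metrics$metric_id[!is.na(s$metrics[[col]]) & s$metrics[[col]] == dim]
  idx <- match(ids, case$scores$metric_id)
  levels <- case$scores$level[idx]
  qualities <- case$scores$quality[idx]
  score <- .weighted_level_mean(levels, qualities, w)
  coverage <- if (length(ids)) sum(!is.na(levels)) / length(ids) else NA_real_
  attr(score, "coverage") <- coverage
  attr(score, "flagged") <- is.na(score) || coverage < w$min_coverage
  score
}

#' Indicator score for one case
#'
#' Under `indicator_method = "dimension_mean"` (default), the unweighted mean
#' of the indicator's non-missing dimension scores; under `"metric_mean"`,
#' the quality-weighted mean over all the indicator's metrics directly. The
#' two differ whenever dimensions hold different numbers of scored metrics.
#'
#' @param case An `fpi_case`.
#' @param ind An indicator id (tbl or sector partitioning) or input component id.
#' @param partitioning `"tbl"`, `"sector"`, or `"input"`.
#' @param s An `fpi_schema`.
#' @param w An `fpi_weights`.
#' @return Numeric score in `[1, 5]` or `NA`.
#' @export
indicator_score <- function(case, ind, partitioning = c("tbl", "sector", "input"),
                            s = fpi_schema(), w = uniform_weights()) {
  partitioning <- match.arg(partitioning)
  stopifnot(inherits(case, "fpi_case"), inherits(s, "fpi_schema"),
            inherits(w, "fpi_weights"))
  known <- if (partitioning == "input") s$components$component_id else
    s$indicators$indicator_id[s$indicators$partitioning == partitioning]
  if (!ind %in% known) {
    stop("unknown indicator '", ind, "' in partitioning '", partitioning, "'",
         call. = FALSE)
  }
  dims <- s$dimensions$dimension_id[s$dimensions$partitioning == partitioning &
                                      s$dimensions$parent == ind]
  if (w$indicator_method == "dimension_mean") {
    ds <- vapply(dims, function(d) as.numeric(dimension_score(case, d, s, w)),
                 numeric(1))
    if (all(is.na(ds))) NA_real_ else mean(ds, na.rm = TRUE)
  } else {
    col <- .dimension_column(partitioning)
    ids <- s$metrics$metric_id[!is.na(s$metrics[[col]]) &
                                 s$metrics[[col]] %in% dims]
    idx <- match(ids, case$scores$metric_id)
    .weighted_level_mean(case$scores$level[idx], case$scores$quality[idx], w)
  }
}

#' Bin a score into a traffic-light color
#'
#' Defaults anchor the instrument's reading of the scale: a score below 3 is
#' in need of improvement (red), `[3, 4)` performing well (yellow), 4 and
#' above performing very well (green).
#'
#' @param score Numeric vector of scores in `[1, 5]` (`NA` allowed, binned as
#'   `NA`).
#' @param bins Two ordered cutpoints `c(yellow_from, green_from)`.
#' @return Character vector in `{"red","yellow","green"}`.
#' @examples
#' color_bin(c(2.9, 3, 5))  # red yellow green
#' @export
color_bin <- function(score, bins = c(3, 4)) {
  stopifnot(length(bins) == 2L, bins[1] < bins[2])
  score <- as.numeric(score)
  if (any(!is.na(score) & (score < 1 | score > 5))) {
    stop("scores must lie in [1, 5]", call. = FALSE)
  }
  out <- ifelse(score < bins[1], "red", ifelse(score < bins[2], "yellow", "green"))
  out
}

#' Score all cases over all nodes of a partitioning
#'
#' Applies [dimension_score()] and [indicator_score()] over every case and
#' every node of the partitioning, producing a long-format score table. Row
#' order is deterministic: cases in input order, indicator rows before their
#' dimensions, nodes in schema order.
#'
#' @param cases A list of `fpi_case` or an `fpi_collection`.
#' @param s An `fpi_schema`.
#' @param w An `fpi_weights`.
#' @param partitioning `"tbl"`, `"sector"`, or `"input"`.
#' @param bins Color cutpoints passed to [color_bin()].
#' @return A data frame of class `fpi_score_table` with columns `case_id`,
#'   `partitioning`, `node_level` (`"indicator"`/`"dimension"`), `node_id`,
#'   `score`, `coverage`, `flag`, `color`.
#' @export
score_all <- function(cases, s = fpi_schema(), w = uniform_weights(),
                      partitioning = c("tbl", "sector", "input"),
                      bins = c(3, 4)) {
  partitioning <- match.arg(partitioning)
  if (inherits(cases, "fpi_collection")) cases <- cases$cases
  stopifnot(all(vapply(cases, inherits, logical(1), "fpi_case")))
  inds <- if (partitioning == "input") s$components$component_id else
    s$indicators$indicator_id[s$indicators$partitioning == partitioning]
  dims <- s$dimensions[s$dimensions$partitioning == partitioning, , drop = FALSE]
  rows <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    case <- cases[[i]]
    ind_scores <- vapply(inds, function(k)
      as.numeric(indicator_score(case, k, partitioning, s, w)), numeric(1))
    dim_vals <- lapply(dims$dimension_id, function(d) dimension_score(case, d, s, w))
    dim_scores <- vapply(dim_vals, as.numeric, numeric(1))
    dim_cov <- vapply(dim_vals, attr, numeric(1), "coverage")
    dim_flag <- vapply(dim_vals, attr, logical(1), "flagged")
    rows[[i]] <- data.frame(
      case_id = case$case_id,
      partitioning = partitioning,
      node_level = c(rep("indicator", length(inds)),
                     rep("dimension", nrow(dims))),
      node_id = c(inds, dims$dimension_id),
      score = c(ind_scores, dim_scores),
      coverage = c(rep(NA_real_, length(inds)), dim_cov),
      flag = c(rep(FALSE, length(inds)), dim_flag),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = character(), partitioning = character(),
               node_level = character(), node_id = character(),
               score = numeric(), coverage = numeric(), flag = logical(),
               stringsAsFactors = FALSE)
  out$color <- color_bin(out$score, bins)
  rownames(out) <- NULL
  class(out) <- c("fpi_score_table", "data.frame")
  out
}

#' Write a score table as delimited text
#'
#' Long format, `case_id,partitioning,node_level,node_id,score,coverage,flag,color`,
#' deterministic row order (as produced by [score_all()]), UTF-8, `.` decimal
#' point, missing values as `NA`.
#'
#' @param table An `fpi_score_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  stopifnot(inherits(table, "fpi_score_table"))
  df <- as.data.frame(table)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.fpi_score_table <- function(x, ...) {
  cat("FPI score table: ", length(unique(x$case_id)), " case(s), partitioning '",
      unique(x$partitioning), "'\n", sep = "")
  NextMethod()
}
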