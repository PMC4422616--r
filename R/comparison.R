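#' @title Cross-case comparison: rankings, rank-sum tests, rank correlation,
#'   group profiles
#' @name comparison
NULL

#' Rank cases by their score on one node
#'
#' Cases are ordered descending by score; ties receive average ranks, so the
#' rank sum over n ranked cases is always n(n+1)/2. Cases with a missing score
#' on the node are excluded from the ranking and listed separately.
#'
#' @param table An `fpi_score_table` (from [score_all()]).
#' @param node_id A node (dimension or indicator id) present in the table.
#' @return An object of class `fpi_ranking`: list with `node_id`, `ranking`
#'   (data frame `case_id`, `score`, `rank`, ordered by rank, ties broken by
#'   case id), `excluded` (case ids with missing score), `tie_method`.
#' @examples
#' # scores A:5 B:3 C:4 rank as A, C, B
#' @export
rank_cases <- function(table, node_id) {
  stopifnot(inherits(table, "fpi_score_table"))
  sub <- table[table$node_id == node_id, , drop = FALSE]
  if (nrow(sub) == 0L) stop("unknown node '", node_id, "'", call. = FALSE)
  excluded <- sub$case_id[is.na(sub$score)]
  sub <- sub[!is.na(sub$score), , drop = FALSE]
  if (nrow(sub) == 0L) {
    ranking <- data.frame(case_id = character(), score = numeric(),
                          rank = numeric(), stringsAsFactors = FALSE)
  } else {
    rk <- rank(-sub$score, ties.method = "average")
    ord <- order(rk, sub$case_id)
    ranking <- data.frame(case_id = sub$case_id[ord], score = sub$score[ord],
                          rank = rk[ord], stringsAsFactors = FALSE)
  }
  structure(list(node_id = node_id, ranking = ranking, excluded = excluded,
                 tie_method = "average"),
            class = "fpi_ranking")
}

#' @export
print.fpi_ranking <- function(x, ...) {
  cat("Ranking on node '", x$node_id, "' (", nrow(x$ranking), " case(s)",
      if (length(x$excluded)) paste0(", ", length(x$excluded), " excluded"),
      ")\n", sep = "")
  print(utils::head(x$ranking, 10), row.names = FALSE)
  invisible(x)
}

# exact null distribution of the rank-sum W of the first sample:
# all C(n, n1) equally likely rank subsets (requires no ties)
.exact_tail_probs <- function(ranks_x, n) {
  n1 <- length(ranks_x)
  combos <- utils::combn(n, n1)
  sums <- colSums(matrix(seq_len(n)[combos], nrow = n1))
  w <- sum(ranks_x)
  c(lower = mean(sums <= w), upper = mean(sums >= w))
}

#' Wilcoxon/Mann-Whitney rank-sum test
#'
#' Two-sided rank-sum test of identical distributions between two score
#' vectors. When both samples are small (`min(n1, n2) <= 10`) and there are
#' no ties, the p-value is exact, by complete enumeration of the
#' `choose(n1 + n2, n1)` equally likely rank assignments under the null.
#' Otherwise the tie-corrected normal approximation with continuity
#' correction is used. Two-sided p is `2 * min(lower tail, upper tail, 0.5)`,
#' capped at 1.
#'
#' @param x,y Numeric score vectors for the two groups (no missing values;
#'   each non-empty).
#' @return An object of class `fpi_ranksum`: list with `W` (rank sum of `x`
#'   in the pooled ranking), `U` (`W - n1(n1+1)/2`), `p_two_sided`, `method`
#'   (`"exact"` or `"normal_approx"`), `n1`, `n2`.
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4))$p_two_sided  # 1/3
#' @export
rank_sum_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) stop("empty sample", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in scores", call. = FALSE)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  rk <- rank(pooled, ties.method = "average")
  W <- sum(rk[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  # enumeration is bounded so a tiny sample paired with a huge one cannot
  # request billions of subsets; such cases fall through to the approximation
  if (!ties && min(n1, n2) <= 10L && choose(n, min(n1, n2)) <= 2e6) {
    tails <- .exact_tail_probs(rk[seq_len(n1)], n)
    p <- min(1, 2 * min(tails["lower"], tails["upper"], 0.5))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tab <- table(pooled)
    tie_term <- sum(tab^3 - tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      sd <- sqrt(sigma2)
      lower <- stats::pnorm(U + 0.5, mean = mu, sd = sd)
      upper <- stats::pnorm(U - 0.5, mean = mu, sd = sd, lower.tail = FALSE)
      p <- min(1, 2 * min(lower, upper, 0.5))
    }
    method <- "normal_approx"
  }
  structure(list(W = W, U = U, p_two_sided = unname(p), method = method,
                 n1 = n1, n2 = n2),
            class = "fpi_ranksum")
}

#' @export
print.fpi_ranksum <- function(x, ...) {
  cat("Wilcoxon/Mann-Whitney rank-sum test (", x$method, ")\n", sep = "")
  cat("  n1 = ", x$n1, ", n2 = ", x$n2, ", W = ", x$W, ", U = ", x$U,
      ", two-sided p = ", format(x$p_two_sided, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Spearman rank correlation between two rankings
#'
#' Spearman's rho computed as the Pearson correlation of the average ranks,
#' so ties are handled by the average-rank convention. The two rankings must
#' cover the same case set.
#'
#' @param r1,r2 `fpi_ranking` objects over the same cases.
#' @return rho in `[-1, 1]`.
#' @examples
#' # identical rankings give 1; an exact reversal with no ties gives -1
#' @export
rank_correlation <- function(r1, r2) {
  stopifnot(inherits(r1, "fpi_ranking"), inherits(r2, "fpi_ranking"))
  a <- r1$ranking; b <- r2$ranking
  if (!setequal(a$case_id, b$case_id)) {
    stop("rankings cover different case sets", call. = FALSE)
  }
  if (nrow(a) < 2L) stop("need at least 2 cases", call. = FALSE)
  m <- match(a$case_id, b$case_id)
  stats::cor(a$rank, b$rank[m])
}

.case_groups <- function(cases, grouping = NULL) {
  if (is.null(grouping)) {
    vapply(cases, `[[`, character(1), "development_status")
  } else if (is.function(grouping)) {
    vapply(cases, function(cs) as.character(grouping(cs)), character(1))
  } else {
    ids <- vapply(cases, `[[`, character(1), "case_id")
    g <- unname(grouping[ids])
    if (anyNA(g)) {
      stop("unlabeled case(s): ", paste(ids[is.na(g)], collapse = ", "),
           call. = FALSE)
    }
    as.character(g)
  }
}

#' Group means of dimension scores
#'
#' Per-dimension mean of the per-case dimension scores within each group
#' (developed vs developing by default), missing-aware: a case missing a
#' dimension does not contribute to that cell, and a group with no
#' contributing case yields `NA`.
#'
#' @param cases List of `fpi_case` or an `fpi_collection`.
#' @param s An `fpi_schema`.
#' @param w An `fpi_weights`.
#' @param grouping `NULL` to group by each case's `development_status`, or a
#'   named character vector `case_id -> group`, or a function of a case.
#' @param partitioning `"tbl"`, `"sector"`, or `"input"`.
#' @return Data frame: `dimension_id`, `dimension_name`, then one numeric
#'   column per group.
#' @export
group_dimension_means <- function(cases, s = fpi_schema(), w = uniform_weights(),
                                  grouping = NULL,
                                  partitioning = c("tbl", "sector", "input")) {
  partitioning <- match.arg(partitioning)
  if (inherits(cases, "fpi_collection")) cases <- cases$cases
  groups <- .case_groups(cases, grouping)
  dims <- s$dimensions[s$dimensions$partitioning == partitioning, , drop = FALSE]
  glev <- unique(groups)
  mat <- matrix(NA_real_, nrow = nrow(dims), ncol = length(glev),
                dimnames = list(dims$dimension_id, glev))
  scores <- vapply(cases, function(cs) {
    vapply(dims$dimension_id, function(d)
      as.numeric(dimension_score(cs, d, s, w)), numeric(1))
  }, numeric(nrow(dims)))
  scores <- matrix(scores, nrow = nrow(dims))  # dims x cases
  for (g in glev) {
    cols <- which(groups == g)
    mat[, g] <- rowMeans(scores[, cols, drop = FALSE], na.rm = TRUE)
  }
  mat[is.nan(mat)] <- NA_real_
  out <- data.frame(dimension_id = dims$dimension_id,
                    dimension_name = dims$name, stringsAsFactors = FALSE)
  for (g in glev) out[[g]] <- unname(mat[, g])
  out
}

#' Group means of score-quality ratings by dimension
#'
#' Quality ratings are mapped to numbers (by default A = 3, B = 2, C = 1:
#' higher means better information) and averaged per dimension within each
#' group, giving the quality-metadata profile of the instrument.
#'
#' @param cases List of `fpi_case` or an `fpi_collection`.
#' @param s An `fpi_schema`.
#' @param partitioning `"tbl"`, `"sector"`, or `"input"`.
#' @param quality_map Named numeric map for `A`, `B`, `C`.
#' @param grouping As in [group_dimension_means()].
#' @return Data frame: `dimension_id`, `dimension_name`, one column per group.
#' @export
quality_profile <- function(cases, s = fpi_schema(),
                            partitioning = c("tbl", "sector", "input"),
                            quality_map = c(A = 3, B = 2, C = 1),
                            grouping = NULL) {
  partitioning <- match.arg(partitioning)
  if (inherits(cases, "fpi_collection")) cases <- cases$cases
  stopifnot(all(c("A", "B", "C") %in% names(quality_map)))
  groups <- .case_groups(cases, grouping)
  dims <- s$dimensions[s$dimensions$partitioning == partitioning, , drop = FALSE]
  col <- .dimension_column(partitioning)
  glev <- unique(groups)
  out <- data.frame(dimension_id = dims$dimension_id,
                    dimension_name = dims$name, stringsAsFactors = FALSE)
  for (g in glev) out[[g]] <- NA_real_
  for (di in seq_len(nrow(dims))) {
    ids <- s$metrics$metric_id[!is.na(s$metrics[[col]]) &
                                 s$metrics[[col]] == dims$dimension_id[di]]
    for (g in glev) {
      qs <- unlist(lapply(cases[groups == g], function(cs) {
        cs$scores$quality[cs$scores$metric_id %in% ids]
      }))
      qs <- qs[!is.na(qs)]
      if (length(qs)) out[[g]][di] <- mean(unname(quality_map[qs]))
    }
  }
  out
}
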