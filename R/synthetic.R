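#' @title Synthetic case-study generation
#'
#' @description Latent-threshold (ordinal-probit-style) generator: each case
#' draws a latent Gaussian vector over all instrument metrics with a nested
#' block-correlation structure (metrics within a dimension correlate at
#' `rho_w`, across dimensions of one indicator at `rho_b`, across indicators
#' at `rho_x`), a latent mean shift `delta` is added for the developed group,
#' and the latent values are cut at fixed cutpoints into levels 1..5.
#' Quality labels are drawn independently of levels, and scores are knocked
#' out independently at a fixed missingness rate. The construction uses a
#' shared-factor decomposition, so any `rho_w >= rho_b >= rho_x >= 0` yields a
#' valid (positive semi-definite) correlation structure.
#'
#' @name synthetic
NULL

# expected ordinal level of a latent N(mu, 1) cut at `cutpoints`
.expected_level <- function(mu, cutpoints) {
  1 + vapply(mu, function(m) sum(stats::pnorm(m - cutpoints)), numeric(1))
}

#' Latent shift producing a target expected level gap
#'
#' Solves for the latent mean shift whose expected ordinal level (under the
#' given cutpoints, baseline mean 0) exceeds the baseline expected level by
#' `gap`. With the default symmetric cutpoints and `gap = 1`, the shift is
#' about 1.086 latent standard deviations.
#'
#' @param gap Target gap in score levels.
#' @param cutpoints Strictly increasing latent cutpoints.
#' @return The latent shift (numeric scalar).
#' @examples
#' latent_shift_for_level_gap(1)
#' @export
latent_shift_for_level_gap <- function(gap = 1, cutpoints = c(-1.5, -0.5, 0.5, 1.5)) {
  stopifnot(gap > 0, gap < 4)
  base <- .expected_level(0, cutpoints)
  stats::uniroot(function(d) .expected_level(d, cutpoints) - base - gap,
                 interval = c(0, 10), tol = 1e-9)$root
}

#' Construct synthetic-generation parameters
#'
#' Defaults emulate the structure the instrument was designed around: two
#' groups of 30 fisheries (the scale of the initial cross-section), clearly
#' correlated metrics within a dimension (`rho_w = 0.6`), weaker coherence
#' across dimensions of an indicator (`rho_b = 0.3`), mild correlation across
#' indicators (`rho_x = 0.1`), a developed-vs-developing latent shift whose
#' expected gap is one score level, mostly confident quality ratings
#' (A 45%, B 35%, C 20%), and 5% missing scores.
#'
#' @param n_cases Cases per group (scalar, or named vector with entries
#'   `developed` and `developing`).
#' @param rho_w Within-dimension latent correlation, in `[0, 1)`.
#' @param rho_b Within-indicator (across-dimension) latent correlation.
#' @param rho_x Cross-indicator latent correlation. Must satisfy
#'   `rho_w >= rho_b >= rho_x >= 0`.
#' @param delta Latent mean shift added to the developed group; scalar, or a
#'   named vector keyed by dimension id for per-dimension shifts.
#' @param cutpoints Strictly increasing latent cutpoints mapping the real
#'   line to levels 1..5.
#' @param quality_probs Probabilities for quality labels `A`, `B`, `C`
#'   (sum to 1).
#' @param missing_rate Independent score knock-out probability, in `[0, 1)`.
#' @param seed Integer seed; the whole collection is reproducible from it.
#' @return An object of class `fpi_synth_params`.
#' @export
synthetic_params <- function(n_cases = 30, rho_w = 0.6, rho_b = 0.3,
                             rho_x = 0.1,
                             delta = latent_shift_for_level_gap(1),
                             cutpoints = c(-1.5, -0.5, 0.5, 1.5),
                             quality_probs = c(A = 0.45, B = 0.35, C = 0.20),
                             missing_rate = 0.05, seed = 1L) {
  if (length(n_cases) == 1L && is.null(names(n_cases))) {
    n_cases <- c(developed = as.integer(n_cases), developing = as.integer(n_cases))
  }
  stopifnot(all(c("developed", "developing") %in% names(n_cases)),
            all(n_cases >= 0))
  if (!(rho_w >= rho_b && rho_b >= rho_x && rho_x >= 0 && rho_w < 1)) {
    stop("need rho_w >= rho_b >= rho_x >= 0 and rho_w < 1 for a valid ",
         "(positive semi-definite) latent correlation structure", call. = FALSE)
  }
  if (length(cutpoints) != 4L || any(diff(cutpoints) <= 0)) {
    stop("cutpoints must be 4 strictly increasing values", call. = FALSE)
  }
  qp <- quality_probs[c("A", "B", "C")]
  if (anyNA(qp) || any(qp < 0) || abs(sum(qp) - 1) > 1e-8) {
    stop("quality_probs must be named non-negative probabilities for A, B, C ",
         "summing to 1", call. = FALSE)
  }
  stopifnot(missing_rate >= 0, missing_rate < 1)
  structure(list(n_cases = n_cases, rho_w = rho_w, rho_b = rho_b, rho_x = rho_x,
                 delta = delta, cutpoints = as.numeric(cutpoints),
                 quality_probs = qp, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "fpi_synth_params")
}

# block structure of metrics: dimension nested in indicator (outputs use the
# TBL partitioning, inputs the component hierarchy)
.metric_blocks <- function(s) {
  m <- s$metrics
  dim_id <- ifelse(m$side == "output", m$tbl_dimension, m$component_dimension)
  parent <- s$dimensions$parent[match(dim_id, s$dimensions$dimension_id)]
  list(metric_id = m$metric_id, dimension = dim_id, indicator = parent)
}

#' Generate a synthetic case collection
#'
#' @param params An `fpi_synth_params`.
#' @param s An `fpi_schema`; metrics and their dimension/indicator nesting are
#'   taken from it.
#' @return An `fpi_collection` with `sum(params$n_cases)` cases; the
#'   developed-group cases carry the latent shift.
#' @examples
#' cc <- generate(synthetic_params(n_cases = 3, seed = 42), fpi_schema())
#' length(cc)
#' @export
generate <- function(params, s = fpi_schema()) {
  stopifnot(inherits(params, "fpi_synth_params"), inherits(s, "fpi_schema"))
  set.seed(params$seed)
  blocks <- .metric_blocks(s)
  M <- length(blocks$metric_id)
  dims <- unique(blocks$dimension)
  inds <- unique(blocks$indicator)
  d_idx <- match(blocks$dimension, dims)
  k_idx <- match(blocks$indicator, inds)

  shift_for <- function(group) {
    if (group != "developed") return(numeric(M))
    if (length(params$delta) == 1L && is.null(names(params$delta))) {
      rep(as.numeric(params$delta), M)
    } else {
      dv <- params$delta[blocks$dimension]
      ifelse(is.na(dv), 0, as.numeric(dv))
    }
  }

  a_x <- sqrt(params$rho_x)
  a_b <- sqrt(params$rho_b - params$rho_x)
  a_w <- sqrt(params$rho_w - params$rho_b)
  a_e <- sqrt(1 - params$rho_w)

  cases <- list()
  counter <- 0L
  for (group in c("developing", "developed")) {
    n <- params$n_cases[[group]]
    if (n == 0L) next
    # latent: shared case factor + indicator factors + dimension factors + noise
    z_case <- stats::rnorm(n)
    z_ind <- matrix(stats::rnorm(n * length(inds)), n, length(inds))
    z_dim <- matrix(stats::rnorm(n * length(dims)), n, length(dims))
    eps <- matrix(stats::rnorm(n * M), n, M)
    latent <- a_x * z_case +
      a_b * z_ind[, k_idx, drop = FALSE] +
      a_w * z_dim[, d_idx, drop = FALSE] +
      a_e * eps
    latent <- sweep(latent, 2L, shift_for(group), `+`)
    level <- matrix(findInterval(latent, params$cutpoints) + 1L, n, M)
    quality <- matrix(sample(c("A", "B", "C"), n * M, replace = TRUE,
                             prob = params$quality_probs), n, M)
    if (params$missing_rate > 0) {
      knock <- matrix(stats::runif(n * M) < params$missing_rate, n, M)
      level[knock] <- NA_integer_
      quality[knock] <- NA_character_
    }
    for (i in seq_len(n)) {
      counter <- counter + 1L
      cases[[counter]] <- case_study(
        case_id = sprintf("synth_%03d", counter),
        fishery_name = sprintf("Synthetic fishery %03d", counter),
        country = "synthetic",
        base_year = 2015L,
        development_status = group,
        scores = data.frame(metric_id = blocks$metric_id,
                            level = level[i, ],
                            quality = quality[i, ],
                            stringsAsFactors = FALSE))
    }
  }
  fpi_collection(cases, provenance = sprintf("synthetic (seed %d)", params$seed),
                 schema_version = s$version)
}

#' Recover generator parameters from a collection
#'
#' Estimates, from an observed two-group collection, the per-dimension group
#' gap (difference of group mean dimension scores, developed minus
#' developing) and the mean within-dimension rank correlation (average
#' pairwise Spearman correlation of metric levels within each dimension,
#' complete pairs, averaged over dimensions with at least 2 metrics).
#'
#' @param cc An `fpi_collection` containing both groups.
#' @param s An `fpi_schema`.
#' @param partitioning Partitioning for the output dimensions (`"tbl"` by
#'   default); input dimensions are always included via the component
#'   hierarchy when `partitioning = "input"`.
#' @return List with `gap` (named numeric vector by dimension id) and
#'   `within_dimension_rho` (scalar).
#' @export
recover_parameters <- function(cc, s = fpi_schema(),
                               partitioning = c("tbl", "sector", "input")) {
  partitioning <- match.arg(partitioning)
  stopifnot(inherits(cc, "fpi_collection"))
  groups <- vapply(cc$cases, `[[`, character(1), "development_status")
  if (length(unique(groups)) < 2L) {
    stop("collection holds a single group; need both developed and developing",
         call. = FALSE)
  }
  gm <- group_dimension_means(cc$cases, s, uniform_weights(),
                              partitioning = partitioning)
  gap <- gm$developed - gm$developing
  names(gap) <- gm$dimension_id

  col <- .dimension_column(partitioning)
  dims <- s$dimensions$dimension_id[s$dimensions$partitioning == partitioning]
  # case x metric level matrix
  ids <- s$metrics$metric_id
  lv <- vapply(cc$cases, function(cs) {
    cs$scores$level[match(ids, cs$scores$metric_id)]
  }, integer(length(ids)))
  lv <- t(matrix(lv, nrow = length(ids)))  # cases x metrics
  colnames(lv) <- ids
  rhos <- c()
  for (d in dims) {
    mids <- ids[!is.na(s$metrics[[col]]) & s$metrics[[col]] == d]
    if (length(mids) < 2L) next
    sub <- lv[, mids, drop = FALSE]
    cm <- suppressWarnings(
      stats::cor(sub, use = "pairwise.complete.obs", method = "spearman"))
    vals <- cm[upper.tri(cm)]
    vals <- vals[!is.na(vals)]
    if (length(vals)) rhos <- c(rhos, mean(vals))
  }
  list(gap = gap, within_dimension_rho = if (length(rhos)) mean(rhos) else NA_real_)
}
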