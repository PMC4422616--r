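#' @title Instrument schema: load, validate, query
#'
#' @description The FPI instrument is data, not code: the full structure --
#' outcome metrics with their dual ("braided") dimension memberships, the
#' enabling-factor metrics under the input-component hierarchy, and the
#' dimension/indicator/component tables -- lives in a packaged YAML definition
#' file. All package functions consult a loaded [fpi_schema] object and never
#' hard-code metric lists.
#'
#' @name schema
NULL

# package-local cache for the default schema
.fpi_cache <- new.env(parent = emptyenv())

#' Path to the packaged default schema definition
#'
#' @return Path to the YAML file shipped with the package.
#' @export
fpi_default_schema_path <- function() {
  system.file("extdata", "fpi_schema.yaml", package = "fpitools", mustWork = TRUE)
}

#' Load an FPI schema definition
#'
#' Reads a structured-config (YAML) instrument definition and returns a
#' validated `fpi_schema` object. The definition file has top-level sections
#' `output_metrics`, `input_metrics`, `dimensions`, `indicators`, `components`
#' and optionally `scales` (reusable 5-level descriptor sets which are
#' expanded into each referencing metric).
#'
#' @param path Path to a schema YAML file; defaults to the packaged
#'   instrument definition.
#' @param validate If `TRUE` (default), stop when the loaded schema has
#'   structural violations.
#' @return An object of class `fpi_schema`: a list with elements `version`,
#'   `metrics` (data frame, one row per metric, columns `metric_id`, `name`,
#'   `side`, `tbl_dimension`, `sector_dimension`, `component_dimension`,
#'   `scale`, `notes`), `levels` (named list of 5-element character vectors of
#'   level descriptors), `dimensions`, `indicators`, `components` (data
#'   frames).
#' @examples
#' s <- load_schema()
#' table(s$metrics$side)
#' @export
load_schema <- function(path = fpi_default_schema_path(), validate = TRUE) {
  raw <- yaml::read_yaml(path)
  for (section in c("output_metrics", "input_metrics", "dimensions",
                    "indicators", "components")) {
    if (is.null(raw[[section]])) {
      stop("schema file lacks required section '", section, "'", call. = FALSE)
    }
  }
  scales <- lapply(raw$scales, function(sc) {
    vapply(as.character(1:5), function(k) {
      if (is.null(sc[[k]])) NA_character_ else as.character(sc[[k]])
    }, character(1))
  })

  mk_metric_row <- function(m, side) {
    data.frame(
      metric_id = as.character(m$id %||% NA_character_),
      name = as.character(m$name %||% m$id),
      side = side,
      tbl_dimension = as.character(m$tbl_dimension %||% NA_character_),
      sector_dimension = as.character(m$sector_dimension %||% NA_character_),
      component_dimension = as.character(m$component_dimension %||% NA_character_),
      scale = as.character(m$scale %||% NA_character_),
      notes = as.character(m$notes %||% ""),
      stringsAsFactors = FALSE
    )
  }
  out_rows <- lapply(raw$output_metrics, mk_metric_row, side = "output")
  in_rows <- lapply(raw$input_metrics, mk_metric_row, side = "input")
  metrics <- do.call(rbind, c(out_rows, in_rows))
  if (is.null(metrics)) {
    metrics <- data.frame(metric_id = character(), name = character(),
                          side = character(), tbl_dimension = character(),
                          sector_dimension = character(),
                          component_dimension = character(),
                          scale = character(), notes = character(),
                          stringsAsFactors = FALSE)
  }

  # expand level descriptors: inline `levels:` wins over a `scale:` reference
  all_defs <- c(raw$output_metrics, raw$input_metrics)
  levels <- list()
  for (m in all_defs) {
    id <- as.character(m$id)
    if (!is.null(m$levels)) {
      levels[[id]] <- vapply(as.character(1:5), function(k) {
        if (is.null(m$levels[[k]])) NA_character_ else as.character(m$levels[[k]])
      }, character(1))
    } else if (!is.null(m$scale) && !is.null(scales[[m$scale]])) {
      levels[[id]] <- scales[[m$scale]]
    } else {
      levels[[id]] <- rep(NA_character_, 5L)
    }
  }

  dimensions <- do.call(rbind, lapply(raw$dimensions, function(d) {
    data.frame(dimension_id = as.character(d$id), name = as.character(d$name %||% d$id),
               partitioning = as.character(d$partitioning),
               parent = as.character(d$parent), stringsAsFactors = FALSE)
  }))
  ind_rows <- list()
  for (part in names(raw$indicators)) {
    for (ind in raw$indicators[[part]]) {
      ind_rows[[length(ind_rows) + 1L]] <- data.frame(
        indicator_id = as.character(ind$id), name = as.character(ind$name %||% ind$id),
        partitioning = part, stringsAsFactors = FALSE)
    }
  }
  indicators <- do.call(rbind, ind_rows)
  components <- do.call(rbind, lapply(raw$components, function(cm) {
    data.frame(component_id = as.character(cm$id),
               name = as.character(cm$name %||% cm$id), stringsAsFactors = FALSE)
  }))

  s <- structure(
    list(version = as.character(raw$version %||% "unversioned"),
         metrics = metrics, levels = levels, dimensions = dimensions,
         indicators = indicators, components = components),
    class = "fpi_schema")

  if (anyDuplicated(metrics$metric_id)) {
    stop("duplicate metric_id in schema file: ",
         paste(unique(metrics$metric_id[duplicated(metrics$metric_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (validate) {
    rep <- validate_schema(s)
    if (nrow(rep) > 0L) {
      stop("schema failed validation:\n",
           paste0("  - ", rep$message, collapse = "\n"), call. = FALSE)
    }
  }
  s
}

#' The packaged default FPI schema
#'
#' Convenience accessor; loads the packaged definition once per session and
#' caches it.
#'
#' @return An `fpi_schema` object (68 outcome metrics, 54 enabling-factor
#'   metrics).
#' @export
fpi_schema <- function() {
  if (is.null(.fpi_cache$default_schema)) {
    .fpi_cache$default_schema <- load_schema()
  }
  .fpi_cache$default_schema
}

.violation <- function(code, id, message) {
  data.frame(code = code, id = id, message = message, stringsAsFactors = FALSE)
}

#' Validate an FPI schema
#'
#' Checks every structural invariant of the instrument: metric totals (68
#' outcome, 54 enabling-factor), 15 input dimensions over 5 components with
#' the stated component membership, the fixed TBL dimension lists, per-metric
#' side/dimension consistency, exactly five level descriptors per metric,
#' resolvable parent references, and the partition property (each outcome
#' metric placed in exactly one dimension under each of the two
#' partitionings).
#'
#' Violations are data, not exceptions: the return value is a data frame with
#' one row per violation (columns `code`, `id`, `message`); an empty frame
#' means the schema is valid.
#'
#' @param s An `fpi_schema` object.
#' @return A data frame of class `fpi_validation`.
#' @examples
#' nrow(validate_schema(fpi_schema()))  # 0
#' @export
validate_schema <- function(s) {
  stopifnot(inherits(s, "fpi_schema"))
  v <- list()
  add <- function(...) v[[length(v) + 1L]] <<- .violation(...)
  m <- s$metrics

  if (nrow(m) == 0L) {
    add("no_metrics", NA_character_, "no metrics")
    return(.finish_validation(v))
  }
  dup <- unique(m$metric_id[duplicated(m$metric_id)])
  for (id in dup) add("duplicate_metric", id, paste0("duplicate metric_id '", id, "'"))

  n_out <- sum(m$side == "output")
  n_in <- sum(m$side == "input")
  if (n_out != 68L)
    add("output_count", NA_character_, paste0("output metric count != 68 (got ", n_out, ")"))
  if (n_in != 54L)
    add("input_count", NA_character_, paste0("input metric count != 54 (got ", n_in, ")"))

  d <- s$dimensions
  n_indim <- sum(d$partitioning == "input")
  if (n_indim != 15L)
    add("input_dimension_count", NA_character_,
        paste0("input dimension count != 15 (got ", n_indim, ")"))
  if (nrow(s$components) != 5L)
    add("component_count", NA_character_,
        paste0("input component count != 5 (got ", nrow(s$components), ")"))

  # stated component -> input-dimension membership (by dimension name)
  comp_map <- list(
    "Macro Factors" = c("General Environmental Performance",
                        "Exogenous Environmental Factors", "Governance",
                        "Economic Conditions"),
    "Property Rights & Responsibility" = c("Fishing Access Rights", "Harvest Rights"),
    "Co-management" = c("Collective Action", "Participation", "Community", "Gender"),
    "Management" = c("Management Inputs", "Data", "Management Methods"),
    "Post-Harvest" = c("Markets & Market Institutions", "Infrastructure"))
  for (comp_name in names(comp_map)) {
    cid <- s$components$component_id[s$components$name == comp_name]
    if (length(cid) != 1L) {
      add("missing_component", comp_name, paste0("component '", comp_name, "' absent"))
      next
    }
    have <- sort(d$name[d$partitioning == "input" & d$parent == cid])
    want <- sort(comp_map[[comp_name]])
    if (!identical(have, want)) {
      add("component_dimensions", cid,
          paste0("component '", comp_name, "' dimensions {",
                 paste(have, collapse = ", "), "} != {",
                 paste(want, collapse = ", "), "}"))
    }
  }

  # fixed TBL dimension lists
  tbl_map <- list(
    Ecology = "Ecology",
    Economics = c("Harvest", "Harvest Assets", "Post-Harvest Assets", "Risk",
                  "Trade", "Product Form"),
    Community = c("Managerial Returns", "Labor Returns", "Health and Sanitation",
                  "Community Support Services", "Local Ownership", "Local Labor",
                  "Career"))
  for (ind_name in names(tbl_map)) {
    iid <- s$indicators$indicator_id[s$indicators$name == ind_name &
                                       s$indicators$partitioning == "tbl"]
    if (length(iid) != 1L) {
      add("missing_indicator", ind_name, paste0("TBL indicator '", ind_name, "' absent"))
      next
    }
    have <- sort(d$name[d$partitioning == "tbl" & d$parent == iid])
    want <- sort(tbl_map[[ind_name]])
    if (!identical(have, want)) {
      add("tbl_dimensions", iid,
          paste0("TBL indicator '", ind_name, "' dimensions {",
                 paste(have, collapse = ", "), "} != {",
                 paste(want, collapse = ", "), "}"))
    }
  }

  # dimension parents resolve within their partitioning
  for (i in seq_len(nrow(d))) {
    ok <- if (d$partitioning[i] == "input") {
      d$parent[i] %in% s$components$component_id
    } else {
      d$parent[i] %in% s$indicators$indicator_id[
        s$indicators$partitioning == d$partitioning[i]]
    }
    if (!ok) add("dangling_parent", d$dimension_id[i],
                 paste0("dimension '", d$dimension_id[i],
                        "' parent '", d$parent[i], "' unresolved"))
  }

  # per-metric side/dimension consistency and resolvable dimension refs
  dim_ids <- function(part) d$dimension_id[d$partitioning == part]
  for (i in seq_len(nrow(m))) {
    id <- m$metric_id[i]
    if (m$side[i] == "output") {
      if (is.na(m$tbl_dimension[i]))
        add("missing_tbl_dimension", id,
            paste0("output metric '", id, "' lacks tbl_dimension"))
      else if (!m$tbl_dimension[i] %in% dim_ids("tbl"))
        add("dangling_dimension", id,
            paste0("output metric '", id, "' tbl_dimension '",
                   m$tbl_dimension[i], "' unresolved"))
      if (is.na(m$sector_dimension[i]))
        add("missing_sector_dimension", id,
            paste0("output metric '", id, "' lacks sector_dimension"))
      else if (!m$sector_dimension[i] %in% dim_ids("sector"))
        add("dangling_dimension", id,
            paste0("output metric '", id, "' sector_dimension '",
                   m$sector_dimension[i], "' unresolved"))
      if (!is.na(m$component_dimension[i]))
        add("spurious_component_dimension", id,
            paste0("output metric '", id, "' carries component_dimension"))
    } else {
      if (is.na(m$component_dimension[i]))
        add("missing_component_dimension", id,
            paste0("input metric '", id, "' lacks component_dimension"))
      else if (!m$component_dimension[i] %in% dim_ids("input"))
        add("dangling_dimension", id,
            paste0("input metric '", id, "' component_dimension '",
                   m$component_dimension[i], "' unresolved"))
      if (!is.na(m$tbl_dimension[i]) || !is.na(m$sector_dimension[i]))
        add("spurious_output_dimension", id,
            paste0("input metric '", id, "' carries an output partitioning dimension"))
    }
    lv <- s$levels[[id]]
    if (is.null(lv) || length(lv) != 5L || anyNA(lv))
      add("level_descriptors", id,
          paste0("metric '", id, "' lacks exactly 5 level descriptors keyed 1..5"))
  }
  .finish_validation(v)
}

.finish_validation <- function(v) {
  out <- if (length(v)) do.call(rbind, v) else
    data.frame(code = character(), id = character(), message = character(),
               stringsAsFactors = FALSE)
  class(out) <- c("fpi_validation", "data.frame")
  out
}

#' @export
print.fpi_validation <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("No violations: valid.\n")
  } else {
    cat(nrow(x), "violation(s):\n")
    for (i in seq_len(nrow(x))) cat("  -", x$message[i], "\n")
  }
  invisible(x)
}

#' Metrics under a schema node
#'
#' Returns the transitive set of metrics belonging to a dimension, an
#' indicator, or an input component under the given partitioning. For an
#' indicator (or component), the result is the union of its dimensions'
#' metric sets, without duplicates.
#'
#' @param s An `fpi_schema`.
#' @param node_id A dimension, indicator, or component id.
#' @param partitioning One of `"tbl"`, `"sector"`, `"input"`.
#' @return The rows of `s$metrics` for the node's metrics.
#' @examples
#' nrow(metrics_of(fpi_schema(), "economics", "tbl"))
#' @export
metrics_of <- function(s, node_id, partitioning = c("tbl", "sector", "input")) {
  stopifnot(inherits(s, "fpi_schema"))
  partitioning <- match.arg(partitioning)
  d <- s$dimensions[s$dimensions$partitioning == partitioning, , drop = FALSE]
  col <- switch(partitioning, tbl = "tbl_dimension", sector = "sector_dimension",
                input = "component_dimension")
  if (node_id %in% d$dimension_id) {
    dims <- node_id
  } else {
    parents_ok <- if (partitioning == "input") {
      node_id %in% s$components$component_id
    } else {
      node_id %in% s$indicators$indicator_id[s$indicators$partitioning == partitioning]
    }
    if (!parents_ok) {
      stop("unknown node_id '", node_id, "' in partitioning '", partitioning, "'",
           call. = FALSE)
    }
    dims <- d$dimension_id[d$parent == node_id]
  }
  out <- s$metrics[!is.na(s$metrics[[col]]) & s$metrics[[col]] %in% dims, ,
                   drop = FALSE]
  out[!duplicated(out$metric_id), , drop = FALSE]
}

#' Write a schema definition file
#'
#' Serializes an `fpi_schema` back to the structured-config (YAML) layout read
#' by [load_schema()]. Level descriptors are written inline per metric, so
#' `load_schema(write_schema(s))` is structurally identical to `s` up to
#' scale-reference expansion.
#'
#' @param s An `fpi_schema`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(s, path) {
  stopifnot(inherits(s, "fpi_schema"))
  metric_entry <- function(i) {
    m <- s$metrics[i, ]
    e <- list(id = m$metric_id, name = m$name)
    if (m$side == "output") {
      e$tbl_dimension <- m$tbl_dimension
      e$sector_dimension <- m$sector_dimension
    } else {
      e$component_dimension <- m$component_dimension
    }
    lv <- s$levels[[m$metric_id]]
    e$levels <- stats::setNames(as.list(lv), as.character(1:5))
    if (nzchar(m$notes)) e$notes <- m$notes
    e
  }
  out_idx <- which(s$metrics$side == "output")
  in_idx <- which(s$metrics$side == "input")
  doc <- list(
    version = s$version,
    indicators = stats::setNames(lapply(unique(s$indicators$partitioning), function(p) {
      df <- s$indicators[s$indicators$partitioning == p, , drop = FALSE]
      lapply(seq_len(nrow(df)), function(i)
        list(id = df$indicator_id[i], name = df$name[i]))
    }), unique(s$indicators$partitioning)),
    components = lapply(seq_len(nrow(s$components)), function(i)
      list(id = s$components$component_id[i], name = s$components$name[i])),
    dimensions = lapply(seq_len(nrow(s$dimensions)), function(i)
      list(id = s$dimensions$dimension_id[i], name = s$dimensions$name[i],
           partitioning = s$dimensions$partitioning[i],
           parent = s$dimensions$parent[i])),
    output_metrics = lapply(out_idx, metric_entry),
    input_metrics = lapply(in_idx, metric_entry))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @export
print.fpi_schema <- function(x, ...) {
  cat("FPI instrument schema (version ", x$version, ")\n", sep = "")
  cat("  outcome metrics: ", sum(x$metrics$side == "output"),
      "  enabling-factor metrics: ", sum(x$metrics$side == "input"), "\n", sep = "")
  for (part in c("tbl", "sector", "input")) {
    cat("  ", part, " dimensions: ",
        sum(x$dimensions$partitioning == part), "\n", sep = "")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
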