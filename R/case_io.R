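#' @title Case-study input/output
#'
#' @description Hand-scored instruments arrive as one worksheet per fishery:
#' a comma-delimited score sheet (`metric_id,level,quality`, missing token
#' `NA`) plus a structured-config metadata sidecar. Multi-case collections
#' travel as a single long-format delimited file plus one metadata sidecar.
#' All text is UTF-8 with `.` as decimal point; ordering is deterministic
#' (case id, then schema metric order) so write/read round-trips are stable.
#'
#' @name case_io
NULL

#' Construct a case collection
#'
#' @param cases List of `fpi_case` with unique case ids.
#' @param provenance Free-text provenance note.
#' @param schema_version Version tag of the schema the cases were scored
#'   against.
#' @return An object of class `fpi_collection`.
#' @export
fpi_collection <- function(cases, provenance = "",
                           schema_version = fpi_schema()$version) {
  stopifnot(is.list(cases), all(vapply(cases, inherits, logical(1), "fpi_case")))
  ids <- vapply(cases, `[[`, character(1), "case_id")
  if (anyDuplicated(ids)) {
    stop("duplicate case_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(cases = cases, provenance = as.character(provenance),
                 schema_version = as.character(schema_version)),
            class = "fpi_collection")
}

#' @export
print.fpi_collection <- function(x, ...) {
  cat("FPI case collection: ", length(x$cases), " case(s), schema version ",
      x$schema_version, "\n", sep = "")
  invisible(x)
}

#' @export
length.fpi_collection <- function(x) length(x$cases)

#' Read one case study from a score sheet and metadata sidecar
#'
#' The sheet is delimited text with header `metric_id,level,quality` and
#' missing token `NA`; the sidecar is structured-config (YAML) with fields
#' `case_id`, `fishery_name`, `country`, `base_year`, `development_status`.
#' Unknown metric ids are never silently dropped: strict mode stops and lists
#' them, lenient mode warns and keeps them (they surface again in
#' [validate_case()]).
#'
#' @param sheet_path Path to the score sheet.
#' @param metadata_path Path to the metadata sidecar.
#' @param s An `fpi_schema`.
#' @param strict Stop (default) or warn on validation violations.
#' @return A validated `fpi_case`.
#' @export
read_case <- function(sheet_path, metadata_path, s = fpi_schema(), strict = TRUE) {
  sheet <- utils::read.csv(sheet_path, stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "character"),
                           na.strings = "NA", fileEncoding = "UTF-8")
  if (!all(c("metric_id", "level", "quality") %in% names(sheet))) {
    stop("score sheet must have header metric_id,level,quality", call. = FALSE)
  }
  meta <- yaml::read_yaml(metadata_path)
  for (f in c("case_id", "fishery_name", "country", "base_year",
              "development_status")) {
    if (is.null(meta[[f]])) stop("metadata lacks field '", f, "'", call. = FALSE)
  }
  cs <- case_study(meta$case_id, meta$fishery_name, meta$country,
                   meta$base_year, meta$development_status, sheet)
  rep <- validate_case(cs, s)
  if (nrow(rep) > 0L) {
    msg <- paste0("case '", cs$case_id, "' has ", nrow(rep), " violation(s): ",
                  paste(rep$message, collapse = "; "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  cs
}

#' Write one case study as a score sheet and metadata sidecar
#'
#' Metrics are written in schema order; metrics absent from the case are
#' omitted.
#'
#' @param case An `fpi_case`.
#' @param sheet_path,metadata_path Output paths.
#' @param s An `fpi_schema` (for the deterministic metric order).
#' @return `sheet_path`, invisibly.
#' @export
write_case <- function(case, sheet_path, metadata_path, s = fpi_schema()) {
  stopifnot(inherits(case, "fpi_case"))
  sc <- case$scores
  ord <- order(match(sc$metric_id, s$metrics$metric_id))
  utils::write.csv(sc[ord, , drop = FALSE], sheet_path, row.names = FALSE,
                   quote = FALSE, na = "NA", fileEncoding = "UTF-8")
  yaml::write_yaml(list(case_id = case$case_id,
                        fishery_name = case$fishery_name,
                        country = case$country,
                        base_year = case$base_year,
                        development_status = case$development_status),
                   metadata_path)
  invisible(sheet_path)
}

.collection_meta_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_meta.yaml")
}

#' Write a case collection as long-format delimited text
#'
#' Writes `case_id,metric_id,level,quality` rows (cases sorted by id, metrics
#' in schema order) to `path`, and all case metadata plus provenance and
#' schema version to a structured-config sidecar next to it
#' (`<path-sans-ext>_meta.yaml`). `read_collection(write_collection(cc))` is
#' the identity on validated collections.
#'
#' @param cc An `fpi_collection`.
#' @param path Output path for the long-format file.
#' @param s An `fpi_schema`.
#' @return `path`, invisibly.
#' @export
write_collection <- function(cc, path, s = fpi_schema()) {
  stopifnot(inherits(cc, "fpi_collection"))
  ids <- vapply(cc$cases, `[[`, character(1), "case_id")
  rows <- lapply(cc$cases[order(ids)], function(cs) {
    sc <- cs$scores
    ord <- order(match(sc$metric_id, s$metrics$metric_id))
    sc <- sc[ord, , drop = FALSE]
    if (nrow(sc) == 0L) return(NULL)
    cbind(data.frame(case_id = cs$case_id, stringsAsFactors = FALSE), sc)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = character(), metric_id = character(),
               level = integer(), quality = character(), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA",
                   fileEncoding = "UTF-8")
  meta <- list(provenance = cc$provenance, schema_version = cc$schema_version,
               cases = lapply(cc$cases[order(ids)], function(cs)
                 list(case_id = cs$case_id, fishery_name = cs$fishery_name,
                      country = cs$country, base_year = cs$base_year,
                      development_status = cs$development_status)))
  yaml::write_yaml(meta, .collection_meta_path(path))
  invisible(path)
}

#' Read a case collection from long-format delimited text
#'
#' @param path Path written by [write_collection()] (the metadata sidecar is
#'   found next to it).
#' @param s An `fpi_schema`; each case is validated against it.
#' @param strict Stop (default) or warn on case validation violations.
#' @return An `fpi_collection`.
#' @export
read_collection <- function(path, s = fpi_schema(), strict = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "integer",
                                       "character"),
                        na.strings = "NA", fileEncoding = "UTF-8")
  meta <- yaml::read_yaml(.collection_meta_path(path))
  if (!is.null(meta$schema_version) &&
      !identical(as.character(meta$schema_version), s$version)) {
    warning("collection was scored against schema version '",
            meta$schema_version, "' but schema is version '", s$version, "'",
            call. = FALSE)
  }
  meta_ids <- vapply(meta$cases, function(m) as.character(m$case_id), character(1))
  if (anyDuplicated(meta_ids)) {
    stop("duplicate case_id in collection metadata: ",
         paste(unique(meta_ids[duplicated(meta_ids)]), collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(unique(df$case_id), meta_ids)
  if (length(extra)) {
    stop("score rows for case(s) absent from metadata: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  cases <- lapply(meta$cases, function(m) {
    sub <- df[df$case_id == m$case_id, c("metric_id", "level", "quality"),
              drop = FALSE]
    cs <- case_study(m$case_id, m$fishery_name, m$country, m$base_year,
                     m$development_status, sub)
    rep <- validate_case(cs, s)
    if (nrow(rep) > 0L) {
      msg <- paste0("case '", cs$case_id, "' has ", nrow(rep),
                    " violation(s): ", paste(rep$message, collapse = "; "))
      if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
    cs
  })
  fpi_collection(cases, provenance = meta$provenance %||% "",
                 schema_version = as.character(meta$schema_version %||% s$version))
}
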