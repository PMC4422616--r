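#' @title Report rendering
#' @name report
NULL

.heatmap_wide <- function(table, node_level) {
  sub <- table[table$node_level == node_level, , drop = FALSE]
  nodes <- unique(sub$node_id)
  cases <- unique(table$case_id)
  wide <- matrix(NA_real_, nrow = length(cases), ncol = length(nodes),
                 dimnames = list(cases, nodes))
  wide[cbind(match(sub$case_id, cases), match(sub$node_id, nodes))] <- sub$score
  wide
}

#' Render a score table as a heatmap-style report
#'
#' Cases form rows, sorted descending by their score on `sort_node` (ties
#' broken by case id, missing sort scores last); indicator and dimension
#' scores form columns, each cell carrying the score and its traffic-light
#' color bin. Output is deterministic: identical inputs give byte-identical
#' artifacts. The text format encodes the bin as a letter suffix
#' (`g`/`y`/`r`); the HTML format is a single self-contained file using
#' inline styles only.
#'
#' @param table An `fpi_score_table`.
#' @param sort_node Node id to sort cases by.
#' @param format `"text"` or `"html"`.
#' @param bins Color cutpoints, as in [color_bin()].
#' @return A character scalar (the rendered artifact).
#' @export
render_heatmap_table <- function(table, sort_node, format = c("text", "html"),
                                 bins = c(3, 4)) {
  format <- match.arg(format)
  stopifnot(inherits(table, "fpi_score_table"))
  if (!sort_node %in% table$node_id) {
    stop("unknown sort node '", sort_node, "'", call. = FALSE)
  }
  ind <- .heatmap_wide(table, "indicator")
  dim <- .heatmap_wide(table, "dimension")
  wide <- cbind(ind, dim)
  key <- wide[, sort_node]
  ord <- order(-ifelse(is.na(key), -Inf, key), rownames(wide))
  wide <- wide[ord, , drop = FALSE]

  cell_txt <- function(x) {
    if (is.na(x)) return("   .  ")
    sprintf("%4.2f %s", x, substr(color_bin(x, bins), 1, 1))
  }
  if (format == "text") {
    colw <- max(nchar(colnames(wide)), 6L)
    idw <- max(nchar(rownames(wide)), nchar("case_id"))
    header <- paste0(formatC("case_id", width = idw), " | ",
                     paste(formatC(colnames(wide), width = colw),
                           collapse = " | "))
    lines <- vapply(seq_len(nrow(wide)), function(i) {
      paste0(formatC(rownames(wide)[i], width = idw), " | ",
             paste(formatC(vapply(wide[i, ], cell_txt, character(1)),
                           width = colw), collapse = " | "))
    }, character(1))
    paste(c(header, strrep("-", nchar(header)), lines, ""), collapse = "\n")
  } else {
    css <- c(red = "background-color:#e06666", yellow = "background-color:#ffd966",
             green = "background-color:#93c47d")
    cell_html <- function(x) {
      if (is.na(x)) return("<td></td>")
      sprintf("<td style=\"%s\">%.2f</td>", css[[color_bin(x, bins)]], x)
    }
    rows <- vapply(seq_len(nrow(wide)), function(i) {
      paste0("<tr><td>", rownames(wide)[i], "</td>",
             paste(vapply(wide[i, ], cell_html, character(1)), collapse = ""),
             "</tr>")
    }, character(1))
    paste0("<html><body><table style=\"border-collapse:collapse\">\n",
           "<tr><th>case_id</th>",
           paste0("<th>", colnames(wide), "</th>", collapse = ""),
           "</tr>\n", paste(rows, collapse = "\n"),
           "\n</table></body></html>\n")
  }
}
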