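# shared fixtures, all built in code

fpi_s <- fpi_schema()

# a case scoring every metric in the schema
make_full_case <- function(case_id = "full", level = 3L, quality = "A",
                           status = "developed") {
  m <- fpi_s$metrics$metric_id
  case_study(case_id, paste("Fishery", case_id), "Testland", 2015L, status,
             data.frame(metric_id = m,
                        level = rep_len(level, length(m)),
                        quality = rep_len(quality, length(m)),
                        stringsAsFactors = FALSE))
}

# a case scoring only the given metrics
make_case <- function(case_id, metric_id, level, quality = NA_character_,
                      status = "developed") {
  case_study(case_id, paste("Fishery", case_id), "Testland", 2015L, status,
             data.frame(metric_id = metric_id, level = level,
                        quality = rep_len(quality, length(metric_id)),
                        stringsAsFactors = FALSE))
}

# independent exact two-sided rank-sum p-value from the Mann-Whitney U
# distribution (stats::pwilcox), for use as an oracle against the package's
# enumeration-based implementation
oracle_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  u <- sum(rank(c(x, y))[seq_len(n1)]) - n1 * (n1 + 1) / 2
  lower <- stats::pwilcox(u, n1, n2)
  upper <- 1 - stats::pwilcox(u - 1, n1, n2)
  min(1, 2 * min(lower, upper, 0.5))
}
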