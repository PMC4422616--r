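s <- fpi_s
labor <- s$metrics$metric_id[!is.na(s$metrics$tbl_dimension) &
                               s$metrics$tbl_dimension == "labor_returns"]

test_that("dimension score is the (quality-weighted) mean of scored levels", {
  cs <- make_case("a", labor[1:3], c(3L, 4L, 5L), quality = "A")
  expect_equal(as.numeric(dimension_score(cs, "labor_returns", s)), 4)

  cs <- make_case("b", labor[1:3], c(4L, 4L, 4L), quality = c("A", "B", "C"))
  expect_equal(as.numeric(dimension_score(cs, "labor_returns", s,
                                          weighting_scheme())), 4)

  # hand-computed weighted-mean oracle: (2*1 + 4*0.3) / 1.3
  cs <- make_case("c", labor[1:2], c(2L, 4L), quality = c("A", "C"))
  w <- weighting_scheme(quality_weights = c(A = 1, B = 0.6, C = 0.3))
  expect_equal(as.numeric(dimension_score(cs, "labor_returns", s, w)),
               (2 * 1 + 4 * 0.3) / 1.3, tolerance = 1e-12)

  expect_error(dimension_score(cs, "no_such_dim", s), "unknown dimension")
})

test_that("unscored dimensions are missing; low coverage flags, never drops", {
  cs <- make_case("a", labor[1], 4L)
  expect_true(is.na(dimension_score(cs, "ecological_status", s)))
  d <- dimension_score(cs, "labor_returns", s)  # 1 of 6 scored
  expect_equal(as.numeric(d), 4)
  expect_equal(attr(d, "coverage"), 1 / 6)
  expect_true(attr(d, "flagged"))
})

test_that("indicator scores follow the configured aggregation method", {
  # dimensions scoring {3, 5} average to 4 under dimension_mean
  harvest <- s$metrics$metric_id[!is.na(s$metrics$tbl_dimension) &
                                   s$metrics$tbl_dimension == "harvest"]
  risk <- s$metrics$metric_id[!is.na(s$metrics$tbl_dimension) &
                                s$metrics$tbl_dimension == "risk"]
  cs <- make_case("a", c(harvest, risk),
                  c(rep(3L, length(harvest)), rep(5L, length(risk))))
  expect_equal(indicator_score(cs, "economics", "tbl", s), 4)

  # the single-dimension Ecology indicator equals its dimension score
  eco <- metrics_of(s, "ecology", "tbl")$metric_id
  cs <- make_case("b", eco, rep_len(c(2L, 4L), length(eco)))
  expect_equal(indicator_score(cs, "ecology", "tbl", s),
               as.numeric(dimension_score(cs, "ecological_status", s)))

  expect_error(indicator_score(cs, "economics", "sector", s), "unknown indicator")
})

test_that("metric_mean matches a flat-average oracle and differs from dimension_mean", {
  set.seed(21)
  cs <- make_full_case(level = sample(1:5, 122, replace = TRUE))
  w_flat <- weighting_scheme(quality_weights = c(A = 1, B = 1, C = 1),
                             indicator_method = "metric_mean")
  ids <- metrics_of(s, "community", "tbl")$metric_id
  oracle <- mean(cs$scores$level[match(ids, cs$scores$metric_id)])
  expect_equal(indicator_score(cs, "community", "tbl", s, w_flat), oracle)
  # dimension sizes differ within Community, so the two methods disagree
  expect_false(isTRUE(all.equal(
    indicator_score(cs, "community", "tbl", s, w_flat),
    indicator_score(cs, "community", "tbl", s, uniform_weights(
      indicator_method = "dimension_mean")))))
})

test_that("color bins anchor 3 as the improvement threshold", {
  expect_identical(color_bin(2.9), "red")
  expect_identical(color_bin(3.0), "yellow")
  expect_identical(color_bin(3.999), "yellow")
  expect_identical(color_bin(c(4, 5)), c("green", "green"))
  expect_true(is.na(color_bin(NA_real_)))
  expect_error(color_bin(5.2), "\\[1, 5\\]")
})

test_that("aggregates respect weighted-mean containment and permutation invariance", {
  set.seed(31)
  for (rep_i in 1:20) {
    k <- sample(2:6, 1)
    cs <- make_case("p", labor[1:k], sample(1:5, k, replace = TRUE),
                    quality = sample(c("A", "B", "C"), k, replace = TRUE))
    w <- weighting_scheme()
    d <- as.numeric(dimension_score(cs, "labor_returns", s, w))
    lv <- cs$scores$level
    expect_gte(d, min(lv)); expect_lte(d, max(lv))
    # permute the sheet rows
    perm <- cs
    ord <- sample(nrow(perm$scores))
    perm$scores <- perm$scores[ord, ]
    expect_equal(as.numeric(dimension_score(perm, "labor_returns", s, w)), d)
  }
})

test_that("removing a metric at the current dimension score leaves it unchanged", {
  cs <- make_case("m", labor[1:3], c(2L, 4L, 3L))  # mean 3
  d0 <- as.numeric(dimension_score(cs, "labor_returns", s))
  cs2 <- make_case("m", labor[1:2], c(2L, 4L))
  expect_equal(as.numeric(dimension_score(cs2, "labor_returns", s)), d0)
})

test_that("score_all builds a bounded, deterministic long table", {
  cc <- generate(synthetic_params(n_cases = 1, missing_rate = 0, seed = 5), s)
  tab <- score_all(cc, s, uniform_weights(), "tbl")
  # 1 case per group, 3 indicators + 14 dimensions each
  expect_identical(nrow(tab), 2L * (3L + 14L))
  expect_true(all(tab$score >= 1 & tab$score <= 5, na.rm = TRUE))
  expect_identical(tab, score_all(cc, s, uniform_weights(), "tbl"))

  empty <- score_all(list(), s, uniform_weights(), "tbl")
  expect_identical(nrow(empty), 0L)
})

test_that("uniform quality weights reproduce unweighted scores exactly", {
  cc <- generate(synthetic_params(n_cases = 4, seed = 9), s)
  flat <- weighting_scheme(quality_weights = c(A = 1, B = 1, C = 1))
  t1 <- score_all(cc, s, uniform_weights(), "tbl")
  t2 <- score_all(cc, s, flat, "tbl")
  expect_identical(t1$score, t2$score)
})
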