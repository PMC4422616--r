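s <- fpi_s

# small score table built directly from full cases with chosen Ecology levels
eco_ids <- metrics_of(s, "ecology", "tbl")$metric_id
table_from_levels <- function(levels_by_case) {
  cases <- lapply(names(levels_by_case), function(id) {
    make_case(id, eco_ids, rep(levels_by_case[[id]], length(eco_ids)))
  })
  score_all(cases, s, uniform_weights(), "tbl")
}

test_that("rank_cases orders descending with average ranks over ties", {
  tab <- table_from_levels(list(A = 5L, B = 3L, C = 4L))
  r <- rank_cases(tab, "ecology")
  expect_identical(r$ranking$case_id, c("A", "C", "B"))
  expect_identical(r$ranking$rank, c(1, 2, 3))
  expect_equal(sum(r$ranking$rank), 3 * 4 / 2)

  tab <- table_from_levels(list(A = 4L, B = 4L))
  r <- rank_cases(tab, "ecology")
  expect_identical(r$ranking$rank, c(1.5, 1.5))

  # all missing on a node -> empty ranking, exclusion list
  cs <- list(make_case("A", eco_ids, rep(3L, length(eco_ids))))
  tab <- score_all(cs, s, uniform_weights(), "tbl")
  r <- rank_cases(tab, "harvest")
  expect_identical(nrow(r$ranking), 0L)
  expect_identical(r$excluded, "A")
  expect_error(rank_cases(tab, "nonesuch"), "unknown node")
})

test_that("rank-sum worked examples match enumeration", {
  r <- rank_sum_test(c(1, 2), c(3, 4))
  expect_identical(r$W, 3)
  expect_identical(r$U, 0)
  expect_equal(r$p_two_sided, 1 / 3)
  expect_identical(r$method, "exact")

  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_identical(r$U, 0)
  expect_equal(r$p_two_sided, 2 / choose(6, 3))

  # identical samples in the approximation branch give p ~= 1
  x <- rep(1:6, 3)
  r <- rank_sum_test(x, x)
  expect_identical(r$method, "normal_approx")
  expect_gte(r$p_two_sided, 0.95)

  expect_error(rank_sum_test(numeric(0), 1), "empty sample")
})

test_that("U = W - n1(n1+1)/2 and 0 <= U <= n1 n2 across random inputs", {
  set.seed(41)
  for (i in 1:50) {
    n1 <- sample(1:12, 1); n2 <- sample(1:12, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    r <- rank_sum_test(x, y)
    expect_equal(r$U, r$W - n1 * (n1 + 1) / 2)
    expect_gte(r$U, 0); expect_lte(r$U, n1 * n2)
    expect_gt(r$p_two_sided, 0); expect_lte(r$p_two_sided, 1)
  }
})

test_that("exact p agrees with the Mann-Whitney distribution oracle for all n1,n2 <= 6", {
  set.seed(42)
  for (n1 in 1:6) {
    for (n2 in 1:6) {
      for (rep_i in 1:3) {
        x <- rnorm(n1); y <- rnorm(n2)  # continuous: no ties
        r <- rank_sum_test(x, y)
        expect_identical(r$method, "exact")
        expect_equal(r$p_two_sided, oracle_exact_p(x, y), tolerance = 1e-12,
                     info = sprintf("n1=%d n2=%d", n1, n2))
      }
    }
  }
})

test_that("ties fall back to the tie-corrected approximation, matching wilcox.test", {
  set.seed(43)
  for (i in 1:20) {
    x <- sample(1:4, 8, replace = TRUE)
    y <- sample(1:4, 9, replace = TRUE)
    r <- rank_sum_test(x, y)
    expect_identical(r$method, "normal_approx")
    w <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(r$p_two_sided, w$p.value, tolerance = 1e-8)
  }
})

test_that("Spearman rho handles identity, reversal, swaps, and monotone maps", {
  tab <- table_from_levels(list(A = 5L, B = 4L, C = 3L, D = 2L))
  r1 <- rank_cases(tab, "ecology")
  expect_equal(rank_correlation(r1, r1), 1)

  rev_tab <- table_from_levels(list(A = 2L, B = 3L, C = 4L, D = 5L))
  r2 <- rank_cases(rev_tab, "ecology")
  expect_equal(rank_correlation(r1, r2), -1)

  # one adjacent swap among 4 cases: rho = 1 - 6*2/(4*15) = 0.8
  swap_tab <- table_from_levels(list(A = 5L, B = 4L, C = 2L, D = 3L))
  r3 <- rank_cases(swap_tab, "ecology")
  expect_equal(rank_correlation(r1, r3), 0.8)

  # invariance under strictly monotone transforms of the scores
  sc <- c(A = 1.2, B = 2.5, C = 3.1, D = 4.9)
  mk_rank <- function(v) {
    tabv <- table_from_levels(list(A = 5L, B = 4L, C = 3L, D = 2L))
    tabv$score[tabv$node_id == "ecology"] <-
      v[match(tabv$case_id[tabv$node_id == "ecology"], names(v))]
    rank_cases(tabv, "ecology")
  }
  expect_equal(rank_correlation(mk_rank(sc), mk_rank(exp(sc))), 1)

  bad <- rank_cases(table_from_levels(list(A = 5L, X = 3L)), "ecology")
  expect_error(rank_correlation(r1, bad), "different case sets")
})

test_that("group dimension means: identical sheets give equal columns", {
  c1 <- make_full_case("dev", level = 4L, status = "developed")
  c2 <- make_full_case("ing", level = 4L, status = "developing")
  gm <- group_dimension_means(list(c1, c2), s, uniform_weights(),
                              partitioning = "tbl")
  expect_equal(gm$developed, gm$developing)
  expect_true(all(gm$developed == 4))

  # an empty group yields a missing column
  gm1 <- group_dimension_means(list(c1), s, grouping = c(dev = "developed"),
                               partitioning = "tbl")
  expect_false("developing" %in% names(gm1))
  expect_error(
    group_dimension_means(list(c1), s, grouping = c(other = "developed")),
    "unlabeled")
})

test_that("quality profile averages the configured numeric map per dimension", {
  eco <- eco_ids
  allA <- make_case("a", eco, rep(3L, length(eco)), quality = "A")
  qp <- quality_profile(list(allA), s, "tbl")
  expect_equal(qp$developed[qp$dimension_id == "ecological_status"], 3)

  # half A / half C averages to the midpoint; use 8 metrics for an even split
  half8 <- make_case("h8", eco[1:8], rep(3L, 8),
                     quality = rep(c("A", "C"), 4))
  qp <- quality_profile(list(half8), s, "tbl")
  expect_equal(qp$developed[qp$dimension_id == "ecological_status"], 2)

  abb <- make_case("abb", eco[1:3], rep(3L, 3), quality = c("A", "B", "B"))
  qp <- quality_profile(list(abb), s, "tbl")
  expect_equal(qp$developed[qp$dimension_id == "ecological_status"], 7 / 3)
})
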