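s <- fpi_s

test_that("parameter validation rejects impossible settings", {
  expect_error(synthetic_params(rho_w = 0.2, rho_b = 0.5), "positive semi-definite")
  expect_error(synthetic_params(cutpoints = c(1, 1, 2, 3)), "increasing")
  expect_error(synthetic_params(quality_probs = c(A = 0.5, B = 0.5, C = 0.5)),
               "summing to 1")
  expect_error(synthetic_params(missing_rate = 1), "missing_rate")
})

test_that("generation is deterministic from the seed", {
  p <- synthetic_params(n_cases = 4, seed = 99)
  cc1 <- generate(p, s)
  cc2 <- generate(p, s)
  expect_identical(cc1, cc2)
  cc3 <- generate(synthetic_params(n_cases = 4, seed = 100), s)
  expect_false(identical(cc1$cases[[1]]$scores, cc3$cases[[1]]$scores))
})

test_that("null configuration gives balanced groups and near-uniform levels", {
  p <- synthetic_params(n_cases = 150, rho_w = 0, rho_b = 0, rho_x = 0,
                        delta = 0, missing_rate = 0, seed = 7,
                        cutpoints = qnorm(c(0.2, 0.4, 0.6, 0.8)))
  cc <- generate(p, s)
  lv <- unlist(lapply(cc$cases, function(cs) cs$scores$level))
  freq <- tabulate(lv, 5) / length(lv)
  expect_true(all(abs(freq - 0.2) < 0.02))
  est <- recover_parameters(cc, s, "tbl")
  # per-dimension gaps are noisy (SE ~ 0.07 here); bound each at ~3.5 SE and
  # the across-dimension average much tighter
  expect_true(all(abs(est$gap) < 0.25))
  expect_lt(abs(mean(est$gap)), 0.06)
  expect_lt(abs(est$within_dimension_rho), 0.05)
})

test_that("level marginals respect the cutpoints (latent normal CDF)", {
  p <- synthetic_params(n_cases = 300, delta = 0, missing_rate = 0, seed = 13)
  cc <- generate(p, s)
  lv <- unlist(lapply(cc$cases, function(cs) cs$scores$level))
  emp_cdf <- cumsum(tabulate(lv, 5) / length(lv))[1:4]
  expect_equal(emp_cdf, pnorm(p$cutpoints), tolerance = 0.02)
})

test_that("missingness matches the requested rate within binomial error", {
  p <- synthetic_params(n_cases = 100, missing_rate = 0.10, seed = 17)
  cc <- generate(p, s)
  lv <- unlist(lapply(cc$cases, function(cs) cs$scores$level))
  n <- length(lv)
  rate <- mean(is.na(lv))
  expect_lt(abs(rate - 0.10), 3 * sqrt(0.1 * 0.9 / n))
  # a missing level never carries a quality rating (constructor contract)
  for (cs in cc$cases[1:5]) {
    expect_true(all(is.na(cs$scores$quality[is.na(cs$scores$level)])))
  }
})

test_that("quality labels follow the configured probabilities", {
  p <- synthetic_params(n_cases = 100, missing_rate = 0, seed = 19,
                        quality_probs = c(A = 0.45, B = 0.35, C = 0.20))
  cc <- generate(p, s)
  q <- unlist(lapply(cc$cases, function(cs) cs$scores$quality))
  freq <- prop.table(table(q))[c("A", "B", "C")]
  expect_equal(as.numeric(freq), c(0.45, 0.35, 0.20), tolerance = 0.02)
})

test_that("the default latent shift targets a one-level expected gap", {
  d <- latent_shift_for_level_gap(1)
  cuts <- c(-1.5, -0.5, 0.5, 1.5)
  expect_equal(1 + sum(pnorm(d - cuts)), 1 + sum(pnorm(0 - cuts)) + 1,
               tolerance = 1e-6)
})

test_that("recovered within-dimension rank correlation matches a latent oracle", {
  # oracle: large bivariate normal sample at the latent correlation,
  # discretized at the same cutpoints, Spearman correlation
  rho_w <- 0.8
  cuts <- c(-1.5, -0.5, 0.5, 1.5)
  set.seed(123)
  n_mc <- 2e5
  z1 <- rnorm(n_mc)
  z2 <- rho_w * z1 + sqrt(1 - rho_w^2) * rnorm(n_mc)
  l1 <- findInterval(z1, cuts) + 1L
  l2 <- findInterval(z2, cuts) + 1L
  attenuated <- cor(l1, l2, method = "spearman")

  p <- synthetic_params(n_cases = 250, rho_w = rho_w, rho_b = 0.2, rho_x = 0.1,
                        delta = 0, missing_rate = 0, seed = 29)
  cc <- generate(p, s)
  est <- recover_parameters(cc, s, "tbl")
  expect_lt(abs(est$within_dimension_rho - attenuated), 0.1)
})

test_that("shuffling group labels under delta = 0 leaves gaps near zero", {
  p <- synthetic_params(n_cases = 100, delta = 0, missing_rate = 0, seed = 37)
  cc <- generate(p, s)
  set.seed(38)
  shuffled <- lapply(cc$cases, function(cs) {
    cs$development_status <- sample(c("developed", "developing"), 1)
    cs
  })
  est <- recover_parameters(fpi_collection(shuffled), s, "tbl")
  expect_true(all(abs(est$gap) < 0.4))
  expect_lt(abs(mean(est$gap)), 0.15)

  single <- lapply(cc$cases, function(cs) {
    cs$development_status <- "developed"; cs
  })
  expect_error(recover_parameters(fpi_collection(single), s), "single group")
})
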