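test_that("sloan frequency has the beta closed form and monotonicity", {
  # alpha = 1: F = (1-d)^(Nm-1)
  expect_equal(sloan_frequency(1 / 1000, 1000, 0.001), 0.999^999,
               tolerance = 1e-12)
  expect_gt(sloan_frequency(0.5, 1e4, 1e-6), 1 - 1e-9)   # Nm*p >> 1
  expect_lt(sloan_frequency(1e-8, 10, 0.01), 1e-4)       # p -> 0
  p_grid <- seq(1e-4, 0.05, length.out = 100)
  f <- sloan_frequency(p_grid, 50, 0.001)
  expect_true(all(diff(f) > 0))
  expect_true(all(diff(sloan_frequency(seq(0.05, 0.9, length.out = 50),
                                       50, 0.001)) >= 0))
  f_nm <- vapply(c(10, 100, 1000), function(nm)
    sloan_frequency(0.01, nm, 0.001), 0)
  expect_true(all(diff(f_nm) > 0))
  expect_error(sloan_frequency(0, 10, 0.01), "strictly inside")
  expect_error(sloan_frequency(0.1, -1, 0.01), "positive")
})

test_that("the NCM fit is deterministic and self-consistent", {
  p <- exp(seq(log(1e-4), log(0.05), length.out = 80))
  fr <- sloan_frequency(p, Nm = 150, d = 5e-4)
  fit <- fit_ncm_freq(p, fr, d = 5e-4, n_samples = 60)
  expect_equal(fit$Nm, 150, tolerance = 1e-3)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  fit2 <- fit_ncm_freq(p, fr, d = 5e-4, n_samples = 60)
  expect_equal(fit$Nm, fit2$Nm, tolerance = 1e-10)
  expect_true(fit$ci_fraction_within >= 0.95)

  few <- make_ct(matrix(5L, 3, 4))
  expect_error(fit_ncm(few), "interior occurrence")
})

test_that("neutral simulation feeds an accurate NCM recovery", {
  ct <- simulate_neutral(S = 100, N = 600, m = 0.1, n_samples = 40,
                         generations = 50, seed = 2)
  expect_true(all(rowSums(ct) == 600))
  fit <- fit_ncm(ct)
  expect_gt(fit$r2, 0.7)
  expect_lt(abs(fit$m - 0.1) / 0.1, 0.3)

  # deterministic filtering depresses the neutral fit on matched size
  flt <- simulate_filtered(S = 100, N = 600, n_samples = 40, strength = 8,
                           seed = 2)
  fitf <- tryCatch(fit_ncm(flt), error = function(e) list(r2 = -Inf))
  expect_lt(fitf$r2, fit$r2)
})

test_that("the occupancy null preserves richness and depth exactly", {
  set.seed(6)
  m <- matrix(rpois(20 * 50, 3), 20, 50)
  ct <- make_ct(m)
  nul <- null_randomize(ct, seed = 9)
  expect_equal(rowSums(unclass(nul) > 0), rowSums(m > 0), ignore_attr = TRUE)
  expect_equal(rowSums(nul), rowSums(m), ignore_attr = TRUE)

  # selection rate tracks occupancy across many randomizations
  set.seed(7)
  msp <- matrix(rpois(20 * 50, 0.6), 20, 50)
  msp[, colSums(msp) == 0] <- rpois(20, 0.6) + 1L  # avoid empty taxa
  cts <- make_ct(msp)
  hits <- numeric(50)
  set.seed(10)
  for (b in 1:1000) hits <- hits + colSums(unclass(null_randomize(cts)) > 0)
  occ <- colMeans(msp > 0)
  expect_gt(cor(hits, occ, method = "spearman"), 0.9)
})

test_that("NST is bounded, near 1 under its own null and near 0 when frozen", {
  set.seed(11)
  tmpl <- simulate_filtered(S = 40, N = 1500, n_samples = 12, strength = 2,
                            seed = 4)
  obs <- null_randomize(tmpl, seed = 12)
  r <- nst(obs, n_null = 60, seed = 13)
  expect_gt(r$nst, 0.7)
  expect_true(r$nst <= 1)

  row <- rmultinom(1, 1500, exp(rnorm(40)))
  ident <- make_ct(matrix(rep(row, 10), nrow = 10, byrow = TRUE))
  r0 <- nst(ident, n_null = 60, seed = 13)
  expect_lt(r0$nst, 0.05)

  # bounded on random tables, both metrics
  for (i in 1:10) {
    ct <- make_ct(matrix(rpois(8 * 25, 4) , 8, 25))
    for (met in c("bray", "jaccard")) {
      v <- nst(ct, n_null = 30, metric = met, seed = i)$nst
      expect_true(v >= 0 && v <= 1)
    }
  }

  # renaming samples never changes the statistic
  ct <- make_ct(matrix(rpois(8 * 25, 4), 8, 25))
  ct2 <- ct; rownames(ct2) <- paste0("zz", 1:8)
  expect_identical(nst(ct, n_null = 40, seed = 3)$nst,
                   nst(ct2, n_null = 40, seed = 3)$nst)
  expect_error(nst(make_ct(matrix(2, 3, 4)), n_null = 40), "4 samples")
})

test_that("neutral assembly scores higher NST than filtered assembly", {
  wins <- 0L
  for (sd in 1:4) {
    neu <- simulate_neutral(S = 50, N = 800, m = 0.3, n_samples = 14,
                            generations = 30, seed = sd)
    flt <- simulate_filtered(S = 50, N = 800, n_samples = 14, strength = 8,
                             seed = sd)
    n1 <- nst(neu, n_null = 60, seed = 20 + sd)$nst
    n2 <- nst(flt, n_null = 60, seed = 20 + sd)$nst
    wins <- wins + (n1 > n2)
  }
  expect_gte(wins, 3L)
})
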