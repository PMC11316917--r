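test_that("resistance index matches its closed form and bounds", {
  expect_equal(orwin_wardle_rs(10, 10), 1)
  expect_equal(orwin_wardle_rs(10, 0), 0)
  expect_equal(orwin_wardle_rs(10, 5), 1 / 3)
  expect_equal(orwin_wardle_rs(10, 30), -1 / 3)
  expect_error(orwin_wardle_rs(0, 1), "C0")
  expect_error(orwin_wardle_rs(3, -1), "non-negative")

  # scale invariance and bounds on random pairs
  set.seed(1)
  C0 <- rexp(200) + 1e-3
  P0 <- rexp(200) * 3
  rs <- orwin_wardle_rs(C0, P0)
  expect_true(all(rs > -1 & rs <= 1))
  expect_equal(rs, orwin_wardle_rs(7.3 * C0, 7.3 * P0), tolerance = 1e-12)
})

test_that("group resistance pairs fields within crops", {
  set.seed(2)
  meta <- make_meta(5)
  groups <- matrix(runif(nrow(meta) * 2, 0.2, 1), nrow(meta), 2,
                   dimnames = list(meta$sample_id, c("G1", "G2")))
  # treated identical to control: RS = 1 for every pair
  ctl_ids <- meta$sample_id[meta$treatment == "control"]
  trt_ids <- meta$sample_id[meta$treatment == "warming"]
  groups[trt_ids, ] <- groups[ctl_ids, ]
  res <- group_resistance(groups, meta, "warming")
  expect_equal(res$rs_mean, c(1, 1))
  expect_equal(res$n_pairs, c(5L, 5L))

  # one group halved everywhere: RS = 1/3 exactly
  groups2 <- groups
  groups2[trt_ids, "G1"] <- groups2[ctl_ids, "G1"] / 2
  res2 <- group_resistance(groups2, meta, "warming")
  expect_equal(res2$rs_mean[res2$group == "G1"], 1 / 3, tolerance = 1e-12)
  expect_equal(res2$rs_mean[res2$group == "G2"], 1)

  # a field whose control sample is missing from the table is skipped
  groups3 <- groups[rownames(groups) != "maize_f01_control", ]
  res3 <- group_resistance(groups3, meta, "warming")
  expect_equal(res3$n_pairs, c(4L, 4L))

  # order invariance
  perm <- sample(nrow(groups))
  res4 <- group_resistance(groups[perm, ], meta, "warming")
  expect_equal(res4$rs_mean, res$rs_mean)

  # fewer than 3 valid pairs triggers the low-n warning
  meta5 <- make_meta(2)
  g5 <- matrix(1, nrow(meta5), 1, dimnames = list(meta5$sample_id, "G1"))
  expect_warning(r5 <- group_resistance(g5, meta5, "warming"), "2 valid pairs")
  expect_true(r5$low_n)
})

test_that("tolerance width is an abundance-weighted sd of the covariate", {
  expect_equal(tolerance_width(c(1, 1, 1), c(1, 2, 3)), sqrt(2 / 3))
  expect_equal(tolerance_width(c(0, 5, 0), c(1, 5, 9)), 0)
  a <- c(2, 1, 4, 3); e <- c(0.1, 2, -1, 0.5)
  expect_equal(tolerance_width(a, e), tolerance_width(2 * a, e),
               tolerance = 1e-12)
  expect_error(tolerance_width(c(0, 0), c(1, 2)), "all abundances")
  expect_error(tolerance_width(c(1, 1), c(1, Inf)), "finite")
})

test_that("nonsynchronization spans [0,1] with the right limits", {
  x <- c(1, 2, 3, 2, 4)
  expect_equal(nonsynchronization(rbind(x, x)), 0)
  xc <- x - mean(x)
  expect_equal(nonsynchronization(rbind(xc, -xc)), 1)
  expect_error(nonsynchronization(rbind(rep(1, 4), rep(2, 4))), "constant")
  expect_error(nonsynchronization(matrix(1, 2, 1)), "2 condition")

  # two independent unit-variance series: phi ~ 1/2
  set.seed(3)
  long <- rbind(rnorm(10000), rnorm(10000))
  expect_equal(nonsynchronization(long), 0.5, tolerance = 0.03)

  # bounded on random matrices
  set.seed(4)
  for (i in 1:1000) {
    m <- matrix(rnorm(5 * 4), 5, 4)
    v <- nonsynchronization(m)
    expect_true(v >= 0 && v <= 1)
  }
})

test_that("group stability summarizes width and synchrony per group", {
  set.seed(5)
  cfg <- do.call(synth_config, c(list(seed = 11), small_synth))
  b <- generate_bundle(cfg)
  rel <- to_relative(b$community)
  grp <- suppressMessages(aggregate_groups(rel, b$annotation,
                                           domain_of = b$domain_map))
  st <- group_stability(rel, grp, b$annotation, b$meta, env_var = "env_gradient")
  expect_equal(nrow(st), 24)
  expect_true(all(st$tolerance_width >= 0))
  ok <- !is.na(st$nonsynchronization)
  expect_true(any(ok))
  expect_true(all(st$nonsynchronization[ok] >= 0 & st$nonsynchronization[ok] <= 1))
})
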