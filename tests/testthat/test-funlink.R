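test_that("multifunctionality averages z-scores with degenerate handling", {
  f1 <- matrix(c(1, 2, 3), 3, 1, dimnames = list(paste0("s", 1:3), "fA"))
  expect_equal(unname(multifunctionality(f1)), as.vector(scale(f1)))
  f2 <- cbind(f1, fB = f1[, 1])
  expect_equal(unname(multifunctionality(f2)), as.vector(scale(f1)))
  f3 <- cbind(fA = c(1, 2, 3), fB = c(3, 2, 1))
  rownames(f3) <- paste0("s", 1:3)
  expect_equal(unname(multifunctionality(f3)), c(0, 0, 0))
  f4 <- cbind(f1, fC = 5)
  expect_warning(mf <- multifunctionality(f4), "constant")
  expect_equal(unname(mf), as.vector(scale(f1)))
  expect_error(multifunctionality(cbind(fA = rep(2, 3))), "constant")
  set.seed(1)
  f5 <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("s", 1:8), paste0("f", 1:5)))
  expect_equal(mean(multifunctionality(f5)), 0, tolerance = 1e-9)
})

test_that("spearman correlation matches rank-Pearson oracles and exact p", {
  expect_equal(spearman_rho(1:6, c(2, 4, 6, 7, 9, 20))$rho, 1)
  expect_equal(spearman_rho(1:6, -(1:6)^3)$rho, -1)
  sr <- spearman_rho(1:5, c(2, 1, 4, 3, 5))
  expect_equal(sr$rho, 0.8, tolerance = 1e-12)

  set.seed(2)
  for (i in 1:100) {
    n <- sample(c(5:9, 12:30), 1)
    x <- rnorm(n); y <- rnorm(n)
    if (i %% 3 == 0) { x <- round(x); y <- round(y) }   # force ties
    oracle <- cor(rank(x), rank(y))
    expect_equal(spearman_rho(x, y)$rho, oracle, tolerance = 1e-12)
  }

  # exact permutation p agrees with the exact reference for tie-free small n
  set.seed(3)
  for (i in 1:10) {
    x <- sample(1:7); y <- sample(1:7)
    ours <- spearman_rho(x, y)$p
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = TRUE)$p.value)
    expect_equal(ours, min(ref, 1), tolerance = 1e-10)
  }
  expect_error(spearman_rho(1:3, 1:3), "at least 4")
  expect_error(spearman_rho(1:5, rep(2, 5)), "zero variance")
})

test_that("R values recover a perfect link and stay centered under shuffles", {
  set.seed(4)
  meta <- make_meta(10, c("control", "warming"))
  n <- nrow(meta)
  f <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(meta$sample_id, paste0("f", 1:3)))
  mf_ctl <- multifunctionality(f[meta$treatment == "control", ])
  groups <- matrix(runif(n * 2), n, 2,
                   dimnames = list(meta$sample_id, c("G1", "G2")))
  groups[names(mf_ctl), "G1"] <- rank(mf_ctl)      # exact rank agreement
  links <- r_values(groups, f, meta)
  r_g1 <- links[links$group == "G1" & links$treatment == "control", ]
  expect_equal(r_g1$r_value, 1)

  # shuffled abundances: null distribution centered at zero
  set.seed(5)
  rs <- replicate(100, {
    g2 <- groups
    g2[, "G1"] <- sample(g2[, "G1"])
    l <- r_values(g2, f, meta)
    l$r_value[l$group == "G1" & l$treatment == "control"]
  })
  expect_lt(abs(mean(rs)), 2 * sd(rs) / sqrt(length(rs)) + 0.05)

  small <- c(1:3, 11:13)                 # 3 control + 3 treated fields
  expect_error(r_values(groups[small, ], f[small, ], meta[small, ]),
               "fewer than 4")
})

test_that("D values subtract the control R value per group and crop", {
  links <- data.frame(group = rep(c("G1", "G2"), each = 3),
                      crop = "all",
                      treatment = rep(c("control", "warming", "N"), 2),
                      r_value = c(0.2, 0.6, 0.2, -0.1, -0.1, 0.3),
                      p_value = NA_real_, n = 20)
  dv <- d_values(links)
  expect_equal(dv$d_value[dv$group == "G1" & dv$treatment == "warming"], 0.4)
  expect_equal(dv$d_value[dv$group == "G1" & dv$treatment == "N"], 0)
  expect_equal(dv$d_value[dv$group == "G2" & dv$treatment == "N"], 0.4)

  # antisymmetry under exchanging the two strata's R values
  swapped <- links
  i_c <- which(swapped$group == "G1" & swapped$treatment == "control")
  i_w <- which(swapped$group == "G1" & swapped$treatment == "warming")
  swapped$r_value[c(i_c, i_w)] <- swapped$r_value[c(i_w, i_c)]
  dv2 <- d_values(swapped)
  expect_equal(dv2$d_value[dv2$group == "G1" & dv2$treatment == "warming"], -0.4)

  expect_error(d_values(links[links$treatment != "control", ]), "missing control")
})

test_that("size regression reproduces closed-form OLS", {
  sizes <- data.frame(group = paste0("G", 1:5),
                      body_size_um = 10^(0:4))
  y <- setNames(-2 * (0:4) + 1, sizes$group)
  r <- suppressWarnings(size_regression(y, sizes))
  expect_equal(r$slope, -2, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-12)
  expect_equal(r$r2, 1, tolerance = 1e-12)

  sizes4 <- data.frame(group = paste0("G", 1:4), body_size_um = 10^(0:3))
  r4 <- size_regression(setNames(c(1, 3, 2, 4), sizes4$group), sizes4)
  expect_equal(r4$slope, 0.8, tolerance = 1e-12)
  expect_equal(r4$intercept, 1.3, tolerance = 1e-12)

  rc <- size_regression(setNames(rep(2, 5), sizes$group), sizes)
  expect_identical(rc$slope, 0)
  expect_identical(rc$r2, 0)

  expect_error(size_regression(setNames(1:2, c("G1", "G2")), sizes), ">= 3")
  same <- data.frame(group = paste0("G", 1:3), body_size_um = 5)
  expect_error(size_regression(setNames(1:3, same$group), same),
               "zero variance")
})

test_that("per-function correlation table covers groups x functions", {
  set.seed(6)
  meta <- make_meta(8, c("control", "warming"))
  n <- nrow(meta)
  groups <- matrix(runif(n * 3), n, 3,
                   dimnames = list(meta$sample_id, c("G1", "G2", "G3")))
  f <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(meta$sample_id, paste0("f", 1:4)))
  fc <- function_correlations(groups, f, meta, "control", by_crop = FALSE)
  expect_equal(nrow(fc), 12)
  expect_true(all(abs(fc$rho) <= 1))
  fc_bh <- function_correlations(groups, f, meta, "control", by_crop = FALSE,
                                 adjust = "BH")
  expect_true(all(fc_bh$p_value >= fc$p_value - 1e-12))
})
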