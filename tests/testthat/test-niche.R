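test_that("shannon and levins match closed forms and brute-force loops", {
  expect_equal(shannon(rep(1, 4)), log(4))
  expect_equal(shannon(c(1, 0, 0)), 0)
  expect_equal(shannon(c(2, 1, 1)), -(0.5 * log(0.5) + 0.5 * log(0.25)))
  expect_error(shannon(c(0, 0)), "all-zero")

  expect_equal(levins_breadth(c(0.5, 0.5)), 2)
  expect_equal(levins_breadth(c(1, 0, 0)), 1)
  expect_equal(levins_breadth(c(0.5, 0.25, 0.25)), 1 / 0.375)
  expect_error(levins_breadth(c(0.5, 0.4)), "normalized")

  # independent loop oracles on random vectors
  set.seed(1)
  for (i in 1:100) {
    v <- rexp(sample(3:12, 1))
    h_oracle <- 0
    for (p in v / sum(v)) if (p > 0) h_oracle <- h_oracle - p * log(p)
    expect_equal(shannon(v), h_oracle, tolerance = 1e-12)
    pr <- v / sum(v)
    b_oracle <- 0
    for (p in pr) b_oracle <- b_oracle + p * p
    expect_equal(levins_breadth(pr), 1 / b_oracle, tolerance = 1e-12)
  }
})

test_that("community breadth is an abundance-weighted member mean", {
  # taxon A: B = 2 over 4 samples; taxon B: B = 4; equal total weight
  m <- cbind(A = c(2, 2, 0, 0), B = rep(1, 4))
  rownames(m) <- paste0("s", 1:4)
  ct <- make_ct(m, "counts")
  expect_equal(community_breadth(ct, "A"), 2)
  expect_equal(community_breadth(ct, c("A", "B")), 3)

  # zero-abundance member changes nothing; all-zero sample row neither
  m2 <- cbind(m, C = 0)
  expect_equal(community_breadth(make_ct(rbind(m2, 0), "counts"),
                                 c("A", "B", "C")), 3)
  expect_error(community_breadth(ct, character(0)), "empty")
})

test_that("generalist/specialist labels recover planted occupancy patterns", {
  n_s <- 20
  depth <- 1000
  set.seed(7)
  flat <- rep(50L, n_s)                       # same count everywhere
  lone <- c(100L, rep(0L, n_s - 1))           # all mass in one sample
  filler <- t(sapply(1:30, function(i) rmultinom(1, 400, rep(1, n_s))[, 1]))
  m <- rbind(flat, lone, filler)
  m <- t(m)                                    # samples x taxa
  rownames(m) <- paste0("s", 1:n_s)
  colnames(m) <- c("flat", "lone", paste0("f", 1:30))
  ct <- make_ct(m)
  lab <- classify_generalists(ct, n_perm = 499, seed = 5)
  expect_equal(lab$label[lab$taxon_id == "flat"], "generalist")
  expect_equal(lab$observed_B[lab$taxon_id == "flat"], n_s)
  expect_equal(lab$label[lab$taxon_id == "lone"], "specialist")
  expect_equal(lab$observed_B[lab$taxon_id == "lone"], 1)

  # reproducibility and the low-power flag
  lab2 <- classify_generalists(ct, n_perm = 499, seed = 5)
  expect_identical(lab, lab2)
  m[, "lone"] <- c(10L, rep(0L, n_s - 1))
  lab3 <- classify_generalists(make_ct(m), n_perm = 499, seed = 5,
                               min_count = 20)
  expect_true(lab3$low_power[lab3$taxon_id == "lone"])
  expect_equal(lab3$label[lab3$taxon_id == "lone"], "neutral")

  expect_error(classify_generalists(make_ct(matrix(1, 1, 3)), 499), "two samples")
})

test_that("group proportions aggregate labels consistently", {
  lab <- data.frame(taxon_id = paste0("t", 1:7),
                    label = c("generalist", "generalist", "specialist",
                              "neutral", "neutral", "neutral", "specialist"),
                    observed_B = 1, null_low = 0, null_high = 2,
                    low_power = c(rep(FALSE, 6), TRUE))
  ann <- make_ann(paste0("t", 1:7),
                  c(rep("G1", 4), rep("G2", 3)))
  gp <- group_gs_proportions(lab, ann)
  expect_equal(gp$prop_generalists[gp$group == "G1"], 0.5)
  expect_equal(gp$prop_specialists[gp$group == "G1"], 0.25)
  expect_equal(gp$prop_generalists[gp$group == "G2"], 0)
  expect_equal(gp$n_classified, c(4L, 2L))

  # group-size-weighted proportions reproduce the global proportions
  global <- mean(lab$label[!lab$low_power] == "generalist")
  expect_equal(sum(gp$prop_generalists * gp$n_classified) / sum(gp$n_classified),
               global)
})

test_that("niche summary returns one row per group with sane values", {
  cfg <- do.call(synth_config, c(list(seed = 3), small_synth))
  b <- generate_bundle(cfg)
  ns <- niche_summary(b$community, b$annotation)
  expect_equal(nrow(ns), 24)
  expect_true(all(ns$shannon_mean >= 0, na.rm = TRUE))
  expect_true(all(ns$breadth_mean >= 1, na.rm = TRUE))
  expect_true(all(ns$breadth_mean <= nrow(b$community) + 1e-9, na.rm = TRUE))
})
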