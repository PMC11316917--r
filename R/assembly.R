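#' Sloan neutral-model occurrence frequency
#'
#' Predicted probability that a taxon with metacommunity mean relative
#' abundance `p` is detected in a sample, under neutral drift plus
#' immigration with composite parameter `Nm` (local community size
#' times immigration rate) and detection limit `d` (typically 1 / mean
#' sequencing depth):
#' \deqn{\hat F(p) = 1 - \mathrm{BetaCDF}(d;\; Nm\,p,\; Nm\,(1-p)).}
#' Nondecreasing in both `p` and `Nm`.
#'
#' @param p mean relative abundance(s), strictly inside (0, 1).
#' @param Nm positive composite immigration parameter.
#' @param d detection limit in (0, 1).
#' @return predicted occurrence frequency in \[0, 1\].
#' @export
sloan_frequency <- function(p, Nm, d) {
  if (any(p <= 0 | p >= 1)) stop("`p` must lie strictly inside (0, 1)")
  if (Nm <= 0) stop("`Nm` must be positive")
  if (d <= 0 || d >= 1) stop("`d` must lie in (0, 1)")
  1 - stats::pbeta(d, Nm * p, Nm * (1 - p))
}

#' Fit the neutral model to abundance/occurrence pairs
#'
#' Least-squares fit of [sloan_frequency()] to observed occurrence
#' frequencies, over a log-spaced grid of `Nm` refined by golden-section
#' search; deterministic for fixed inputs. The 95% band around the
#' fitted curve is a Wilson binomial interval with `n_samples` trials.
#'
#' @param p mean relative abundances (0 < p < 1).
#' @param freq observed occurrence frequencies in \[0, 1\].
#' @param d detection limit.
#' @param n_samples number of samples behind `freq` (for the band).
#' @return list: `Nm`, `r2`, `n_taxa`, `ci_fraction_within`, `d`,
#'   `fitted` (data frame `p`, `freq`, `fit`, `lower`, `upper`).
#' @export
fit_ncm_freq <- function(p, freq, d, n_samples) {
  if (length(p) != length(freq)) stop("`p` and `freq` lengths differ")
  if (length(p) < 2L) stop("need at least 2 taxa to fit")
  sse <- function(Nm) sum((freq - sloan_frequency(p, Nm, d))^2)
  grid <- 10^seq(-1, 7, length.out = 161)
  vals <- vapply(grid, sse, 0)
  i <- which.min(vals)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(sse, c(lo, hi), tol = 1e-12)
  Nm <- opt$minimum
  if (!is.finite(opt$objective))
    stop("neutral-model fit failed to converge on the initialization grid")
  sst <- sum((freq - mean(freq))^2)
  r2 <- 1 - opt$objective / sst
  fit <- sloan_frequency(p, Nm, d)
  band <- wilson_band(fit, n_samples)
  list(Nm = Nm, r2 = r2, n_taxa = length(p),
       ci_fraction_within = mean(freq >= band$lower & freq <= band$upper),
       d = d,
       fitted = data.frame(p = p, freq = freq, fit = fit,
                           lower = band$lower, upper = band$upper))
}

wilson_band <- function(phat, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  den <- 1 + z^2 / n
  ctr <- (phat + z^2 / (2 * n)) / den
  hw <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / den
  list(lower = pmax(ctr - hw, 0), upper = pmin(ctr + hw, 1))
}

#' Fit the Sloan neutral community model to a counts table
#'
#' Computes each taxon's mean relative abundance and occurrence
#' frequency (fraction of samples with count > 0) and fits `Nm` by
#' nonlinear least squares. The detection limit defaults to half a
#' read at the mean depth (`d = 0.5 / mean depth`, a midpoint
#' continuity correction: a zero count corresponds to a continuous
#' abundance below half an individual's worth); the naive `1 / mean
#' depth` overstates the limit and biases `Nm` upward by tens of
#' percent in simulation. Taxa at the occurrence boundaries (present
#' everywhere or detected nowhere) carry no information about the
#' curve and are excluded from the fit; at least 10 interior taxa are
#' required. The immigration rate is reported as `m = Nm / mean
#' depth`.
#'
#' @param t counts-mode `community_table`.
#' @param members optional subset of taxon ids (e.g. one organism
#'   group); default all taxa.
#' @param d detection limit override in (0, 1).
#' @return list as [fit_ncm_freq()] plus `m` and `mean_depth`.
#' @export
fit_ncm <- function(t, members = NULL, d = NULL) {
  stopifnot(is_community_table(t), identical(ct_mode(t), "counts"))
  m <- unclass(t)
  if (!is.null(members)) {
    members <- intersect(members, colnames(m))
    m <- m[, members, drop = FALSE]
  }
  depths <- rowSums(unclass(t))          # depths from the full community
  rel <- m / depths
  p <- colMeans(rel)
  freq <- colMeans(m > 0)
  keep <- freq > 0 & freq < 1 & p > 0 & p < 1
  if (sum(keep) < 10L)
    stop(sprintf("only %d taxa have interior occurrence; need >= 10 to fit",
                 sum(keep)))
  mean_depth <- mean(depths)
  if (is.null(d)) d <- 0.5 / mean_depth
  fit <- fit_ncm_freq(p[keep], freq[keep], d = d, n_samples = nrow(m))
  fit$m <- fit$Nm / mean_depth
  fit$mean_depth <- mean_depth
  fit
}

#' Occupancy-proportional, richness-preserving null randomization
#'
#' Builds one null community table: every randomized sample keeps its
#' observed richness and depth; the taxa it contains are drawn without
#' replacement with probability proportional to occupancy frequency
#' across samples, and its reads are then allocated to the chosen taxa
#' by a multinomial draw with probabilities proportional to the taxa's
#' regional mean relative abundances.
#'
#' @param t counts-mode `community_table`.
#' @param seed integer seed.
#' @return counts-mode `community_table`, same dimensions; per-sample
#'   richness and depth equal the input's exactly.
#' @export
null_randomize <- function(t, seed = NULL) {
  stopifnot(is_community_table(t), identical(ct_mode(t), "counts"))
  if (!is.null(seed)) set.seed(seed)
  m <- unclass(t)
  depths <- rowSums(m)
  occ <- colMeans(m > 0)
  q <- colMeans(m / depths)              # regional mean relative abundance
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  S <- ncol(m)
  for (s in seq_len(nrow(m))) {
    r <- sum(m[s, ] > 0)
    if (r == 0L) next
    sel <- sample.int(S, r, replace = FALSE, prob = occ)
    # one guaranteed read per selected taxon keeps richness exact
    out[s, sel] <- 1 + stats::rmultinom(1, depths[s] - r, q[sel])
  }
  community_table(out, "counts")
}

#' Normalized stochasticity ratio
#'
#' Compares observed pairwise community dissimilarity with its
#' expectation under the occupancy-proportional null of
#' [null_randomize()]. For each sample pair (i, j) with observed
#' dissimilarity `D` and null mean `E`:
#' \deqn{ST_{ij} = D/E \; (D \le E), \qquad (1-D)/(1-E) \; (D > E),}
#' a ratio that is 1 when the observation matches the null exactly and
#' falls toward 0 as assembly becomes more deterministic than the null
#' in either direction. The statistic is the mean over pairs; pairs
#' whose null expectation is exactly 0 or 1 are excluded.
#'
#' @param t counts-mode `community_table` (>= 4 samples).
#' @param members optional taxon subset (e.g. one organism group).
#' @param n_null number of null randomizations (>= 30; production runs
#'   use >= 100, default 200).
#' @param metric `"bray"` (abundance-based, on row proportions) or
#'   `"jaccard"` (incidence-based).
#' @param seed integer seed for the null stream.
#' @return list: `nst` in \[0, 1\], `n_pairs`, `n_excluded`, `n_null`,
#'   `metric`, and `st_pairs` (the per-pair ratios, as a `dist`).
#' @export
nst <- function(t, members = NULL, n_null = 200L, metric = c("bray", "jaccard"),
                seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(is_community_table(t), identical(ct_mode(t), "counts"))
  if (!is.null(members)) {
    members <- intersect(members, colnames(t))
    sub <- unclass(t)[, members, drop = FALSE]
    keep <- rowSums(sub) > 0
    t <- community_table(sub[keep, , drop = FALSE], "counts")
  }
  if (nrow(t) < 4L) stop("NST needs at least 4 samples")
  if (n_null < 30L) stop("`n_null` must be at least 30")
  dis <- function(x) {
    m <- unclass(x)
    if (metric == "bray") vegan::vegdist(m / rowSums(m), method = "bray")
    else vegan::vegdist(m, method = "jaccard", binary = TRUE)
  }
  D <- dis(t)
  set.seed(seed)
  Ebar <- Reduce(`+`, lapply(seq_len(n_null), function(b) dis(null_randomize(t)))) / n_null
  st <- ifelse(D <= Ebar, D / Ebar, (1 - D) / (1 - Ebar))
  ok <- Ebar > 0 & Ebar < 1
  list(nst = mean(st[ok]), n_pairs = sum(ok), n_excluded = sum(!ok),
       n_null = n_null, metric = metric, st_pairs = st)
}

#' Per-group, per-treatment assembly summary (NCM + NST)
#'
#' Subsets the counts table to each organism group's member taxa and
#' each treatment's samples, fits the neutral model and computes NST.
#' Groups where the neutral fit is not identified (too few taxa with
#' interior occurrence) get `NA` fit fields.
#'
#' @param t counts-mode `community_table`.
#' @param ann taxon annotation.
#' @param meta sample metadata.
#' @param treatments treatments to analyse (default all in `meta`).
#' @param n_null,metric,seed passed to [nst()].
#' @return data frame: `group`, `treatment`, `Nm`, `m`, `r2`, `n_taxa`,
#'   `nst`, `n_null`, `metric`.
#' @export
assembly_summary <- function(t, ann, meta, treatments = NULL,
                             n_null = 200L, metric = "bray", seed = 1L) {
  stopifnot(is_community_table(t))
  ann <- validate_annotation(ann)
  meta <- validate_metadata(meta)
  if (is.null(treatments)) treatments <- unique(meta$treatment)
  out <- list()
  for (tr in treatments) {
    ids <- meta$sample_id[meta$treatment == tr]
    sub <- community_table(unclass(t)[intersect(ids, rownames(t)), , drop = FALSE],
                           "counts")
    for (g in unique(ann$group)) {
      members <- ann$taxon_id[ann$group == g]
      fit <- tryCatch(fit_ncm(sub, members), error = function(e) NULL)
      ns <- tryCatch(nst(sub, members, n_null = n_null, metric = metric,
                         seed = seed),
                     error = function(e) NULL)
      out[[length(out) + 1L]] <- data.frame(
        group = g, treatment = tr,
        Nm = if (is.null(fit)) NA_real_ else fit$Nm,
        m = if (is.null(fit)) NA_real_ else fit$m,
        r2 = if (is.null(fit)) NA_real_ else fit$r2,
        n_taxa = if (is.null(fit)) NA_integer_ else fit$n_taxa,
        nst = if (is.null(ns)) NA_real_ else ns$nst,
        n_null = n_null, metric = metric)
    }
  }
  do.call(rbind, out)
}
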