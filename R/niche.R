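#' Shannon diversity index
#'
#' \eqn{H = -\sum_i p_i \ln p_i} over the nonzero entries of an
#' abundance vector (natural log). Bounded by \eqn{\ln k} for k nonzero
#' entries, attained at the uniform distribution.
#'
#' @param abund non-negative abundance vector with positive total.
#' @return scalar H >= 0.
#' @export
shannon <- function(abund) {
  if (any(abund < 0)) stop("abundances must be non-negative")
  tot <- sum(abund)
  if (tot <= 0) stop("Shannon index undefined for an all-zero vector")
  p <- abund[abund > 0] / tot
  -sum(p * log(p))
}

#' Levins niche breadth
#'
#' \eqn{B = 1 / \sum_j P_{ij}^2}, where \eqn{P_{ij}} is the fraction of
#' taxon i's total abundance found in habitat j. B ranges from 1 (all
#' mass in one habitat: a strict specialist) to the number of habitats
#' (uniform occupancy: the broadest possible niche).
#'
#' @param p proportions of a taxon's abundance across habitats; must sum
#'   to 1 within 1e-9 (the caller normalizes).
#' @return scalar B in \[1, `length(p)`\].
#' @export
levins_breadth <- function(p) {
  if (any(p < 0)) stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-9)
    stop("`p` must be normalized to sum to 1 (caller normalizes)")
  1 / sum(p^2)
}

#' Abundance-weighted community niche breadth
#'
#' Group-level niche breadth: the mean of the member taxa's Levins
#' breadths across samples (habitats), weighted by each taxon's total
#' relative abundance. Members with zero total abundance carry zero
#' weight and do not affect the result.
#'
#' @param t a `community_table` (counts or relative); habitats are its
#'   samples.
#' @param members character vector of member taxon ids.
#' @return scalar weighted-mean breadth.
#' @export
community_breadth <- function(t, members) {
  stopifnot(is_community_table(t))
  members <- intersect(members, colnames(t))
  if (!length(members)) stop("empty member set")
  m <- unclass(t)[, members, drop = FALSE]
  tots <- colSums(m)
  if (all(tots <= 0)) stop("no member taxon has nonzero total abundance")
  keep <- tots > 0
  B <- vapply(which(keep), function(i) levins_breadth(m[, i] / tots[i]), 0)
  sum(B * tots[keep]) / sum(tots[keep])
}

#' Classify taxa as habitat generalists or specialists
#'
#' Observed Levins breadth of each taxon across samples is compared with
#' a permutation null that redistributes the taxon's total count over
#' samples by a multinomial draw with probabilities proportional to
#' sample totals (preserving uneven sequencing effort, the dominant
#' artifact). A taxon is a generalist when its observed breadth exceeds
#' the upper empirical quantile of its null distribution, a specialist
#' when it falls below the lower quantile, and neutral otherwise. Taxa
#' with fewer than `min_count` total reads are labeled neutral and
#' flagged `low_power` (their breadth estimate is too noisy to test).
#'
#' @param t counts-mode `community_table` with >= 2 samples.
#' @param n_perm number of null draws (>= 100; default 999).
#' @param ci two-sided confidence level for the null interval
#'   (default 0.95).
#' @param seed integer seed; labels are reproducible given it.
#' @param min_count minimum taxon total for testing (default 20).
#' @return data frame: `taxon_id`, `label` (generalist/specialist/
#'   neutral), `observed_B`, `null_low`, `null_high`, `low_power`.
#' @export
classify_generalists <- function(t, n_perm = 999L, ci = 0.95, seed = 1L,
                                 min_count = 20L) {
  stopifnot(is_community_table(t), identical(ct_mode(t), "counts"))
  if (nrow(t) < 2L)
    stop("niche breadth needs at least two samples (habitats)")
  if (n_perm < 100L) stop("`n_perm` must be at least 100")
  if (!(ci > 0 && ci < 1)) stop("`ci` must be in (0, 1)")
  m <- unclass(t)
  depths <- rowSums(m)
  probs <- depths / sum(depths)
  totals <- colSums(m)
  alpha <- (1 - ci) / 2

  set.seed(seed)
  res <- lapply(seq_len(ncol(m)), function(i) {
    Ti <- totals[i]
    if (Ti <= 0)
      return(data.frame(taxon_id = colnames(m)[i], label = "neutral",
                        observed_B = NA_real_, null_low = NA_real_,
                        null_high = NA_real_, low_power = TRUE))
    obs <- 1 / sum((m[, i] / Ti)^2)
    if (Ti < min_count)
      return(data.frame(taxon_id = colnames(m)[i], label = "neutral",
                        observed_B = obs, null_low = NA_real_,
                        null_high = NA_real_, low_power = TRUE))
    draws <- stats::rmultinom(n_perm, Ti, probs)        # samples x n_perm
    nullB <- 1 / colSums((draws / Ti)^2)
    q <- stats::quantile(nullB, c(alpha, 1 - alpha), names = FALSE)
    lab <- if (obs > q[2]) "generalist" else if (obs < q[1]) "specialist" else "neutral"
    data.frame(taxon_id = colnames(m)[i], label = lab, observed_B = obs,
               null_low = q[1], null_high = q[2], low_power = FALSE)
  })
  do.call(rbind, res)
}

#' Per-group generalist and specialist proportions
#'
#' Proportions are taken over each group's classifiable taxa (those not
#' flagged `low_power`). Groups with no classifiable taxa get `NA`.
#'
#' @param labels output of [classify_generalists()].
#' @param ann taxon annotation.
#' @return data frame: `group`, `prop_generalists`, `prop_specialists`,
#'   `n_classified`.
#' @export
group_gs_proportions <- function(labels, ann) {
  ann <- validate_annotation(ann)
  lab <- labels[!labels$low_power, , drop = FALSE]
  grp <- ann$group[match(lab$taxon_id, ann$taxon_id)]
  if (anyNA(grp)) stop("every classified taxon must be annotated")
  out <- lapply(unique(ann$group), function(g) {
    li <- lab$label[grp == g]
    if (!length(li)) {
      message(sprintf("group '%s' has no classifiable taxa", g))
      return(data.frame(group = g, prop_generalists = NA_real_,
                        prop_specialists = NA_real_, n_classified = 0L))
    }
    data.frame(group = g,
               prop_generalists = mean(li == "generalist"),
               prop_specialists = mean(li == "specialist"),
               n_classified = length(li))
  })
  do.call(rbind, out)
}

#' Per-group diversity and niche summary
#'
#' Shannon diversity is computed per sample on the group's member-taxon
#' counts and then averaged across samples; niche breadth is the
#' abundance-weighted community breadth across samples. Optionally
#' merges generalist/specialist proportions.
#'
#' @param t counts-mode `community_table`.
#' @param ann taxon annotation.
#' @param gs_labels optional output of [classify_generalists()].
#' @return data frame: `group`, `shannon_mean`, `breadth_mean`,
#'   `n_taxa`, and (if labels given) the proportion columns.
#' @export
niche_summary <- function(t, ann, gs_labels = NULL) {
  stopifnot(is_community_table(t))
  ann <- validate_annotation(ann)
  m <- unclass(t)
  out <- lapply(unique(ann$group), function(g) {
    members <- intersect(ann$taxon_id[ann$group == g], colnames(m))
    if (!length(members))
      return(data.frame(group = g, shannon_mean = NA_real_,
                        breadth_mean = NA_real_, n_taxa = 0L))
    sub <- m[, members, drop = FALSE]
    hs <- apply(sub, 1, function(row) if (sum(row) > 0) shannon(row) else NA_real_)
    data.frame(group = g, shannon_mean = mean(hs, na.rm = TRUE),
               breadth_mean = community_breadth(t, members),
               n_taxa = length(members))
  })
  out <- do.call(rbind, out)
  if (!is.null(gs_labels))
    out <- merge(out, group_gs_proportions(gs_labels, ann), by = "group",
                 sort = FALSE)
  out
}
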