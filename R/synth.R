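#' Configuration for the synthetic community generator
#'
#' Returns the default study configuration: 2 crops x 25 fields x 4
#' treatments (about 200 samples), 24 organism groups spanning roughly
#' three decades of body size, taxon richness decreasing with size
#' (80 taxa for the smallest group down to 20 for the largest), and a
#' planted body-size-dependent disturbance sensitivity. Every element
#' can be overridden through `...`.
#'
#' Planted structure, all recoverable downstream:
#' * disturbance sensitivity `s_g = max(0, sensitivity_slope *
#'   log10(size_g))`; disturbed expected proportions are multiplied by
#'   `exp(-s_g * dose + eps)`;
#' * field-to-field selection (an environmental-gradient response plus
#'   idiosyncratic field preference) whose strength grows with body
#'   size (`niche_sigma_range`), so larger groups have narrower niches,
#'   more specialists and lower assembly stochasticity;
#' * function links whose strength grows with size in the control
#'   stratum (`link_control_range`) and shrinks with size in treated
#'   strata (`link_treated_range`).
#'
#' @param seed integer; structure and sampling noise use separate
#'   streams derived from it.
#' @param ... overrides for any configuration element.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, ...) {
  sizes <- default_group_sizes()
  u <- size_rank01(sizes$body_size_um)
  cfg <- list(
    seed = as.integer(seed),
    crops = c("maize", "rice"),
    n_fields = 25L,
    treatments = c("control", "warming", "N", "P"),
    doses = c(control = 0, warming = 1, N = 0.8, P = 0.6),
    groups = sizes,
    n_taxa_per_group = stats::setNames(round(80 - 60 * u), sizes$group),
    depth = 50000,
    depth_dispersion = 20,
    lognormal_sigma = 1.0,
    group_share_sigma = 0.6,
    domain_shares = c(bacteria = 0.5, fungi = 0.3, protist = 0.2),
    sensitivity_slope = 0.4,
    eps_sigma = 0.15,
    eps_share_group = 0.6,
    niche_sigma_range = c(0.02, 0.9),
    n_functions = 11L,
    function_names = c("respiration", "N_mineralization", "nitrification",
                       "denitrification", "N_fixation", "P_availability",
                       "glucosidase", "urease", "phosphatase",
                       "organic_C", "microbial_biomass"),
    link_control_range = c(0.05, 0.90),
    link_treated_range = c(0.90, 0.05),
    link_profile_power = 2,
    gradient_frac = 0.05,
    function_var_shared = 0.5,
    function_var_own = 0.2,
    unannotated_frac = 0.35,
    unannotated_taxa_frac = 0.4)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop(sprintf("unknown config element(s): %s",
                                paste(bad, collapse = ", ")))
  cfg[names(dots)] <- dots
  if (cfg$n_fields < 3L) stop("n_fields must be >= 3")
  if (cfg$depth < 100) stop("depth must be >= 100")
  if (any(unlist(cfg$n_taxa_per_group) < 1)) stop("every group needs >= 1 taxon")
  if (any(abs(c(cfg$link_control_range, cfg$link_treated_range)) >= 1))
    stop("correlation strengths must lie inside (-1, 1)")
  structure(cfg, class = c("synth_config", "list"))
}

size_rank01 <- function(sizes) {
  lx <- log10(sizes)
  (lx - min(lx)) / (max(lx) - min(lx))
}

#' Generate a complete synthetic study bundle
#'
#' Builds a paired control/disturbance data set with known, planted
#' structure: a counts community table, a taxon annotation, sample
#' metadata (field, crop, treatment, an environmental gradient and the
#' treatment dose), an 11-function table linked to group abundances,
#' and the planted truth needed to verify recovery. Structure (baseline
#' compositions, field effects) and sampling noise use separate seed
#' streams so the same landscape can be resampled.
#'
#' @param cfg a [synth_config()].
#' @return list with elements `community` (counts
#'   [community_table()]), `annotation` (grouped taxa only), `meta`,
#'   `functions`, `truth` (the planted parameters), and `domain_map`
#'   (taxon to domain, covering background taxa too).
#' @export
generate_bundle <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  g <- cfg$groups
  n_groups <- nrow(g)
  u <- size_rank01(g$body_size_um)
  s_g <- pmax(0, cfg$sensitivity_slope * log10(g$body_size_um))
  sigma_g <- cfg$niche_sigma_range[1] +
    diff(cfg$niche_sigma_range) * u
  fn_of <- stats::setNames(rep(seq_len(cfg$n_functions), length.out = n_groups),
                           g$group)
  # convex profile: link strength concentrated at one end of the size
  # axis, so the latent activity is not diluted over all 24 groups
  pw <- cfg$link_profile_power
  rho_ctl <- cfg$link_control_range[1] + diff(cfg$link_control_range) * u^pw
  rho_trt <- cfg$link_treated_range[2] + diff(rev(cfg$link_treated_range)) * (1 - u)^pw

  ## ---- structure stream ----
  set.seed(cfg$seed)
  n_taxa <- unlist(cfg$n_taxa_per_group[g$group])
  taxon_group <- rep(g$group, n_taxa)
  # ungrouped background taxa per domain: the organism groups cover only
  # part of each domain's sequences (the coverage filter's subject), and
  # the background absorbs compositional renormalization
  dom_of <- stats::setNames(g$domain, g$group)
  n_unannot <- vapply(unique(g$domain), function(d)
    max(5L, as.integer(round(cfg$unannotated_taxa_frac *
                               sum(n_taxa[g$domain == d])))),
    integer(1))
  u_domain <- rep(names(n_unannot), n_unannot)
  taxon_domain <- c(dom_of[taxon_group], u_domain)
  is_grouped <- c(rep(TRUE, length(taxon_group)), rep(FALSE, length(u_domain)))
  taxon_id <- c(paste0("t", formatC(seq_along(taxon_group), width = 4,
                                    flag = "0"), "_",
                       abbreviate(taxon_group, 6)),
                paste0("u", formatC(seq_along(u_domain), width = 4,
                                    flag = "0"), "_", u_domain))
  ann <- data.frame(taxon_id = taxon_id[is_grouped],
                    domain = unname(dom_of[taxon_group]),
                    group = taxon_group,
                    body_size_um = rep(g$body_size_um, n_taxa))
  domain_map <- data.frame(taxon_id = taxon_id, domain = unname(taxon_domain))
  # baseline composition: domain share x (grouped vs background split) x
  # lognormal group share x lognormal taxon share
  grp_share <- stats::setNames(exp(stats::rnorm(n_groups, 0, cfg$group_share_sigma)),
                               g$group)
  uf <- cfg$unannotated_frac
  for (d in unique(g$domain)) {
    sel <- g$domain == d
    grp_share[sel] <- grp_share[sel] / sum(grp_share[sel]) *
      cfg$domain_shares[[d]] * (1 - uf)
  }
  tax_share <- exp(stats::rnorm(length(taxon_id), 0, cfg$lognormal_sigma))
  base <- numeric(length(taxon_id))
  for (gg in g$group) {
    sel <- which(is_grouped)[taxon_group == gg]
    base[sel] <- grp_share[[gg]] * tax_share[sel] / sum(tax_share[sel])
  }
  for (d in unique(g$domain)) {
    sel <- !is_grouped & taxon_domain == d
    base[sel] <- cfg$domain_shares[[d]] * uf * tax_share[sel] / sum(tax_share[sel])
  }
  base <- base / sum(base)

  fields <- sprintf("f%02d", seq_len(cfg$n_fields))
  # field landscape: per-crop gradient value per field, per-taxon gradient
  # response and idiosyncratic field preference (variance split evenly)
  grad <- matrix(stats::rnorm(length(cfg$crops) * cfg$n_fields), cfg$n_fields,
                 dimnames = list(fields, cfg$crops))
  sigma_dom <- tapply(sigma_g, g$domain, mean)
  s_dom <- tapply(s_g, g$domain, mean)
  sg_taxon <- numeric(length(taxon_id))
  sg_taxon[is_grouped] <- sigma_g[match(taxon_group, g$group)]
  sg_taxon[!is_grouped] <- sigma_dom[u_domain]
  s_taxon <- numeric(length(taxon_id))
  s_taxon[is_grouped] <- s_g[match(taxon_group, g$group)]
  s_taxon[!is_grouped] <- s_dom[u_domain]
  b_resp <- stats::rnorm(length(taxon_id), 0,
                         sg_taxon * sqrt(cfg$gradient_frac))
  eta_idio <- array(stats::rnorm(cfg$n_fields * length(cfg$crops) * length(taxon_id),
                                 0, rep(sg_taxon * sqrt(1 - cfg$gradient_frac),
                                        each = cfg$n_fields * length(cfg$crops))),
                    dim = c(cfg$n_fields, length(cfg$crops), length(taxon_id)),
                    dimnames = list(fields, cfg$crops, taxon_id))

  ## ---- sampling-noise stream ----
  set.seed(cfg$seed + 1L)
  meta <- expand.grid(field_id = fields, crop = cfg$crops,
                      treatment = cfg$treatments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$sample_id <- paste(meta$crop, meta$field_id, meta$treatment, sep = "_")
  meta$dose <- unname(cfg$doses[meta$treatment])
  meta$env_gradient <- grad[cbind(meta$field_id, meta$crop)] + meta$dose
  meta <- meta[, c("sample_id", "field_id", "crop", "treatment",
                   "env_gradient", "dose")]

  counts <- matrix(0L, nrow(meta), length(taxon_id),
                   dimnames = list(meta$sample_id, taxon_id))
  dom_share_taxon <- cfg$domain_shares[ann$domain]
  for (sidx in seq_len(nrow(meta))) {
    fi <- meta$field_id[sidx]; cr <- meta$crop[sidx]
    dose <- meta$dose[sidx]
    eta <- b_resp * grad[fi, cr] + eta_idio[fi, cr, ]
    lw <- log(base) + eta
    if (dose > 0) {
      # response noise grows with planted sensitivity: larger organisms
      # respond more variably as well as more negatively. The noise is
      # split into a group-coherent part and taxon-idiosyncratic scatter
      # (eps_share_group); the split is chosen so that, after
      # compositional renormalization, the net group-level noise is
      # approximately size-neutral when sensitivity_slope = 0 (the
      # coherent part is self-damped in proportion to a group's domain
      # weight, the idiosyncratic part shrinks with group richness, and
      # the two biases run in opposite directions along the size axis)
      sd_g <- cfg$eps_sigma * (1 + 2 * s_g)
      a <- cfg$eps_share_group
      eps_grp <- stats::rnorm(n_groups, 0, sqrt(a) * sd_g)
      shift <- numeric(length(lw))
      shift[is_grouped] <- (-s_g * dose + eps_grp)[match(taxon_group, g$group)] +
        stats::rnorm(sum(is_grouped), 0,
                     sqrt(1 - a) * sd_g[match(taxon_group, g$group)])
      shift[!is_grouped] <- -s_taxon[!is_grouped] * dose +
        stats::rnorm(sum(!is_grouped), 0,
                     cfg$eps_sigma * (1 + 2 * s_taxon[!is_grouped]))
      lw <- lw + shift
    }
    w <- exp(lw - max(lw))
    # one joint composition: disturbance shifts domain totals too, so the
    # planted size effect is visible in global group shares
    pi_s <- w / sum(w)
    depth_s <- max(1000, stats::rnbinom(1, mu = cfg$depth,
                                        size = cfg$depth_dispersion))
    counts[sidx, ] <- stats::rmultinom(1, depth_s, pi_s)
  }
  community <- community_table(counts, "counts")

  ## functions: within each (crop, treatment) stratum all 11 functions share
  ## a latent "activity" axis built from standardized group abundances with
  ## treatment-dependent link strengths (soil functions are mutually
  ## correlated); each function adds a smaller own-group term and noise
  rel <- to_relative(community)
  # functions respond to within-domain group shares, with the ungrouped
  # background in the denominator damping compositional coupling
  grp_ab <- suppressMessages(aggregate_groups(rel, ann, groups = g$group,
                                              domain_of = domain_map))
  fmat <- matrix(NA_real_, nrow(meta), cfg$n_functions,
                 dimnames = list(meta$sample_id,
                                 cfg$function_names[seq_len(cfg$n_functions)]))
  a_sh <- sqrt(cfg$function_var_shared)
  a_own <- sqrt(cfg$function_var_own)
  a_eps <- sqrt(1 - cfg$function_var_shared - cfg$function_var_own)
  zscale <- function(v) if (stats::sd(v) > 0) as.vector(scale(v)) else v * 0
  for (cr in cfg$crops) for (tr in cfg$treatments) {
    ids <- meta$sample_id[meta$crop == cr & meta$treatment == tr]
    z <- apply(grp_ab[ids, , drop = FALSE], 2, zscale)
    rho <- if (tr == "control") rho_ctl else rho_trt
    A <- zscale(as.vector(z %*% rho))
    for (k in seq_len(cfg$n_functions)) {
      own <- zscale(as.vector(z[, fn_of == k, drop = FALSE] %*% rho[fn_of == k]))
      fmat[ids, k] <- a_sh * A + a_own * own +
        a_eps * stats::rnorm(length(ids))
    }
  }

  truth <- list(seed = cfg$seed,
                sensitivity = stats::setNames(s_g, g$group),
                niche_sigma = stats::setNames(sigma_g, g$group),
                baseline = stats::setNames(base, taxon_id),
                group_share = grp_share,
                function_assignment = fn_of,
                link_control = stats::setNames(rho_ctl, g$group),
                link_treated = stats::setNames(rho_trt, g$group),
                doses = cfg$doses,
                unannotated_frac = uf)
  list(community = community, annotation = ann, meta = meta,
       functions = fmat, truth = truth, domain_map = domain_map)
}

#' Neutral-assembly simulator (Moran model with immigration)
#'
#' Each sample is an independent local community of `N` individuals.
#' At every update step one random individual dies; with probability
#' `m` it is replaced by an immigrant drawn from the fixed source-pool
#' proportions, otherwise by the offspring of a resident drawn
#' proportional to local abundance. Communities are initialized by a
#' multinomial draw from the source pool and run for
#' `generations * N` steps (default 50 N, several relaxation times of
#' the drift-immigration balance at moderate `m`).
#'
#' @param S number of taxa.
#' @param N individuals per local community (>= 100).
#' @param m immigration probability in (0, 1].
#' @param n_samples number of local communities.
#' @param generations burn-in length in units of N update steps
#'   (default 50).
#' @param pool source-pool proportions (length S, summing to 1); by
#'   default lognormal(sd = 1) proportions drawn under `seed`.
#' @param seed integer seed.
#' @return counts-mode [community_table()]; every row sums to `N`.
#' @export
simulate_neutral <- function(S, N, m, n_samples, generations = 50L,
                             pool = NULL, seed = 1L) {
  if (!(m > 0 && m <= 1)) stop("`m` must lie in (0, 1]")
  if (N < 100) stop("`N` must be >= 100")
  set.seed(seed)
  if (is.null(pool)) {
    pool <- exp(stats::rnorm(S, 0, 1))
    pool <- pool / sum(pool)
  }
  if (length(pool) != S || abs(sum(pool) - 1) > 1e-8)
    stop("`pool` must have length S and sum to 1")
  steps <- as.integer(generations) * as.integer(N)
  counts <- .simulate_neutral_cpp(as.integer(S), as.integer(N), m,
                                  as.integer(n_samples), steps,
                                  as.numeric(pool))
  dimnames(counts) <- list(sprintf("s%03d", seq_len(n_samples)),
                           sprintf("t%04d", seq_len(S)))
  community_table(counts, "counts")
}

#' Environmentally filtered community simulator
#'
#' Deterministic counterpart of [simulate_neutral()]: samples sit on an
#' environmental gradient and each taxon has a gradient optimum; the
#' expected abundance of taxon i in sample s is its pool abundance
#' times a Gaussian filter `exp(-strength * (env_s - opt_i)^2)`, then
#' `N` reads are drawn multinomially. `strength = 0` reduces to
#' repeated multinomial sampling of the pool; increasing strength makes
#' assembly increasingly deterministic along the gradient.
#'
#' @param S,N,n_samples as in [simulate_neutral()].
#' @param strength non-negative filtering strength.
#' @param seed integer seed.
#' @return counts-mode [community_table()].
#' @export
simulate_filtered <- function(S, N, n_samples, strength, seed = 1L) {
  if (strength < 0) stop("`strength` must be non-negative")
  set.seed(seed)
  pool <- exp(stats::rnorm(S, 0, 1)); pool <- pool / sum(pool)
  opt <- stats::runif(S, -1, 1)
  env <- seq(-1, 1, length.out = n_samples)
  counts <- matrix(0L, n_samples, S,
                   dimnames = list(sprintf("s%03d", seq_len(n_samples)),
                                   sprintf("t%04d", seq_len(S))))
  for (s in seq_len(n_samples)) {
    w <- pool * exp(-strength * (env[s] - opt)^2)
    counts[s, ] <- stats::rmultinom(1, N, w)
  }
  community_table(counts, "counts")
}
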