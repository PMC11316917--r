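#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()].
#' Either `synthesize = TRUE` (the default), in which case a synthetic
#' bundle is generated with [generate_bundle()] under `synth` overrides,
#' or the four input paths (`community`, `annotation`, `metadata`,
#' `functions`) must point to existing files.
#'
#' @param synthesize generate inputs instead of reading them.
#' @param paths named list of input paths (`community`, `annotation`,
#'   `metadata`, `functions`) when `synthesize = FALSE`.
#' @param out_dir output directory (created if missing).
#' @param seed master seed; stage streams are derived from it.
#' @param coverage_threshold domain sequence-coverage requirement
#'   (default 0.6).
#' @param control control treatment label.
#' @param n_perm permutations for generalist/specialist nulls.
#' @param n_null randomizations for NST.
#' @param ci two-sided confidence level for the niche null interval.
#' @param metric dissimilarity for NST (`"bray"` or `"jaccard"`).
#' @param run_assembly fit the neutral model and NST per group x
#'   treatment (the slowest stage); defaults to TRUE.
#' @param synth list of overrides passed to [synth_config()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthesize = TRUE, paths = NULL,
                            out_dir = "sizestab_out", seed = 1L,
                            coverage_threshold = 0.6, control = "control",
                            n_perm = 999L, n_null = 200L, ci = 0.95,
                            metric = "bray", run_assembly = TRUE,
                            synth = list()) {
  cfg <- list(synthesize = isTRUE(synthesize), paths = paths,
              out_dir = out_dir, seed = as.integer(seed),
              coverage_threshold = coverage_threshold, control = control,
              n_perm = as.integer(n_perm), n_null = as.integer(n_null),
              ci = ci, metric = metric, run_assembly = isTRUE(run_assembly),
              synth = synth)
  if (!cfg$synthesize) {
    need <- c("community", "annotation", "metadata", "functions")
    if (is.null(paths) || !all(need %in% names(paths)))
      stop(sprintf("when not synthesizing, `paths` must name: %s",
                   paste(need, collapse = ", ")))
    missing <- !vapply(paths[need], file.exists, logical(1))
    if (any(missing))
      stop(sprintf("input file(s) not found: %s",
                   paste(unlist(paths[need][missing]), collapse = ", ")))
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

# small FNV-1a hash so manifests can fingerprint the configuration
# without a cryptography dependency
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(h, b) * 16777619) %% 4294967296
  sprintf("%08x", h)
}

write_tsv <- function(df, path) {
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: input/validation, coverage filter,
#' resistance and stability, diversity/niche/generalists, neutral-model
#' and NST fits (optional), function linkage with R and D values, and
#' the body-size regressions behind every panel. Every stage writes a
#' TSV under `cfg$out_dir`; a JSON manifest records the configuration
#' hash, seeds and output files. Reruns with the same configuration and
#' seed are byte-identical.
#'
#' @param cfg a [pipeline_config()].
#' @return the manifest, invisibly (a list).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(df, name) {
    p <- file.path(cfg$out_dir, name)
    outputs <<- c(outputs, write_tsv(df, p))
    df
  }

  ## stage: inputs ----------------------------------------------------
  dmap <- NULL
  if (cfg$synthesize) {
    sc <- do.call(synth_config, c(list(seed = cfg$seed), cfg$synth))
    bundle <- generate_bundle(sc)
    comm <- bundle$community; ann <- bundle$annotation
    meta <- bundle$meta; fmat <- bundle$functions
    dmap <- bundle$domain_map
    write_community(comm, file.path(cfg$out_dir, "community.tsv"))
    outputs <- c(outputs, file.path(cfg$out_dir, "community.tsv"))
    emit(ann, "annotation.tsv")
    emit(meta, "metadata.tsv")
    emit(data.frame(sample_id = rownames(fmat), fmat, check.names = FALSE),
         "functions.tsv")
    truth_path <- file.path(cfg$out_dir, "planted_truth.json")
    jsonlite::write_json(bundle$truth, truth_path, auto_unbox = TRUE,
                         digits = NA)
    outputs <- c(outputs, truth_path)
  } else {
    comm <- read_community(cfg$paths$community)
    ann <- read_taxon_annotation(cfg$paths$annotation)
    meta <- read_sample_metadata(cfg$paths$metadata, cfg$control)
    fmat <- read_function_table(cfg$paths$functions)
    if (!is.null(cfg$paths$domains))
      dmap <- utils::read.delim(cfg$paths$domains, header = TRUE, sep = "\t")
  }
  validate_community(comm)
  meta <- validate_metadata(meta, cfg$control)
  sizes <- unique(ann[, c("group", "domain", "body_size_um")])
  treatments <- setdiff(unique(meta$treatment), cfg$control)

  ## stage: coverage filter -------------------------------------------
  rel <- to_relative(comm)
  covr <- coverage_filter(rel, ann, cfg$coverage_threshold, domain_of = dmap)
  emit(covr$coverage, "coverage.tsv")

  ## stage: group aggregation -----------------------------------------
  grp <- aggregate_groups(rel, ann, groups = sizes$group, domain_of = dmap)
  emit(data.frame(sample_id = rownames(grp), grp, check.names = FALSE),
       "groups.tsv")

  ## stage: resistance + stability ------------------------------------
  resist <- do.call(rbind, lapply(treatments, function(tr)
    group_resistance(grp, meta, tr, cfg$control)))
  emit(resist, "resistance.tsv")
  stab <- group_stability(rel, grp, ann, meta)
  emit(stab, "stability.tsv")

  ## stage: diversity / niche / generalists ---------------------------
  ## classification uses the undisturbed (control) samples within each
  ## crop: the species-environment association across fields, not the
  ## disturbance response
  labels <- list()
  props <- list()
  for (cr in unique(meta$crop)) {
    ids <- meta$sample_id[meta$crop == cr & meta$treatment == cfg$control]
    sub <- community_table(unclass(comm)[ids, , drop = FALSE], "counts")
    lab <- classify_generalists(sub, n_perm = cfg$n_perm, ci = cfg$ci,
                                seed = cfg$seed + 11L)
    lab$crop <- cr
    labels[[cr]] <- lab
    props[[cr]] <- group_gs_proportions(lab[lab$taxon_id %in% ann$taxon_id, ],
                                        ann)
  }
  labels <- do.call(rbind, labels)
  emit(labels, "gs_labels.tsv")
  gs <- stats::aggregate(cbind(prop_generalists, prop_specialists) ~ group,
                         data = do.call(rbind, props), FUN = mean,
                         na.action = stats::na.omit)
  niche <- merge(niche_summary(comm, ann), gs, by = "group", all.x = TRUE,
                 sort = FALSE)
  emit(niche, "niche.tsv")

  ## stage: assembly (NCM + NST) --------------------------------------
  assembly <- NULL
  if (cfg$run_assembly) {
    assembly <- assembly_summary(comm, ann, meta, n_null = cfg$n_null,
                                 metric = cfg$metric, seed = cfg$seed + 23L)
    emit(assembly, "assembly.tsv")
  }

  ## stage: function linkage ------------------------------------------
  links_crop <- r_values(grp, fmat, meta, by_crop = TRUE)
  emit(links_crop, "links_by_crop.tsv")
  links <- r_values(grp, fmat, meta, by_crop = FALSE)
  emit(links, "links.tsv")
  dvals <- d_values(links, cfg$control)
  emit(dvals, "d_values.tsv")
  fcor <- do.call(rbind, lapply(unique(meta$treatment), function(tr)
    function_correlations(grp, fmat, meta, tr, by_crop = FALSE)))
  emit(fcor, "function_correlations.tsv")

  ## stage: size regressions ------------------------------------------
  reg <- size_regressions(resist, niche, links, dvals, sizes,
                          control = cfg$control)
  emit(reg, "regressions.tsv")

  manifest <- list(
    package = "sizestab",
    version = as.character(utils::packageVersion("sizestab")),
    config_hash = fnv1a(unclass(cfg)),
    seed = cfg$seed,
    seed_streams = list(synthesis = cfg$seed, gs_null = cfg$seed + 11L,
                        nst_null = cfg$seed + 23L),
    n_samples = nrow(comm), n_taxa = ncol(comm),
    n_groups = nrow(sizes),
    outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(manifest,
              list(tables = list(resistance = resist, stability = stab,
                                 niche = niche, assembly = assembly,
                                 links = links, links_by_crop = links_crop,
                                 d_values = dvals, regressions = reg,
                                 coverage = covr$coverage))))
}

#' Body-size regressions for every summary metric
#'
#' Collects the per-group metrics produced by the earlier stages and
#' regresses each on log10 body size: mean resistance per treatment
#' (averaged over crops), Shannon diversity, niche breadth, generalist
#' proportion, the control-stratum R value, and the mean D value across
#' treatments.
#'
#' @param resist output of [group_resistance()] (stacked treatments).
#' @param niche output of [niche_summary()] with proportion columns.
#' @param links output of [r_values()].
#' @param dvals output of [d_values()].
#' @param sizes data frame `group`, `body_size_um`.
#' @param control control treatment label.
#' @return data frame: `metric`, `treatment`, `slope`, `intercept`,
#'   `r2`, `p_value`, `n`.
#' @export
size_regressions <- function(resist, niche, links, dvals, sizes,
                             control = "control") {
  rows <- list()
  add <- function(metric, treatment, vec) {
    r <- tryCatch(size_regression(vec, sizes), error = function(e) NULL)
    if (is.null(r)) return()
    rows[[length(rows) + 1L]] <<- cbind(data.frame(metric = metric,
                                                   treatment = treatment), r)
  }
  for (tr in unique(resist$treatment)) {
    sub <- resist[resist$treatment == tr, ]
    m <- tapply(sub$rs_mean, sub$group, mean, na.rm = TRUE)
    add("resistance", tr, stats::setNames(as.vector(m), names(m)))
  }
  add("shannon", "all", stats::setNames(niche$shannon_mean, niche$group))
  add("breadth", "all", stats::setNames(niche$breadth_mean, niche$group))
  if ("prop_generalists" %in% names(niche))
    add("prop_generalists", "all",
        stats::setNames(niche$prop_generalists, niche$group))
  ctl <- links[links$treatment == control, ]
  rv <- tapply(ctl$r_value, ctl$group, mean, na.rm = TRUE)
  add("r_value", control, stats::setNames(as.vector(rv), names(rv)))
  dv <- tapply(dvals$d_value, dvals$group, mean, na.rm = TRUE)
  add("d_value", "all", stats::setNames(as.vector(dv), names(dv)))
  do.call(rbind, rows)
}
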