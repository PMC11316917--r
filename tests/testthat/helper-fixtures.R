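# small builders shared across test files

make_ct <- function(m, mode = "counts") {
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("t", seq_len(ncol(m)))
  community_table(m, mode)
}

# k taxa split over two groups in one domain, equal body sizes unless given
make_ann <- function(taxa, groups, domain = "bacteria", sizes = NULL) {
  if (is.null(sizes)) sizes <- stats::setNames(rep(1, length(unique(groups))),
                                               unique(groups))
  data.frame(taxon_id = taxa, domain = domain, group = groups,
             body_size_um = unname(sizes[groups]))
}

# paired design: n fields x (control + treatments), one crop
make_meta <- function(n_fields, treatments = c("control", "warming"),
                      crop = "maize") {
  meta <- expand.grid(field_id = sprintf("f%02d", seq_len(n_fields)),
                      treatment = treatments, stringsAsFactors = FALSE)
  meta$crop <- crop
  meta$sample_id <- paste(meta$crop, meta$field_id, meta$treatment, sep = "_")
  meta$env <- stats::rnorm(nrow(meta))
  meta[, c("sample_id", "field_id", "crop", "treatment", "env")]
}

# small synthetic study for pipeline tests: ~2 min of structure in seconds
small_synth <- list(
  n_fields = 6L,
  n_taxa_per_group = stats::setNames(
    round(10 - 6 * sizestab:::size_rank01(default_group_sizes()$body_size_um)),
    default_group_sizes()$group),
  depth = 4000,
  unannotated_taxa_frac = 0.2)
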