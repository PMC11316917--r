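#' Read a community table from TSV or BIOM
#'
#' The TSV dialect is fixed: samples in rows, taxa in columns, first
#' column named `sample_id`. BIOM files (JSON, format version 1) are
#' accepted as a secondary format through the biomformat package and are
#' transposed into the same samples x taxa orientation.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @return a counts-mode [community_table()].
#' @export
read_community <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # taxa x samples
    return(community_table(base::t(m), "counts"))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = NA)
  if (ncol(df) < 2 || names(df)[1] != "sample_id")
    stop("malformed header: first column must be 'sample_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    conv <- suppressWarnings(as.numeric(m))
    bad <- which(is.na(conv) & !is.na(m))[1]
    stop(sprintf("non-numeric abundance cell at row %d, column '%s'",
                 (bad - 1) %% nrow(m) + 1,
                 colnames(m)[(bad - 1) %/% nrow(m) + 1]))
  }
  rownames(m) <- as.character(df$sample_id)
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at sample '%s', taxon '%s'",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  community_table(m, "counts")
}

#' Write a community table as TSV
#'
#' Inverse of [read_community()]; the round trip is lossless.
#'
#' @param t a `community_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_community <- function(t, path) {
  stopifnot(is_community_table(t))
  df <- data.frame(sample_id = rownames(t), unclass(t), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_annotation <- function(ann) {
  need <- c("taxon_id", "domain", "group", "body_size_um")
  if (!all(need %in% names(ann)))
    stop(sprintf("annotation must have columns: %s", paste(need, collapse = ", ")))
  ann$taxon_id <- as.character(ann$taxon_id)
  ann$domain <- as.character(ann$domain)
  ann$group <- as.character(ann$group)
  if (anyDuplicated(ann$taxon_id)) stop("duplicated taxon_id in annotation")
  if (any(!is.finite(ann$body_size_um)) || any(ann$body_size_um <= 0))
    stop("body_size_um must be positive and finite (log10 must exist)")
  gd <- unique(ann[, c("group", "domain")])
  if (anyDuplicated(gd$group))
    stop("each organism group must map to exactly one domain")
  ann
}

#' Read a taxon annotation table
#'
#' TSV with columns `taxon_id`, `domain` (bacteria/fungi/protist),
#' `group` (one of the configured organism groups) and `body_size_um`
#' (characteristic linear dimension in micrometres).
#'
#' @param path file path.
#' @return validated data frame.
#' @export
read_taxon_annotation <- function(path) {
  validate_annotation(utils::read.delim(path, header = TRUE, sep = "\t"))
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `field_id`, `crop`, `treatment`, plus
#' any number of numeric environmental covariate columns. Enforces the
#' pairing requirement: every non-control sample's field must also have
#' a control sample within the same crop.
#'
#' @param path file path.
#' @param control label of the undisturbed treatment (default
#'   `"control"`).
#' @return validated data frame.
#' @export
read_sample_metadata <- function(path, control = "control") {
  meta <- utils::read.delim(path, header = TRUE, sep = "\t")
  validate_metadata(meta, control)
}

validate_metadata <- function(meta, control = "control") {
  need <- c("sample_id", "field_id", "crop", "treatment")
  if (!all(need %in% names(meta)))
    stop(sprintf("metadata must have columns: %s", paste(need, collapse = ", ")))
  for (cc in need) meta[[cc]] <- as.character(meta[[cc]])
  if (anyDuplicated(meta$sample_id)) stop("duplicated sample_id in metadata")
  key <- paste(meta$crop, meta$field_id, meta$treatment)
  if (anyDuplicated(key))
    stop("each (crop, field_id, treatment) may occur at most once")
  ctl <- meta[meta$treatment == control, ]
  trt <- meta[meta$treatment != control, ]
  orphan <- !(paste(trt$crop, trt$field_id) %in% paste(ctl$crop, ctl$field_id))
  if (any(orphan))
    stop(sprintf("treated samples without a paired control in their field: %s",
                 paste(utils::head(trt$sample_id[orphan], 5), collapse = ", ")))
  meta
}

#' Read a samples x functions table
#'
#' TSV with a `sample_id` column followed by numeric function columns
#' (by default the 11 measured soil functions).
#'
#' @param path file path.
#' @param n_functions expected number of function columns; `NULL` skips
#'   the check.
#' @return numeric matrix, samples in rows, functions in columns.
#' @export
read_function_table <- function(path, n_functions = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (names(df)[1] != "sample_id") stop("first column must be 'sample_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df$sample_id)
  if (!is.numeric(m)) stop("function columns must be numeric")
  if (!is.null(n_functions) && ncol(m) != n_functions)
    stop(sprintf("expected %d function columns, found %d", n_functions, ncol(m)))
  m
}

#' Default organism-group body-size table
#'
#' Returns the bundled lookup of 24 soil organism groups (12 bacterial,
#' 7 fungal, 5 protistan) with a characteristic body size in
#' micrometres. These sizes are synthetic, literature-plausible fixture
#' values meant for simulation and examples, not measurements; real
#' analyses should supply their own lookup.
#'
#' @return data frame with columns `group`, `domain`, `body_size_um`.
#' @export
default_group_sizes <- function() {
  path <- system.file("extdata", "group_sizes_synthetic.tsv", package = "sizestab")
  utils::read.delim(path, header = TRUE, sep = "\t")
}

#' Rarefy a counts table to even depth
#'
#' Optional utility; the pipeline's default normalization is relative
#' abundance, not rarefaction.
#'
#' @param t counts-mode `community_table`.
#' @param depth target depth; defaults to the minimum row sum.
#' @param seed integer seed for the subsampling.
#' @return counts-mode `community_table` with every row summing to
#'   `depth`; samples shallower than `depth` are dropped with a warning.
#' @export
rarefy_even <- function(t, depth = NULL, seed = 1L) {
  stopifnot(is_community_table(t), identical(ct_mode(t), "counts"))
  rs <- rowSums(t)
  if (is.null(depth)) depth <- min(rs)
  keep <- rs >= depth
  if (!all(keep))
    warning(sprintf("dropping %d samples shallower than %d", sum(!keep), depth))
  m <- unclass(t)[keep, , drop = FALSE]
  set.seed(seed)
  out <- base::t(apply(m, 1, function(row) {
    pool <- rep.int(seq_along(row), row)
    tabulate(sample(pool, depth), nbins = length(row))
  }))
  dimnames(out) <- dimnames(m)
  community_table(out, "counts")
}
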