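#' Construct a community table
#'
#' A community table is the universal exchange object of the package: a
#' numeric samples x taxa matrix of non-negative abundances, carrying a
#' `mode` attribute that records whether the cells are raw counts or
#' relative abundances (row proportions).
#'
#' @param values numeric matrix, samples in rows, taxa in columns; both
#'   dimensions must be named with unique identifiers.
#' @param mode `"counts"` or `"relative"`.
#' @return an object of class `community_table` (a matrix subclass).
#' @examples
#' m <- matrix(c(5, 0, 5, 10), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("t1", "t2")))
#' ct <- community_table(m, "counts")
#' @export
community_table <- function(values, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x taxa)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample (row) and taxon (column) names")
  x <- structure(values, mode_ct = mode, class = c("community_table", class(values)))
  validate_community(x)
  x
}

#' @rdname community_table
#' @param x object to test or validate.
#' @export
is_community_table <- function(x) inherits(x, "community_table")

ct_mode <- function(x) attr(x, "mode_ct")

#' Validate a community table
#'
#' Checks the structural invariants: no negative or non-finite entries,
#' unique sample and taxon identifiers, and (in relative mode) unit row
#' sums within 1e-9.
#'
#' @param x a `community_table`.
#' @return `x`, invisibly, if valid; otherwise an error naming the
#'   offending cells or identifiers.
#' @export
validate_community <- function(x) {
  stopifnot(is_community_table(x))
  if (anyNA(x) || any(!is.finite(x)))
    stop("community table contains missing or non-finite values")
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at sample '%s', taxon '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]))
  }
  if (anyDuplicated(rownames(x))) stop("duplicated sample identifiers")
  if (anyDuplicated(colnames(x))) stop("duplicated taxon identifiers")
  if (identical(ct_mode(x), "relative")) {
    rs <- rowSums(x)
    off <- which(abs(rs - 1) > 1e-9)
    if (length(off))
      stop(sprintf("relative-mode rows must sum to 1; first offender: '%s' (sum %.6g)",
                   rownames(x)[off[1]], rs[off[1]]))
  }
  invisible(x)
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d samples x %d taxa, mode = %s\n",
              nrow(x), ncol(x), ct_mode(x)))
  nr <- min(nrow(x), 6L); nc <- min(ncol(x), 6L)
  print(unclass(x)[seq_len(nr), seq_len(nc), drop = FALSE])
  if (nrow(x) > nr || ncol(x) > nc) cat("...\n")
  invisible(x)
}

#' Convert counts to relative abundance
#'
#' Divides every row by its total so each sample becomes a composition
#' summing to 1. Calling it on an already-relative table is an error, as
#' is a sample with zero total counts.
#'
#' @param t a counts-mode `community_table` with positive row sums.
#' @return a relative-mode `community_table`.
#' @export
to_relative <- function(t) {
  stopifnot(is_community_table(t))
  if (!identical(ct_mode(t), "counts"))
    stop("`to_relative()` expects a counts-mode table; input is already relative")
  rs <- rowSums(t)
  if (any(rs <= 0))
    stop(sprintf("sample '%s' has zero total count; cannot form proportions",
                 rownames(t)[which(rs <= 0)[1]]))
  community_table(unclass(t) / rs, "relative")
}

#' Aggregate taxa into organism groups
#'
#' Sums the relative abundances of member taxa into one column per
#' organism group. Taxa missing from the annotation are dropped (their
#' count is reported via a message), so group rows need not sum to 1.
#'
#' @param t a relative-mode `community_table`.
#' @param ann taxon annotation data frame with columns `taxon_id`,
#'   `domain`, `group`, `body_size_um` (see [read_taxon_annotation()]).
#' @param groups optional character vector fixing the group column order
#'   (groups absent from the table yield all-zero columns, with a warning).
#' @param relative_to `"domain"` (default) expresses each group as a
#'   share of its own domain's total in that sample, emulating
#'   marker-gene runs that are sequenced and normalized separately per
#'   domain; `"total"` keeps shares of the whole community.
#' @param domain_of optional data frame (`taxon_id`, `domain`) assigning
#'   a domain to every taxon, so that taxa outside the configured groups
#'   still count toward their domain's denominator; default: annotated
#'   taxa only.
#' @return a samples x groups matrix (plain matrix with a `dropped_taxa`
#'   attribute); cells are summed member proportions.
#' @export
aggregate_groups <- function(t, ann, groups = NULL,
                             relative_to = c("domain", "total"),
                             domain_of = NULL) {
  relative_to <- match.arg(relative_to)
  stopifnot(is_community_table(t))
  if (!identical(ct_mode(t), "relative"))
    stop("`aggregate_groups()` expects a relative-mode table")
  ann <- validate_annotation(ann)
  keep <- colnames(t) %in% ann$taxon_id
  n_drop <- sum(!keep)
  if (all(!keep)) stop("no taxon in the table is annotated")
  if (n_drop > 0)
    message(sprintf("aggregate_groups: dropped %d unannotated taxa", n_drop))
  sub <- unclass(t)[, keep, drop = FALSE]
  idx <- match(colnames(sub), ann$taxon_id)
  grp <- ann$group[idx]
  if (is.null(groups)) groups <- unique(ann$group)
  out <- matrix(0, nrow(sub), length(groups),
                dimnames = list(rownames(sub), groups))
  agg <- rowsum(base::t(sub), grp)           # groups x samples
  out[, rownames(agg)] <- base::t(agg)
  if (relative_to == "domain") {
    dom_of_grp <- ann$domain[match(colnames(out), ann$group)]
    if (is.null(domain_of)) {
      dom_tot <- rowsum(base::t(sub), ann$domain[idx])  # domains x samples
    } else {
      dkeep <- colnames(t) %in% domain_of$taxon_id
      dom_tot <- rowsum(base::t(unclass(t)[, dkeep, drop = FALSE]),
                        domain_of$domain[match(colnames(t)[dkeep],
                                               domain_of$taxon_id)])
    }
    den <- base::t(dom_tot)[, dom_of_grp, drop = FALSE]
    den[den <= 0] <- Inf                      # empty domain -> share 0
    out <- out / den
  }
  empty <- setdiff(groups, rownames(agg))
  if (length(empty))
    warning(sprintf("groups with no member taxa in the table: %s",
                    paste(empty, collapse = ", ")))
  attr(out, "dropped_taxa") <- n_drop
  out
}

#' Sequence-coverage group-selection filter
#'
#' Checks, per domain, what fraction of that domain's mean relative
#' abundance the configured organism groups capture. A domain passes
#' when the selected groups account for at least `threshold` of its
#' sequences (the study-design requirement behind restricting analysis
#' to well-covered groups).
#'
#' @param t a relative-mode `community_table` (full taxon resolution).
#' @param ann taxon annotation; taxa absent from `ann` count toward the
#'   domain total only if listed in `domain_of` (see below), otherwise
#'   they are outside every domain and ignored.
#' @param threshold required coverage fraction in (0, 1]; default 0.6.
#' @param domain_of optional data frame (`taxon_id`, `domain`) giving a
#'   domain for *every* taxon, so that unannotated (group-less) taxa
#'   still contribute to their domain's total abundance. When `NULL`
#'   the annotated taxa define the domain totals.
#' @return a list with `selected_groups` (character), and `coverage`, a
#'   data frame (`domain`, `coverage`, `passes`). Domains with no taxa
#'   are reported with `NA` coverage.
#' @export
coverage_filter <- function(t, ann, threshold = 0.6, domain_of = NULL) {
  stopifnot(is_community_table(t))
  if (!identical(ct_mode(t), "relative"))
    stop("`coverage_filter()` expects a relative-mode table")
  if (!(threshold > 0 && threshold <= 1)) stop("`threshold` must be in (0, 1]")
  ann <- validate_annotation(ann)
  mean_ab <- colMeans(unclass(t))

  if (is.null(domain_of)) {
    domain_of <- ann[, c("taxon_id", "domain")]
  }
  domain_of <- domain_of[domain_of$taxon_id %in% names(mean_ab), , drop = FALSE]
  domains <- unique(domain_of$domain)

  in_group <- names(mean_ab) %in% ann$taxon_id
  cov <- lapply(domains, function(d) {
    ids <- domain_of$taxon_id[domain_of$domain == d]
    tot <- sum(mean_ab[ids])
    if (length(ids) == 0L || tot <= 0)
      return(data.frame(domain = d, coverage = NA_real_, passes = NA))
    sel <- sum(mean_ab[ids[ids %in% ann$taxon_id]])
    data.frame(domain = d, coverage = sel / tot, passes = sel / tot >= threshold)
  })
  cov <- do.call(rbind, cov)
  list(selected_groups = unique(ann$group), coverage = cov)
}
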