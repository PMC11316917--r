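#' Orwin-Wardle resistance index
#'
#' Bounded index of how little a response variable changes under
#' disturbance relative to its paired control:
#' \deqn{RS = 1 - \frac{2|D_0|}{C_0 + |D_0|}, \quad D_0 = C_0 - P_0}
#' where `C0` is the control value and `P0` the disturbed value. RS is 1
#' when the response is unchanged, 0 when it is lost entirely, and
#' approaches -1 as the disturbed value grows without bound. The index
#' is invariant to a common rescaling of `(C0, P0)`.
#'
#' @param C0 control value(s), strictly positive.
#' @param P0 disturbed value(s), non-negative; recycled against `C0`.
#' @return numeric vector of RS values in (-1, 1].
#' @examples
#' orwin_wardle_rs(10, 5)    # 1/3
#' orwin_wardle_rs(10, 10)   # 1: no change
#' @export
orwin_wardle_rs <- function(C0, P0) {
  if (any(!is.finite(C0)) || any(!is.finite(P0)))
    stop("C0 and P0 must be finite")
  if (any(C0 <= 0)) stop("RS is undefined for C0 <= 0")
  if (any(P0 < 0)) stop("P0 must be non-negative")
  D0 <- C0 - P0
  1 - 2 * abs(D0) / (C0 + abs(D0))
}

#' Per-group community resistance from paired samples
#'
#' For each organism group and crop, computes the resistance index for
#' every field that has both a control sample and a sample of the given
#' treatment, using the group's relative abundance as the response
#' variable (`C0` = control abundance, `P0` = treated abundance in the
#' same field). Pairs whose control abundance is zero are skipped.
#'
#' @param groups samples x groups abundance matrix (relative scale), as
#'   returned by [aggregate_groups()].
#' @param meta sample metadata data frame (see [read_sample_metadata()]).
#' @param treatment treatment label to contrast against the control.
#' @param control control label, default `"control"`.
#' @return data frame with one row per group x crop: `group`, `crop`,
#'   `treatment`, `rs_mean`, `rs_sd`, `n_pairs`, `n_skipped`,
#'   `low_n` (TRUE when fewer than 3 valid pairs, also warned about),
#'   and a list-column `rs_per_pair`.
#' @export
group_resistance <- function(groups, meta, treatment, control = "control") {
  meta <- validate_metadata(meta, control)
  if (!treatment %in% meta$treatment)
    stop(sprintf("treatment '%s' not present in metadata", treatment))
  stopifnot(all(meta$sample_id %in% rownames(groups)) || {
    meta <- meta[meta$sample_id %in% rownames(groups), ]; TRUE
  })
  meta <- meta[meta$sample_id %in% rownames(groups), ]
  out <- list()
  for (crop in unique(meta$crop)) {
    ctl <- meta[meta$crop == crop & meta$treatment == control, ]
    trt <- meta[meta$crop == crop & meta$treatment == treatment, ]
    common <- intersect(ctl$field_id, trt$field_id)
    if (length(common) == 0L) next
    cs <- ctl$sample_id[match(common, ctl$field_id)]
    ts <- trt$sample_id[match(common, trt$field_id)]
    for (g in colnames(groups)) {
      C0 <- groups[cs, g]
      P0 <- groups[ts, g]
      ok <- C0 > 0
      rs <- if (any(ok)) orwin_wardle_rs(C0[ok], P0[ok]) else numeric(0)
      low <- length(rs) < 3L
      if (low)
        warning(sprintf("group '%s' (%s, %s): only %d valid pairs",
                        g, crop, treatment, length(rs)))
      out[[length(out) + 1L]] <- data.frame(
        group = g, crop = crop, treatment = treatment,
        rs_mean = if (length(rs)) mean(rs) else NA_real_,
        rs_sd = if (length(rs) > 1) stats::sd(rs) else NA_real_,
        n_pairs = length(rs), n_skipped = sum(!ok), low_n = low)
      out[[length(out)]]$rs_per_pair <- list(unname(rs))
    }
  }
  if (!length(out)) stop("no control/treatment field pairs found")
  do.call(rbind, out)
}

#' Abundance-weighted tolerance width
#'
#' Spread of an environmental covariate weighted by where a group's
#' abundance mass sits:
#' \deqn{W = \sqrt{\sum_j a_j (e_j - \bar e)^2 / \sum_j a_j}},
#' with \eqn{\bar e} the abundance-weighted mean of the covariate. A
#' wide W means the group maintains abundance across a wide range of
#' conditions; W is invariant to rescaling all abundances.
#'
#' @param abund non-negative abundance vector over samples.
#' @param env environmental covariate, same length, finite.
#' @return non-negative scalar (units of `env`).
#' @export
tolerance_width <- function(abund, env) {
  if (length(abund) != length(env)) stop("`abund` and `env` lengths differ")
  if (any(!is.finite(env))) stop("`env` must be finite")
  if (any(abund < 0)) stop("`abund` must be non-negative")
  tot <- sum(abund)
  if (tot <= 0) stop("tolerance width undefined: all abundances are zero")
  w <- abund / tot
  ebar <- sum(w * env)
  sqrt(sum(w * (env - ebar)^2))
}

#' Nonsynchronization of member responses
#'
#' One minus the Loreau-de Mazancourt community synchrony statistic
#' \deqn{\varphi = \mathrm{Var}(\sum_i x_i) / (\sum_i \mathrm{SD}(x_i))^2,}
#' computed over a taxa x conditions response matrix. The result lies in
#' \[0, 1\]: 0 when all member taxa move perfectly in proportion, 1 when
#' they cancel so the aggregate is constant. High nonsynchronization
#' means asynchronous member responses buffer the community aggregate.
#'
#' @param responses numeric matrix, member taxa in rows, disturbance
#'   conditions in columns (at least 2 columns).
#' @return scalar in \[0, 1\].
#' @export
nonsynchronization <- function(responses) {
  if (!is.matrix(responses) || ncol(responses) < 2L)
    stop("`responses` must be a matrix with at least 2 condition columns")
  sds <- apply(responses, 1, stats::sd)
  if (all(sds == 0)) stop("nonsynchronization undefined: all taxa constant")
  phi <- stats::var(colSums(responses)) / sum(sds)^2
  1 - min(max(phi, 0), 1)
}

#' Per-group stability summary: tolerance width and nonsynchronization
#'
#' Tolerance width is computed from the group's abundance across all
#' samples against one environmental covariate. Nonsynchronization is
#' computed per field from the member-taxon abundances across the
#' ordered disturbance conditions, then averaged over fields (fields
#' lacking a full set of conditions or with all-constant members are
#' skipped).
#'
#' @param t relative-mode `community_table` (taxon resolution).
#' @param groups samples x groups matrix from [aggregate_groups()].
#' @param ann taxon annotation.
#' @param meta sample metadata.
#' @param env_var name of the metadata column holding the covariate
#'   (default: first numeric non-identifier column).
#' @param treatment_order condition order used for the response matrix;
#'   default: control first, then the remaining treatments in their
#'   order of appearance.
#' @return data frame: `group`, `tolerance_width`, `nonsynchronization`,
#'   `n_fields_sync`.
#' @export
group_stability <- function(t, groups, ann, meta, env_var = NULL,
                            treatment_order = NULL) {
  stopifnot(is_community_table(t))
  meta <- validate_metadata(meta)
  if (is.null(env_var)) {
    numcols <- names(meta)[vapply(meta, is.numeric, logical(1))]
    if (!length(numcols)) stop("metadata has no numeric covariate column")
    env_var <- numcols[1]
  }
  if (is.null(treatment_order))
    treatment_order <- unique(c("control", meta$treatment))
  ann <- validate_annotation(ann)
  meta <- meta[meta$sample_id %in% rownames(t), ]
  env <- meta[[env_var]][match(rownames(groups), meta$sample_id)]

  res <- lapply(colnames(groups), function(g) {
    wide <- tolerance_width(groups[meta$sample_id, g],
                            meta[[env_var]])
    members <- ann$taxon_id[ann$group == g]
    members <- intersect(members, colnames(t))
    vals <- numeric(0)
    for (crop in unique(meta$crop)) for (f in unique(meta$field_id[meta$crop == crop])) {
      sel <- meta[meta$crop == crop & meta$field_id == f, ]
      sel <- sel[match(treatment_order, sel$treatment), ]
      if (anyNA(sel$sample_id)) next
      m <- base::t(unclass(t)[sel$sample_id, members, drop = FALSE])
      if (all(apply(m, 1, stats::sd) == 0)) next
      vals <- c(vals, nonsynchronization(m))
    }
    data.frame(group = g, tolerance_width = wide,
               nonsynchronization = if (length(vals)) mean(vals) else NA_real_,
               n_fields_sync = length(vals))
  })
  do.call(rbind, res)
}
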