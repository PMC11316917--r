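#' Ecosystem multifunctionality (averaged z-scores)
#'
#' Standardizes each function across samples to zero mean and unit SD,
#' then averages the z-scores per sample. Functions with zero variance
#' carry no information and are dropped with a warning.
#'
#' @param f samples x functions numeric matrix (>= 2 samples).
#' @return named numeric vector, one multifunctionality value per
#'   sample; mean 0 across samples when no function was dropped.
#' @export
multifunctionality <- function(f) {
  if (!is.matrix(f) || nrow(f) < 2L)
    stop("`f` must be a samples x functions matrix with >= 2 samples")
  sds <- apply(f, 2, stats::sd)
  if (all(sds == 0)) stop("all functions are constant; multifunctionality undefined")
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant function(s): %s", sum(sds == 0),
                    paste(colnames(f)[sds == 0], collapse = ", ")))
    f <- f[, sds > 0, drop = FALSE]
  }
  z <- scale(f)
  stats::setNames(rowMeans(z), rownames(f))
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' The coefficient is the Pearson correlation of mid-ranks (ties get
#' average ranks). The p-value uses the t approximation with n - 2
#' degrees of freedom; for n <= 9 an exact two-sided permutation
#' p-value is computed by full enumeration of rank permutations.
#'
#' @param x,y numeric vectors of equal length, n >= 4.
#' @return list with `rho` and `p`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ")
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("Spearman correlation undefined: zero variance in ranks")
  rho <- stats::cor(rx, ry)
  if (n <= 9L) {
    perms <- all_permutations(n)                 # n! x n index matrix
    sx <- (rx - mean(rx)) / stats::sd(rx)
    sy <- (ry - mean(ry)) / stats::sd(ry)
    rho_null <- as.vector(matrix(sx[perms], nrow(perms)) %*% sy) / (n - 1)
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- if (abs(rho) >= 1) 0 else 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p)
}

# all permutations of 1..n as an n! x n matrix (n <= 9)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- k
    out[rows, -1] <- ifelse(sub >= k, sub + 1L, sub)
  }
  out
}

#' Group-multifunctionality correlations (R values)
#'
#' Within every (crop, treatment) stratum, correlates each organism
#' group's relative abundance with the multifunctionality index across
#' that stratum's samples (Spearman). This R value measures how tightly
#' a group of a given body size is linked to ecosystem functioning
#' under that condition.
#'
#' @param groups samples x groups abundance matrix.
#' @param f samples x functions matrix (same sample ids).
#' @param meta sample metadata.
#' @param by_crop analyse crops separately (default) or pooled.
#' @return data frame of link records: `group`, `crop`, `treatment`,
#'   `r_value`, `p_value`, `n`.
#' @export
r_values <- function(groups, f, meta, by_crop = TRUE) {
  meta <- validate_metadata(meta)
  common <- intersect(rownames(groups), rownames(f))
  common <- intersect(common, meta$sample_id)
  meta <- meta[match(common, meta$sample_id), ]
  crops <- if (by_crop) unique(meta$crop) else "all"
  out <- list()
  for (crop in crops) for (tr in unique(meta$treatment)) {
    ids <- meta$sample_id[meta$treatment == tr &
                            (!by_crop | meta$crop == crop)]
    if (length(ids) < 4L)
      stop(sprintf("stratum (%s, %s) has fewer than 4 samples", crop, tr))
    mf <- multifunctionality(f[ids, , drop = FALSE])
    for (g in colnames(groups)) {
      ab <- groups[ids, g]
      rec <- data.frame(group = g, crop = crop, treatment = tr,
                        r_value = NA_real_, p_value = NA_real_,
                        n = length(ids))
      if (stats::sd(rank(ab)) > 0) {
        sr <- spearman_rho(ab, mf)
        rec$r_value <- sr$rho; rec$p_value <- sr$p
      } else {
        message(sprintf("group '%s' constant in stratum (%s, %s); R value missing",
                        g, crop, tr))
      }
      out[[length(out) + 1L]] <- rec
    }
  }
  do.call(rbind, out)
}

#' Per-function Spearman correlations (heat-map matrix)
#'
#' Correlates every organism group with every single function within a
#' stratum; the long-format output mirrors a groups x functions
#' correlation heat map. No multiple-testing adjustment is applied by
#' default (the map is descriptive); `adjust = "BH"` applies
#' Benjamini-Hochberg across all cells.
#'
#' @param groups samples x groups matrix.
#' @param f samples x functions matrix.
#' @param meta sample metadata.
#' @param treatment stratum treatment label.
#' @param by_crop analyse crops separately (default) or pooled.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return long data frame: `group`, `crop`, `treatment`, `fun`, `rho`,
#'   `p_value`.
#' @export
function_correlations <- function(groups, f, meta, treatment,
                                  by_crop = TRUE, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  meta <- validate_metadata(meta)
  crops <- if (by_crop) unique(meta$crop) else "all"
  out <- list()
  for (crop in crops) {
    ids <- meta$sample_id[meta$treatment == treatment &
                            (!by_crop | meta$crop == crop)]
    ids <- intersect(ids, intersect(rownames(groups), rownames(f)))
    for (g in colnames(groups)) for (fn in colnames(f)) {
      ab <- groups[ids, g]; y <- f[ids, fn]
      if (stats::sd(rank(ab)) == 0 || stats::sd(rank(y)) == 0) next
      sr <- spearman_rho(ab, y)
      out[[length(out) + 1L]] <- data.frame(
        group = g, crop = crop, treatment = treatment, fun = fn,
        rho = sr$rho, p_value = sr$p)
    }
  }
  out <- do.call(rbind, out)
  if (adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out
}

#' D values: treatment-induced change in function linkage
#'
#' For each group, crop and non-control treatment, the D value is the
#' R value in the treated stratum minus the R value in the control
#' stratum. Positive D means the group's link to multifunctionality
#' strengthened under disturbance.
#'
#' @param links output of [r_values()].
#' @param control control treatment label.
#' @return data frame: `group`, `crop`, `treatment`, `d_value`.
#' @export
d_values <- function(links, control = "control") {
  ctl <- links[links$treatment == control, ]
  trt <- links[links$treatment != control, ]
  key <- paste(trt$group, trt$crop)
  ckey <- paste(ctl$group, ctl$crop)
  if (!all(key %in% ckey))
    stop(sprintf("missing control R value for: %s",
                 paste(utils::head(unique(key[!key %in% ckey]), 5), collapse = ", ")))
  data.frame(group = trt$group, crop = trt$crop, treatment = trt$treatment,
             d_value = trt$r_value - ctl$r_value[match(key, ckey)])
}

#' Ordinary least-squares regression of a group metric on log body size
#'
#' The workhorse behind every size-trend panel: regresses a per-group
#' metric on log10 body size (micrometres) by OLS and reports the
#' slope, intercept, r-squared and the two-sided t-test p-value for the
#' slope (n - 2 degrees of freedom).
#'
#' @param metric named numeric vector (names = groups), or a data frame
#'   with columns `group` and `value`.
#' @param sizes data frame with columns `group` and `body_size_um`
#'   (e.g. [default_group_sizes()] or a taxon annotation collapsed to
#'   groups).
#' @return one-row data frame: `slope`, `intercept`, `r2`, `p_value`,
#'   `n`.
#' @export
size_regression <- function(metric, sizes) {
  if (is.data.frame(metric))
    metric <- stats::setNames(metric$value, metric$group)
  sz <- stats::setNames(sizes$body_size_um, sizes$group)
  groups <- intersect(names(metric)[is.finite(metric)], names(sz))
  if (length(groups) < 3L) stop("need >= 3 groups with finite metric and size")
  x <- log10(sz[groups]); y <- metric[groups]
  if (stats::sd(x) == 0) stop("zero variance in log10 body size")
  if (stats::sd(y) == 0)                      # flat response: no trend
    return(data.frame(slope = 0, intercept = y[[1]], r2 = 0,
                      p_value = NA_real_, n = length(groups)))
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  data.frame(slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             r2 = s$r.squared,
             p_value = unname(s$coefficients[2, 4]),
             n = length(groups))
}
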