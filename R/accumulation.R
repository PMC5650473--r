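#' Distribution summary of log2 ratios in one sorted fraction
#'
#' The per-fraction statistics behind the violin ("neeps") display:
#' median, quartiles and IQR of the log2 ratios measured in a fraction.
#' Quartiles use linear interpolation (R's type-7 convention) for
#' determinism.
#'
#' @param x A [profile_matrix()].
#' @param fraction Fraction label.
#' @param replicate Optional replicate index; default pools all replicates.
#' @return One-row data frame: `fraction`, `n`, `q1`, `median`, `q3`,
#'   `iqr` (all on the log2 scale).
#' @export
fraction_distribution_summary <- function(x, fraction, replicate = NULL) {
  stopifnot(inherits(x, "profile_matrix"))
  keep <- x$fractions == fraction
  if (!is.null(replicate)) keep <- keep & x$replicates == replicate
  if (!any(keep)) stop("empty fraction: ", fraction, call. = FALSE)
  v <- log2(x$ratios[, keep])
  v <- v[!is.na(v)]
  if (length(v) < 4) {
    stop("need >= 4 values to summarise fraction ", fraction, call. = FALSE)
  }
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(fraction = fraction, n = length(v),
             q1 = q[1], median = q[2], q3 = q[3], iqr = q[3] - q[1])
}

#' Bulk mean accumulation profile
#'
#' The mean log2 ratio across all proteins, per fraction, with standard
#' errors — the population-level accumulation signal. Means are
#' available-case (missing values ignored per fraction). The reference
#' fraction's mean is subtracted (log scale), anchoring the profile at the
#' reference.
#'
#' @param x A [profile_matrix()] or a proteins x fractions median matrix.
#' @param reference_fraction Fraction used as the log2 zero point; default
#'   the first fraction.
#' @return Data frame: `fraction`, `n`, `mean_log2` (raw), `sem`,
#'   `mean_log2_rel` (reference-anchored), `ratio_rel` (linear).
#' @export
bulk_mean_profile <- function(x, reference_fraction = NULL) {
  med <- if (inherits(x, "profile_matrix")) replicate_median_profile(x) else x
  if (is.null(reference_fraction)) reference_fraction <- colnames(med)[1]
  lm2 <- log2(med)
  n <- colSums(!is.na(lm2))
  mu <- colMeans(lm2, na.rm = TRUE)
  sem <- apply(lm2, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    stats::sd(v) / sqrt(length(v))
  })
  rel <- mu - mu[reference_fraction]
  data.frame(fraction = colnames(med), n = n, mean_log2 = mu, sem = sem,
             mean_log2_rel = rel, ratio_rel = 2^rel, row.names = NULL)
}

#' Fit the exponential growth model to a bulk accumulation profile
#'
#' Least-squares fit of `y = e^(m x)` on the log scale: `ln(y)` is
#' regressed on `x = t - anchor_time` with no intercept, because the
#' profile is normalized to its reference fraction (ratio 1 at the
#' reference position). `anchor_time` defaults to the first timepoint,
#' i.e. the reference fraction's position on the timeline; pass
#' `anchor_time = 0` for data anchored at division. `fold_over_cycle` is
#' `exp(m)`, the factor by which content grows over one unit of normalized
#' time; a doubling proteome gives `m = ln 2` and fold 2.0. R^2 is the
#' squared Pearson correlation between `ln(y)` and `x` (1 for an exact
#' fit, including the degenerate all-constant case).
#'
#' @param t Normalized cell-cycle positions.
#' @param y Linear mean ratios at those positions (> 0).
#' @param anchor_time Time at which the model equals 1.
#' @return A `growth_fit` list: `m`, `r2`, `fold_over_cycle`, `data`.
#' @export
fit_exponential <- function(t, y, anchor_time = t[1]) {
  if (length(t) != length(y) || length(t) < 3) {
    stop("need >= 3 (t, y) points", call. = FALSE)
  }
  if (any(y <= 0)) stop("`y` must be positive", call. = FALSE)
  x <- t - anchor_time
  ly <- log(y)
  m <- sum(x * ly) / sum(x^2)
  resid <- ly - m * x
  r2 <- if (all(abs(resid) < 1e-12)) 1 else stats::cor(x, ly)^2
  structure(list(m = m, r2 = r2, fold_over_cycle = exp(m),
                 data = data.frame(t = t, y = y, x = x)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Exponential growth fit: m = %.4f, fold over cycle = %.3f, R2 = %.4f\n",
              x$m, x$fold_over_cycle, x$r2))
  invisible(x)
}

#' Mean profiles of annotation groups
#'
#' Averages the replicate-median profiles of all proteins carrying each
#' annotation label (the heatmap of functional-group dynamics). Means are
#' available-case per fraction.
#'
#' @param med Proteins x fractions median matrix (from
#'   [replicate_median_profile()]).
#' @param labels Character vector of annotation labels, named by protein
#'   identifier, or a list mapping label -> protein ids.
#' @return Data frame: one row per label x fraction with `mean_ratio` and
#'   membership count `n_members`.
#' @export
group_mean_profiles <- function(med, labels) {
  if (!is.list(labels)) {
    labels <- split(names(labels), unname(labels))
  }
  rows <- lapply(names(labels), function(lab) {
    ids <- labels[[lab]]
    missing_ids <- setdiff(ids, rownames(med))
    if (length(missing_ids)) {
      stop("unknown proteins for label '", lab, "': ",
           paste(utils::head(missing_ids, 5), collapse = ", "),
           call. = FALSE)
    }
    sub <- med[ids, , drop = FALSE]
    data.frame(label = lab, fraction = colnames(med),
               mean_ratio = colMeans(sub, na.rm = TRUE),
               n_members = length(ids), row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Max/min fold change of each protein's median profile
#'
#' For every protein, the ratio of the largest to the smallest fraction
#' value of its replicate-median profile (>= 1 by construction), with the
#' fractions at which the extremes occur. Proteins quantified in fewer
#' than two fractions get `NA`.
#'
#' @param med Proteins x fractions median matrix.
#' @return Data frame: `protein_id`, `fold`, `max_fraction`,
#'   `min_fraction`, `n_fractions`.
#' @export
per_protein_fold <- function(med) {
  res <- lapply(seq_len(nrow(med)), function(i) {
    v <- med[i, ]
    ok <- !is.na(v)
    if (sum(ok) < 2) {
      return(data.frame(protein_id = rownames(med)[i], fold = NA_real_,
                        max_fraction = NA_character_,
                        min_fraction = NA_character_,
                        n_fractions = sum(ok)))
    }
    v <- v[ok]
    data.frame(protein_id = rownames(med)[i],
               fold = max(v) / min(v),
               max_fraction = names(v)[which.max(v)],
               min_fraction = names(v)[which.min(v)],
               n_fractions = length(v))
  })
  do.call(rbind, res)
}
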