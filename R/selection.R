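#' Selection configuration
#'
#' Parameters of the significance procedure for cell-cycle-regulated
#' proteins: the Z multiplier of the max-fold-change cutoff (1.96 for 95%
#' confidence), the ANOVA p-value cutoff (0.05, interphase design), the
#' replicate-correlation rule (Pearson, at least `min_positive_pairs`
#' positive pairs; mitotic design) and an optional BH-FDR correction of
#' the ANOVA p-values (off by default — the published cutoff is an
#' uncorrected 0.05).
#'
#' @param design `"interphase"` (G1/S/G2/M, ANOVA secondary criterion) or
#'   `"mitotic"` (Pro/PM1/PM2/Ana, replicate-correlation secondary
#'   criterion).
#' @param z_multiplier Z-score multiplier of the fold cutoff.
#' @param p_cutoff ANOVA p-value cutoff.
#' @param min_positive_pairs Minimum number of positively correlated
#'   replicate pairs required to pass.
#' @param fdr Apply BH correction to ANOVA p-values before the cutoff.
#' @return A `selection_config` list.
#' @export
selection_config <- function(design = c("interphase", "mitotic"),
                             z_multiplier = 1.96, p_cutoff = 0.05,
                             min_positive_pairs = 1, fdr = FALSE) {
  design <- match.arg(design)
  if (z_multiplier <= 0) stop("`z_multiplier` must be > 0", call. = FALSE)
  if (p_cutoff <= 0 || p_cutoff >= 1) {
    stop("`p_cutoff` must lie in (0, 1)", call. = FALSE)
  }
  structure(list(design = design, z_multiplier = z_multiplier,
                 p_cutoff = p_cutoff,
                 min_positive_pairs = as.integer(min_positive_pairs),
                 fdr = isTRUE(fdr)),
            class = "selection_config")
}

#' Max fold change of a median profile
#'
#' `max/min` of the non-missing fraction values, linear space. Needs at
#' least two quantified fractions.
#'
#' @param profile Numeric vector (one protein's replicate-median profile).
#' @return Fold change >= 1, or `NA` if fewer than two fractions present.
#' @export
max_fold_change <- function(profile) {
  v <- profile[!is.na(profile)]
  if (length(v) < 2) return(NA_real_)
  max(v) / min(v)
}

#' Z-score fold-change cutoff
#'
#' The significance threshold on max fold changes: fold changes are
#' log2-transformed and the cutoff is `median + z * sd` on that scale,
#' returned in fold units. Applied one-sided upward, since max/min folds
#' are bounded below by 1 (the lower cutoff `median - z*sd` selects
#' nothing). With zero variance the threshold degenerates to the median
#' and is flagged.
#'
#' @param folds Max fold changes (>= 1), `NA`s ignored.
#' @param z_multiplier Z multiplier, default 1.96.
#' @return Threshold in fold units, with attribute `"degenerate"` when the
#'   fold distribution has zero variance.
#' @export
zscore_cutoff <- function(folds, z_multiplier = 1.96) {
  lf <- log2(folds[!is.na(folds)])
  if (length(lf) < 3) stop("need >= 3 fold values", call. = FALSE)
  s <- stats::sd(lf)
  if (s == 0) {
    thr <- 2^stats::median(lf)
    attr(thr, "degenerate") <- TRUE
    return(thr)
  }
  thr <- 2^(stats::median(lf) + z_multiplier * s)
  attr(thr, "degenerate") <- FALSE
  thr
}

#' One-way ANOVA across biological replicates
#'
#' Tests whether a protein's log2 ratios differ between sorted fractions,
#' treating replicates as observations within each fraction group.
#' Following the published procedure, proteins with any missing value are
#' excluded from testing rather than tested on partial data.
#'
#' @param profile_by_rep Numeric matrix, fractions x replicates, of linear
#'   ratios for one protein.
#' @return List: `p` (p-value, `NA` if excluded), `excluded` (logical),
#'   `reason`.
#' @export
anova_across_replicates <- function(profile_by_rep) {
  m <- as.matrix(profile_by_rep)
  if (anyNA(m)) {
    return(list(p = NA_real_, excluded = TRUE, reason = "excluded (missing)"))
  }
  df <- data.frame(
    y = log2(as.vector(m)),
    fraction = factor(rep(rownames(m) %||% seq_len(nrow(m)),
                          times = ncol(m)))
  )
  if (stats::var(df$y) == 0) {
    # no variance at all: F undefined; no evidence of between-group change
    return(list(p = 1, excluded = FALSE, reason = "no variance"))
  }
  fit <- stats::aov(y ~ fraction, data = df)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  list(p = p, excluded = FALSE, reason = "tested")
}

#' Pairwise replicate-correlation criterion
#'
#' Pearson correlations between all replicate pairs of a protein's log2
#' profile across the sorted fractions. The protein passes when at least
#' `min_positive_pairs` pairs correlate positively — i.e. the abundance
#' pattern reproduces across biological replicates. Pairs with fewer than
#' three shared fractions or a constant profile are skipped (`NA`).
#'
#' @param profile_by_rep Numeric matrix, fractions x replicates, linear
#'   ratios.
#' @param min_positive_pairs Pairs required, default 1.
#' @return List: `pass`, `r` (named pairwise correlations), `n_positive`.
#' @export
replicate_correlation_criterion <- function(profile_by_rep,
                                            min_positive_pairs = 1) {
  m <- log2(as.matrix(profile_by_rep))
  nrep <- ncol(m)
  if (nrep < 2) stop("need >= 2 replicates", call. = FALSE)
  pairs <- utils::combn(nrep, 2)
  r <- apply(pairs, 2, function(ij) {
    a <- m[, ij[1]]; b <- m[, ij[2]]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3) return(NA_real_)
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(NA_real_)
    stats::cor(a[ok], b[ok])
  })
  names(r) <- apply(pairs, 2, function(ij) paste0("r", ij[1], ij[2]))
  n_pos <- sum(r > 0, na.rm = TRUE)
  list(pass = n_pos >= min_positive_pairs, r = r, n_positive = n_pos)
}

#' Reproducible-missing-value rescue rule
#'
#' A protein missing in the *same single fraction in every replicate*, and
#' quantified in all other fraction x replicate cells, is rescued: absence
#' reproducing in one fraction is more plausibly physiological
#' down-regulation below the detection limit than stochastic
#' data-dependent-acquisition dropout. Rescued proteins join the candidate
#' list but are excluded from clustering (k-means cannot take missing
#' values).
#'
#' @param x A [profile_matrix()] with >= 2 replicates.
#' @return Data frame: `protein_id`, `missing_fraction`.
#' @export
missing_value_rescue <- function(x) {
  stopifnot(inherits(x, "profile_matrix"))
  if (length(unique(x$replicates)) < 2) {
    stop("rescue rule needs >= 2 replicates", call. = FALSE)
  }
  fr <- unique(x$fractions)
  out <- lapply(seq_len(nrow(x$ratios)), function(i) {
    present <- !is.na(x$ratios[i, ])
    # fraction-level presence: all replicates present / all absent?
    by_fr <- vapply(fr, function(f) {
      p <- present[x$fractions == f]
      if (all(p)) 1L else if (!any(p)) -1L else 0L
    }, integer(1))
    if (sum(by_fr == -1L) == 1 && all(by_fr[by_fr != -1L] == 1L)) {
      data.frame(protein_id = rownames(x$ratios)[i],
                 missing_fraction = fr[by_fr == -1L])
    } else {
      NULL
    }
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(),
                      missing_fraction = character())
  }
  out
}

#' Select cell-cycle-regulated candidate proteins
#'
#' The full significance procedure:
#' 1. replicate-median profile per protein; max fold change across
#'    fractions;
#' 2. one-sided Z-score cutoff on the log2 fold-change distribution
#'    (median + 1.96 sd by default);
#' 3. design-specific secondary criterion — one-way ANOVA p < 0.05 across
#'    replicates (interphase) or a positive Pearson correlation between at
#'    least one replicate pair (mitotic);
#' 4. reproducible-missing-value rescue.
#'
#' Proteins missing in any fraction of the median profile are not
#' eligible for the fold test (the published procedure discards them
#' before fold-change ranking) but remain visible to the rescue rule.
#'
#' @param x A normalized [profile_matrix()].
#' @param config A [selection_config()].
#' @return A `selection_verdicts` data frame: one row per protein with
#'   `max_fold_change`, `z_threshold`, the secondary-criterion statistics,
#'   `passes_fold`, `passes_second`, `rescued`, `significant` and a
#'   machine-readable `reason` trace. The realized fold threshold is also
#'   attached as attribute `"z_threshold"`.
#' @export
select_candidates <- function(x, config) {
  stopifnot(inherits(x, "profile_matrix"),
            inherits(config, "selection_config"))
  med <- replicate_median_profile(x)
  complete <- !apply(is.na(med), 1, any)
  folds <- apply(med, 1, max_fold_change)
  folds[!complete] <- NA_real_
  thr <- zscore_cutoff(folds, config$z_multiplier)

  fr <- unique(x$fractions)
  reps <- sort(unique(x$replicates))
  ids <- rownames(x$ratios)
  n <- length(ids)

  passes_fold <- !is.na(folds) & folds > thr
  second_stat <- rep(NA_real_, n)
  passes_second <- rep(NA, n)
  reason <- character(n)

  anova_p_adj <- NULL
  if (config$design == "interphase") {
    praw <- vapply(seq_len(n), function(i) {
      m <- t(vapply(fr, function(f) {
        vapply(reps, function(r) {
          x$ratios[i, x$fractions == f & x$replicates == r][1]
        }, numeric(1))
      }, numeric(length(reps))))
      rownames(m) <- fr
      anova_across_replicates(m)$p
    }, numeric(1))
    anova_p_adj <- if (config$fdr) stats::p.adjust(praw, "BH") else praw
    second_stat <- praw
    passes_second <- !is.na(anova_p_adj) & anova_p_adj < config$p_cutoff
  } else {
    for (i in seq_len(n)) {
      m <- vapply(reps, function(r) {
        vapply(fr, function(f) {
          x$ratios[i, x$fractions == f & x$replicates == r][1]
        }, numeric(1))
      }, numeric(length(fr)))
      cc <- tryCatch(replicate_correlation_criterion(
        m, config$min_positive_pairs),
        error = function(e) list(pass = NA, r = NA_real_, n_positive = NA))
      second_stat[i] <- suppressWarnings(max(cc$r, na.rm = TRUE))
      if (!is.finite(second_stat[i])) second_stat[i] <- NA_real_
      passes_second[i] <- isTRUE(cc$pass)
    }
  }

  rescue <- missing_value_rescue(x)
  rescued <- ids %in% rescue$protein_id

  significant <- (passes_fold & passes_second %in% TRUE) | rescued
  for (i in seq_len(n)) {
    reason[i] <- if (rescued[i]) {
      "rescued: reproducibly missing in a single fraction"
    } else if (!complete[i]) {
      "excluded: missing fraction in median profile"
    } else if (!passes_fold[i]) {
      "fold below threshold"
    } else if (!isTRUE(passes_second[i])) {
      if (config$design == "interphase") "fold pass; ANOVA fail"
      else "fold pass; no positively correlated replicate pair"
    } else {
      "significant: fold and secondary criterion"
    }
  }

  thr_value <- as.vector(thr)  # strip the degeneracy flag attribute
  out <- data.frame(
    protein_id = ids,
    max_fold_change = folds,
    z_threshold = thr_value,
    second_statistic = second_stat,
    passes_fold = passes_fold,
    passes_second = passes_second,
    rescued = rescued,
    significant = significant,
    reason = reason,
    stringsAsFactors = FALSE, row.names = NULL
  )
  names(out)[names(out) == "second_statistic"] <-
    if (config$design == "interphase") "anova_p" else "max_pairwise_r"
  attr(out, "z_threshold") <- thr_value
  attr(out, "design") <- config$design
  class(out) <- c("selection_verdicts", "data.frame")
  out
}
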