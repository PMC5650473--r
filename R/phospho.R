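#' Classify mitotic phosphorylation sites as early or late risers
#'
#' Among sites whose phosphorylation peaks in mitosis, an "early riser" is
#' already significantly elevated in the G2-enriched fraction: its mean
#' G2 log2 ratio exceeds the interphase baseline (G1 and S values across
#' replicates) by `k_sd` baseline standard deviations. Sites peaking in M
#' without the G2 elevation are "late risers"; non-significant sites are
#' excluded; sites lacking a G2 value are unclassifiable and flagged.
#'
#' @param x A [profile_matrix()] of site quantitation (linear ratios).
#' @param significant Logical vector (named by site id or in row order):
#'   which sites passed the significance screen.
#' @param baseline_fractions Fractions forming the interphase baseline.
#' @param g2_fraction,m_fraction The G2-enriched and mitotic fractions.
#' @param k_sd Baseline standard deviations required for "significantly
#'   increased in G2" (default 2).
#' @return Data frame: `site_id`, `label` (early/late/excluded/
#'   unclassifiable), `g2_mean_log2`, `baseline_mean_log2`,
#'   `baseline_sd_log2`, `peaks_in_m`.
#' @export
classify_early_risers <- function(x, significant,
                                  baseline_fractions = c("G1", "S"),
                                  g2_fraction = "G2", m_fraction = "M",
                                  k_sd = 2) {
  stopifnot(inherits(x, "profile_matrix"))
  ids <- rownames(x$ratios)
  if (!is.null(names(significant))) significant <- significant[ids]
  lm2 <- log2(x$ratios)
  base_cols <- x$fractions %in% baseline_fractions
  g2_cols <- x$fractions == g2_fraction
  m_cols <- x$fractions == m_fraction
  fr <- unique(x$fractions)

  out <- lapply(seq_along(ids), function(i) {
    row <- lm2[i, ]
    rec <- data.frame(site_id = ids[i], label = "excluded",
                      g2_mean_log2 = NA_real_, baseline_mean_log2 = NA_real_,
                      baseline_sd_log2 = NA_real_, peaks_in_m = NA,
                      stringsAsFactors = FALSE)
    if (!isTRUE(significant[i])) return(rec)
    g2v <- row[g2_cols]; g2v <- g2v[!is.na(g2v)]
    if (!length(g2v)) { rec$label <- "unclassifiable"; return(rec) }
    base <- row[base_cols]; base <- base[!is.na(base)]
    if (length(base) < 2) { rec$label <- "unclassifiable"; return(rec) }
    fmeans <- vapply(fr, function(f) mean(row[x$fractions == f], na.rm = TRUE),
                     numeric(1))
    rec$g2_mean_log2 <- mean(g2v)
    rec$baseline_mean_log2 <- mean(base)
    rec$baseline_sd_log2 <- stats::sd(base)
    rec$peaks_in_m <- names(which.max(fmeans)) == m_fraction
    early <- rec$peaks_in_m &&
      rec$g2_mean_log2 > rec$baseline_mean_log2 + k_sd * rec$baseline_sd_log2
    rec$label <- if (!rec$peaks_in_m) "excluded" else
      if (early) "early" else "late"
    rec
  })
  do.call(rbind, out)
}

#' Phosphoacceptor residue frequencies
#'
#' Fractions of phosphoserine, phosphothreonine and phosphotyrosine among
#' the sites; sums to 1.
#'
#' @param sites Data frame with an `amino_acid` column (letters S/T/Y).
#' @return Named numeric vector `c(S = , T = , Y = )`.
#' @export
residue_frequencies <- function(sites) {
  aa <- sites$amino_acid
  if (!length(aa)) stop("empty site table", call. = FALSE)
  bad <- setdiff(unique(aa), c("S", "T", "Y"))
  if (length(bad)) {
    stop("phosphoacceptor outside S/T/Y: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tab <- table(factor(aa, levels = c("S", "T", "Y")))
  as.numeric(tab) / length(aa) -> f
  names(f) <- c("S", "T", "Y")
  f
}

#' Match CDK-related motifs in a sequence window
#'
#' Tests the +/-7-residue window (15-mer, phosphosite at position 8,
#' `_`-padded at protein termini) for:
#' * `proline_directed`: the site is S or T and the +1 residue is proline
#'   (the minimal CDK/MAPK motif, \[S/T\]P);
#' * `full_cdk_consensus`: additionally the +3 residue is basic (K or R),
#'   i.e. \[S/T\]-P-x-\[K/R\].
#'
#' @param sequence_window Character vector of 15-mer windows.
#' @return Data frame: `sequence_window`, `proline_directed`,
#'   `full_cdk_consensus`.
#' @export
motif_match <- function(sequence_window) {
  if (any(nchar(sequence_window) != 15)) {
    stop("sequence windows must be 15-mers (+/-7 residues, '_' padded)",
         call. = FALSE)
  }
  center <- substr(sequence_window, 8, 8)
  plus1 <- substr(sequence_window, 9, 9)
  plus3 <- substr(sequence_window, 11, 11)
  pd <- center %in% c("S", "T") & plus1 == "P"
  data.frame(sequence_window = sequence_window,
             proline_directed = pd,
             full_cdk_consensus = pd & plus3 %in% c("K", "R"),
             stringsAsFactors = FALSE)
}

#' Compare M-phase phosphorylation of early vs late risers
#'
#' Group means (with s.e.m.) of the M-fraction log2 ratios for the two
#' riser classes, and their difference. A single-site group has no s.e.m.
#' and is flagged.
#'
#' @param x A [profile_matrix()] of site quantitation.
#' @param labels Character vector (named by site id) with values
#'   `"early"`/`"late"` (other labels ignored).
#' @param m_fraction Mitotic fraction label.
#' @return Data frame with one row per group (`mean_m_log2`, `sem`, `n`)
#'   and attributes `"difference"` (early - late) and `"direction"`.
#' @export
compare_early_late <- function(x, labels, m_fraction = "M") {
  stopifnot(inherits(x, "profile_matrix"))
  m_cols <- x$fractions == m_fraction
  mvals <- rowMeans(log2(x$ratios[, m_cols, drop = FALSE]), na.rm = TRUE)
  labels <- labels[rownames(x$ratios)]
  out <- lapply(c("early", "late"), function(g) {
    v <- mvals[which(labels == g)]
    v <- v[!is.na(v)]
    if (!length(v)) stop("empty group: ", g, call. = FALSE)
    data.frame(group = g, n = length(v), mean_m_log2 = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                     else NA_real_,
               flagged = length(v) == 1)
  })
  out <- do.call(rbind, out)
  attr(out, "difference") <- out$mean_m_log2[1] - out$mean_m_log2[2]
  attr(out, "direction") <-
    if (attr(out, "difference") > 0) "early > late" else "early <= late"
  out
}

#' Fisher's exact enrichment of annotation labels in a candidate set
#'
#' For each label, builds the 2x2 table (in/out of the candidate set x
#' has/lacks the label over the background) and computes the two-sided
#' Fisher exact (hypergeometric) p-value and the sample odds ratio.
#'
#' @param candidates Character vector of candidate ids (subset of
#'   `background`).
#' @param background Character vector of all ids.
#' @param labels Data frame with columns `id` and `label` (an id may carry
#'   several labels).
#' @param bh Apply Benjamini-Hochberg correction across labels.
#' @return Data frame per label: counts, `odds_ratio`, `p` (and `p_adj`
#'   when `bh = TRUE`).
#' @export
fisher_enrichment <- function(candidates, background, labels, bh = FALSE) {
  if (!length(background)) stop("empty background", call. = FALSE)
  if (!all(candidates %in% background)) {
    stop("candidates must be a subset of the background", call. = FALSE)
  }
  labs <- unique(labels$label)
  out <- lapply(labs, function(L) {
    with_label <- unique(labels$id[labels$label == L])
    a <- sum(candidates %in% with_label)
    b <- length(candidates) - a
    cc <- sum(background %in% with_label) - a
    d <- length(background) - length(candidates) - cc
    tab <- matrix(c(a, b, cc, d), 2)
    degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    p <- if (degenerate) 1 else stats::fisher.test(tab)$p.value
    or <- if (degenerate) 1 else (a * d) / (b * cc)
    data.frame(label = L, in_candidates = a, out_candidates = b,
               in_background_rest = cc, out_background_rest = d,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (bh) out$p_adj <- stats::p.adjust(out$p, "BH")
  out
}

#' Normalize site profiles to their protein's abundance profile
#'
#' Divides each site's per-fraction ratio by its protein's replicate-median
#' ratio in the same fraction, isolating phosphorylation stoichiometry
#' changes from protein-level accumulation or degradation. Sites whose
#' protein is absent from the matrix pass through unchanged, flagged
#' `normalized = FALSE`.
#'
#' @param sites Site data frame (with `site_id`, `protein_id` and
#'   quantitation columns, as from [simulate_phosphosites()]).
#' @param protein_median Proteins x fractions median matrix.
#' @return The site data frame with quantitation columns divided through
#'   and a `normalized` logical column appended.
#' @export
normalize_sites_to_protein <- function(sites, protein_median) {
  qcols <- grep("^[A-Za-z0-9]+\\.R[0-9]+$", names(sites), value = TRUE)
  frs <- vapply(strsplit(qcols, ".R", fixed = TRUE), `[`, "", 1)
  out <- sites
  out$normalized <- sites$protein_id %in% rownames(protein_median)
  for (j in seq_along(qcols)) {
    f <- frs[j]
    if (!f %in% colnames(protein_median)) next
    prot <- protein_median[match(sites$protein_id, rownames(protein_median)), f]
    if (any(prot <= 0, na.rm = TRUE)) {
      stop("zero or negative protein ratio in fraction ", f, call. = FALSE)
    }
    idx <- out$normalized & !is.na(prot)
    out[[qcols[j]]][idx] <- sites[[qcols[j]]][idx] / prot[idx]
  }
  out
}
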