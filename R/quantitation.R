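#' Correct TMT reporter intensities for isotope impurities
#'
#' Reporter channels cross-contaminate through the isotopic envelope of the
#' label. With an impurity matrix `M` whose column `j` gives the
#' distribution of channel `j`'s signal across observed channels, the
#' observed intensities satisfy `observed = M %*% true`; the correction
#' solves this linear system per protein. Negative solutions (possible
#' with noisy data) are clamped to 0 and flagged.
#'
#' @param observed Numeric matrix, proteins x channels.
#' @param impurity_matrix Square channel x channel impurity matrix
#'   (entries >= 0, column sums <= 1, invertible).
#' @return Corrected intensity matrix with a logical `"clamped"` attribute
#'   marking proteins where any channel was clamped.
#' @export
correct_isotope_impurities <- function(observed, impurity_matrix) {
  observed <- as.matrix(observed)
  check_impurity_matrix(impurity_matrix, ncol(observed))
  if (abs(det(impurity_matrix)) < 1e-12) {
    stop("impurity matrix is singular", call. = FALSE)
  }
  true <- t(solve(impurity_matrix, t(observed)))
  clamped <- apply(true < -1e-12, 1, any)
  true[true < 0] <- 0
  dimnames(true) <- dimnames(observed)
  attr(true, "clamped") <- clamped
  true
}

#' Sum-normalize TMT reporter intensities
#'
#' Divides each protein's reporter intensities by their sum, so each row
#' describes the distribution of the protein's signal across channels and
#' sums to exactly 1.
#'
#' @param corrected Numeric matrix, proteins x channels, values >= 0.
#' @return Row-normalized matrix (rows sum to 1).
#' @export
normalize_reporters <- function(corrected) {
  corrected <- as.matrix(corrected)
  rs <- rowSums(corrected)
  bad <- which(rs <= 0 | is.na(rs))
  if (length(bad)) {
    stop("all-zero reporter rows: ",
         paste(utils::head(rownames(corrected)[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  corrected / rs
}

#' Convert normalized channel fractions to reference-fraction ratios
#'
#' Maps channels to sorted fractions and divides by the reference
#' fraction's value, so the reference ratio is exactly 1. Rows whose
#' reference channel is zero or missing are set to `NA` and flagged (not
#' silently dropped).
#'
#' @param normalized Matrix of per-protein channel fractions (from
#'   [normalize_reporters()]), columns named by channel.
#' @param channel_map Named character vector mapping channel -> fraction,
#'   e.g. `c("126" = "G2", "127N" = "M", ...)`; must be a bijection onto
#'   the fractions.
#' @param reference_fraction Fraction whose ratio is fixed at 1.
#' @return Matrix of ratios, columns renamed to fractions, with a
#'   `"missing_reference"` attribute listing flagged proteins.
#' @export
reference_ratios <- function(normalized, channel_map, reference_fraction) {
  normalized <- as.matrix(normalized)
  if (is.null(colnames(normalized))) {
    stop("`normalized` must have channel column names", call. = FALSE)
  }
  if (anyDuplicated(channel_map) || anyDuplicated(names(channel_map))) {
    stop("`channel_map` must be a bijection channel -> fraction",
         call. = FALSE)
  }
  miss <- setdiff(colnames(normalized), names(channel_map))
  if (length(miss)) {
    stop("channels not in map: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  fr <- unname(channel_map[colnames(normalized)])
  if (!reference_fraction %in% fr) {
    stop("reference fraction ", reference_fraction,
         " absent from channel map", call. = FALSE)
  }
  ref <- normalized[, which(fr == reference_fraction)]
  flagged <- which(is.na(ref) | ref <= 0)
  out <- normalized / ref
  out[flagged, ] <- NA_real_
  colnames(out) <- fr
  attr(out, "missing_reference") <- rownames(normalized)[flagged]
  out
}

#' Normalize SILAC ratios to a reference fraction
#'
#' Two published modes:
#' * `"g1"` (interphase design): each replicate's profile is divided by its
#'   own G1 (reference) ratio.
#' * `"pro1"` (mitotic design): every replicate is divided by the reference
#'   (prophase) ratio of replicate 1, preserving between-replicate
#'   differences.
#'
#' A row whose reference value is missing is excluded from the normalized
#' output for the affected replicate(s) (set `NA`) and logged in the
#' `"excluded"` attribute.
#'
#' @param x A [profile_matrix()].
#' @param mode `"g1"` or `"pro1"`.
#' @param reference_fraction Reference fraction label (default the first
#'   fraction present, i.e. `"G1"` or `"Pro"` in the shipped designs).
#' @return Normalized [profile_matrix()]; reference fraction equals 1
#'   wherever quantified. Idempotent.
#' @export
normalize_silac <- function(x, mode = c("g1", "pro1"),
                            reference_fraction = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "profile_matrix"))
  if (is.null(reference_fraction)) reference_fraction <- x$fractions[1]
  if (!reference_fraction %in% x$fractions) {
    stop("reference fraction ", reference_fraction, " not present",
         call. = FALSE)
  }
  excluded <- data.frame(protein_id = character(), replicate = integer())
  if (mode == "g1") {
    for (r in unique(x$replicates)) {
      cols <- which(x$replicates == r)
      refcol <- cols[x$fractions[cols] == reference_fraction]
      ref <- x$ratios[, refcol]
      bad <- is.na(ref)
      x$ratios[, cols] <- x$ratios[, cols] / ref
      if (any(bad)) {
        x$ratios[bad, cols] <- NA_real_
        excluded <- rbind(excluded,
                          data.frame(protein_id = rownames(x$ratios)[bad],
                                     replicate = r))
      }
    }
  } else {
    r1 <- min(x$replicates)
    refcol <- which(x$replicates == r1 & x$fractions == reference_fraction)
    ref <- x$ratios[, refcol]
    bad <- is.na(ref)
    x$ratios <- x$ratios / ref
    if (any(bad)) {
      x$ratios[bad, ] <- NA_real_
      excluded <- data.frame(protein_id = rownames(x$ratios)[bad],
                             replicate = NA_integer_)
    }
  }
  attr(x, "excluded") <- excluded
  attr(x, "reference_fraction") <- reference_fraction
  x
}

#' Merge SILAC and TMT quantitation streams
#'
#' Outer join on the leading razor protein identifier. Both inputs must be
#' normalized to the same reference fraction. Replicate columns are
#' preserved per source (TMT replicates renumbered to follow the SILAC
#' ones) and each column keeps its source tag, so the merge can be split
#' back without value mutation. The identifier overlap is reported.
#'
#' @param silac,tmt [profile_matrix()] objects sharing fraction labels.
#' @return A merged [profile_matrix()] with attributes `"overlap"` (count)
#'   and `"overlap_fraction"` (overlap / union).
#' @export
merge_datasets <- function(silac, tmt) {
  stopifnot(inherits(silac, "profile_matrix"), inherits(tmt, "profile_matrix"))
  ids_s <- rownames(silac$ratios)
  ids_t <- rownames(tmt$ratios)
  all_ids <- union(ids_s, ids_t)
  shift <- max(silac$replicates)
  reps_t <- tmt$replicates + shift

  m <- matrix(NA_real_, length(all_ids),
              ncol(silac$ratios) + ncol(tmt$ratios),
              dimnames = list(all_ids, NULL))
  m[match(ids_s, all_ids), seq_len(ncol(silac$ratios))] <- silac$ratios
  m[match(ids_t, all_ids),
    ncol(silac$ratios) + seq_len(ncol(tmt$ratios))] <- tmt$ratios

  out <- profile_matrix(
    m,
    fractions = c(silac$fractions, tmt$fractions),
    replicates = c(silac$replicates, reps_t),
    source = c(silac$source, tmt$source)
  )
  overlap <- length(intersect(ids_s, ids_t))
  attr(out, "overlap") <- overlap
  attr(out, "overlap_fraction") <- overlap / length(all_ids)
  out
}

#' Standard channel -> fraction map of the mitotic 6-plex
#'
#' Channels 126, 127N, 128C, 129N, 130C and 131 carry the G2, M, prophase,
#' cyclin A- prometaphase (PM2), cyclin A+ prometaphase (PM1) and anaphase
#' fractions respectively.
#'
#' @return Named character vector (channel -> fraction).
#' @export
mitotic_channel_map <- function() {
  c("126" = "G2", "127N" = "M", "128C" = "Pro",
    "129N" = "PM2", "130C" = "PM1", "131" = "Ana")
}
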