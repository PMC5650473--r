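#' Protein (or site) profile matrix
#'
#' The central quantitation container: one row per protein (keyed by the
#' leading razor protein identifier), one column per (fraction, replicate)
#' pair, holding relative-abundance ratios in linear space. Missing values
#' are explicit `NA`s (never zero) because downstream selection reasons
#' about missingness patterns; all present values must be positive, since
#' ratios are multiplicative.
#'
#' @param ratios Numeric matrix, rownames = protein identifiers, one column
#'   per fraction x replicate measurement.
#' @param fractions Character vector, fraction label of each column.
#' @param replicates Integer vector, replicate index of each column.
#' @param peptide_count Optional integer vector per protein.
#' @param annotation Optional character vector of free-text functional
#'   labels per protein (`NA` where unannotated).
#' @param source Scalar tag for the quantitation stream of each column
#'   (e.g. `"silac"`, `"tmt"`), recycled to the number of columns.
#' @return A `profile_matrix` object.
#' @export
profile_matrix <- function(ratios, fractions, replicates,
                           peptide_count = NULL, annotation = NULL,
                           source = "silac") {
  ratios <- as.matrix(ratios)
  if (is.null(rownames(ratios))) {
    stop("`ratios` must have protein identifiers as rownames", call. = FALSE)
  }
  if (anyDuplicated(rownames(ratios))) {
    stop("duplicate protein identifiers: ",
         paste(unique(rownames(ratios)[duplicated(rownames(ratios))]),
               collapse = ", "), call. = FALSE)
  }
  if (length(fractions) != ncol(ratios) || length(replicates) != ncol(ratios)) {
    stop("`fractions`/`replicates` must match the number of columns",
         call. = FALSE)
  }
  if (any(ratios <= 0, na.rm = TRUE)) {
    stop("ratios must be positive (missing values are NA, never 0)",
         call. = FALSE)
  }
  colnames(ratios) <- paste0(fractions, ".R", replicates)
  structure(list(
    ratios = ratios,
    fractions = as.character(fractions),
    replicates = as.integer(replicates),
    peptide_count = peptide_count,
    annotation = annotation,
    source = rep_len(as.character(source), ncol(ratios))
  ), class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("<profile_matrix> ", nrow(x$ratios), " proteins x ",
      ncol(x$ratios), " columns (",
      length(unique(x$fractions)), " fractions, ",
      length(unique(x$replicates)), " replicates; source: ",
      paste(unique(x$source), collapse = "+"), ")\n", sep = "")
  cat("  missing values:", sum(is.na(x$ratios)), "\n")
  invisible(x)
}

#' @export
dim.profile_matrix <- function(x) dim(x$ratios)

#' Subset a profile matrix by protein identifiers
#' @param x A `profile_matrix`.
#' @param ids Protein identifiers to keep (in order).
#' @return A `profile_matrix` restricted to `ids`.
#' @export
pm_subset <- function(x, ids) {
  stopifnot(inherits(x, "profile_matrix"))
  keep <- match(ids, rownames(x$ratios))
  if (anyNA(keep)) {
    stop("unknown protein identifiers: ",
         paste(ids[is.na(keep)], collapse = ", "), call. = FALSE)
  }
  x$ratios <- x$ratios[keep, , drop = FALSE]
  if (!is.null(x$peptide_count)) x$peptide_count <- x$peptide_count[keep]
  if (!is.null(x$annotation)) x$annotation <- x$annotation[keep]
  x
}

#' Columns of a profile matrix belonging to one replicate
#' @param x A `profile_matrix`.
#' @param replicate Replicate index.
#' @return Matrix of that replicate's columns, named by fraction.
#' @export
replicate_profile <- function(x, replicate) {
  stopifnot(inherits(x, "profile_matrix"))
  keep <- x$replicates == replicate
  if (!any(keep)) stop("no columns for replicate ", replicate, call. = FALSE)
  m <- x$ratios[, keep, drop = FALSE]
  colnames(m) <- x$fractions[keep]
  m
}

#' Median profile across replicates
#'
#' The per-protein replicate-median profile: for each fraction, the median
#' ratio over the replicates in which the protein was quantified. A
#' fraction with no quantified replicate is `NA`.
#'
#' @param x A `profile_matrix`.
#' @return Numeric matrix, proteins x fractions (fractions in first-seen
#'   order).
#' @export
replicate_median_profile <- function(x) {
  stopifnot(inherits(x, "profile_matrix"))
  fr <- unique(x$fractions)
  out <- vapply(fr, function(f) {
    cols <- x$ratios[, x$fractions == f, drop = FALSE]
    apply(cols, 1, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) NA_real_ else stats::median(v)
    })
  }, numeric(nrow(x$ratios)))
  out <- matrix(out, nrow = nrow(x$ratios),
                dimnames = list(rownames(x$ratios), fr))
  out
}
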