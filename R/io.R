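#' Write a protein-groups table
#'
#' Tab-separated, header row, missing values as empty cells: one row per
#' protein with `protein_id`, `gene_name`, `peptide_count`, `annotation`
#' and one `fraction.R<rep>` ratio column per measurement. Ground-truth
#' class labels are *not* written here; keep them in a separate table.
#'
#' @param x A [profile_matrix()].
#' @param path Output file.
#' @export
write_protein_groups <- function(x, path) {
  stopifnot(inherits(x, "profile_matrix"))
  df <- data.frame(
    protein_id = rownames(x$ratios),
    gene_name = rownames(x$ratios),
    peptide_count = x$peptide_count %||% NA_integer_,
    annotation = x$annotation %||% NA_character_,
    stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(x$ratios))
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read a protein-groups table
#'
#' @param path TSV written by [write_protein_groups()] (or any MaxQuant
#'   style protein table with `protein_id` and `fraction.R<rep>` columns).
#' @return A [profile_matrix()].
#' @export
read_protein_groups <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!"protein_id" %in% names(df)) {
    stop("malformed table ", path, ": no protein_id column", call. = FALSE)
  }
  qcols <- grep("^[A-Za-z0-9]+\\.R[0-9]+$", names(df), value = TRUE)
  if (!length(qcols)) {
    stop("malformed table ", path, ": no fraction.R<rep> columns",
         call. = FALSE)
  }
  parts <- strsplit(qcols, ".R", fixed = TRUE)
  m <- as.matrix(df[, qcols])
  m[m == ""] <- NA
  mode(m) <- "numeric"
  rownames(m) <- df$protein_id
  profile_matrix(m,
                 fractions = vapply(parts, `[`, "", 1),
                 replicates = as.integer(vapply(parts, `[`, "", 2)),
                 peptide_count = df$peptide_count,
                 annotation = df$annotation)
}

#' Write / read a phosphosite table
#'
#' Same TSV dialect as the protein-groups table, with site metadata
#' columns (`site_id`, `protein_id`, `position`, `amino_acid`,
#' `sequence_window`, `localization_prob`).
#'
#' @param sites Site data frame (see [simulate_phosphosites()]).
#' @param path File path.
#' @export
write_phospho_sites <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phospho_sites
#' @export
read_phospho_sites <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("site_id", "protein_id", "position", "amino_acid",
            "sequence_window")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("malformed site table ", path, ": missing columns ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a JSON run configuration
#'
#' Validates the minimal schema of a pipeline run configuration: design,
#' seed, phase frequency table, selection settings, clustering settings
#' and (for TMT runs) an impurity matrix.
#'
#' @param path JSON file.
#' @return A named list with validated fields.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$design) || !cfg$design %in% c("interphase", "mitotic")) {
    stop("config schema violation: `design` must be 'interphase' or 'mitotic'",
         call. = FALSE)
  }
  if (is.null(cfg$seed)) {
    stop("config schema violation: `seed` is required", call. = FALSE)
  }
  cfg
}

# provenance record written next to every pipeline output
write_provenance <- function(out_dir, config_list, seed) {
  cfg_json <- jsonlite::toJSON(config_list, auto_unbox = TRUE, digits = NA,
                               null = "null", force = TRUE)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  # no timestamp: re-running with the same config and seed must produce
  # byte-identical outputs, provenance record included
  rec <- list(
    config_md5 = unname(tools::md5sum(tmp)),
    seed = seed,
    package_version = as.character(utils::packageVersion("primmus"))
  )
  unlink(tmp)
  jsonlite::write_json(rec, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(rec)
}
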