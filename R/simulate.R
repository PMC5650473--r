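#' Simulation configuration for synthetic sorted-fraction proteomics
#'
#' Collects the knobs of the synthetic-data generator. Defaults are the
#' study conditions emulated throughout the package: asynchronous NB4-like
#' cells (24 h doubling time, cumulative phase frequencies 21/65/92/98%),
#' FACS gate purity 0.96 (the measured mitotic purity of the M gate),
#' multiplicative lognormal measurement noise with CV 0.15 on ratios, and
#' missing-completely-at-random dropout per protein x fraction x replicate
#' (each sorted fraction is a separate MS run).
#'
#' @param n_cells Number of cells in the asynchronous population.
#' @param n_proteins Named integer vector: number of proteins per
#'   trajectory class (see [trajectory()]).
#' @param doubling_time Hours per division.
#' @param phase_boundaries Named, strictly increasing cumulative phase
#'   frequencies in `(0, 1]`.
#' @param gate_purity Fraction of each sorted gate's cells that truly
#'   belong to the gated phase, in `(0.5, 1]`.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal measurement noise.
#' @param dropout_rate Probability that a protein is unobserved in a given
#'   fraction x replicate run, in `[0, 1)`.
#' @param dropout_mode `"mcar"` (missing completely at random) or
#'   `"abundance"` (logistic in log-abundance, emulating data-dependent
#'   acquisition preferring abundant precursors).
#' @param compression TMT ratio-compression factor in `(0, 1]`
#'   (observed ratio = true ratio ^ compression).
#' @param n_replicates Biological replicates.
#' @param seed RNG seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_cells = 1e5,
                              n_proteins = c(bulk_exponential = 100),
                              doubling_time = 24,
                              phase_boundaries = c(G1 = 0.21, S = 0.65,
                                                   G2 = 0.92, M = 0.98),
                              gate_purity = 0.96,
                              noise_cv = 0.15,
                              dropout_rate = 0,
                              dropout_mode = c("mcar", "abundance"),
                              compression = 1,
                              n_replicates = 3,
                              seed = 1L) {
  dropout_mode <- match.arg(dropout_mode)
  if (!is.numeric(n_cells) || n_cells < 1) {
    stop("`n_cells` must be a positive count", call. = FALSE)
  }
  if (any(diff(phase_boundaries) <= 0) ||
      any(phase_boundaries <= 0) || any(phase_boundaries > 1)) {
    stop("`phase_boundaries` must be strictly increasing within (0, 1]",
         call. = FALSE)
  }
  if (gate_purity <= 0.5 || gate_purity > 1) {
    stop("`gate_purity` must lie in (0.5, 1]", call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("`dropout_rate` must lie in [0, 1)", call. = FALSE)
  }
  if (compression <= 0 || compression > 1) {
    stop("`compression` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(
    n_cells = as.integer(n_cells), n_proteins = n_proteins,
    doubling_time = doubling_time, phase_boundaries = phase_boundaries,
    gate_purity = gate_purity, noise_cv = noise_cv,
    dropout_rate = dropout_rate, dropout_mode = dropout_mode,
    compression = compression, n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# sdlog of a lognormal with unit median and coefficient of variation cv
lognormal_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Sample an asynchronous cell population
#'
#' Draws cell-cycle ages from the exponential-growth age density
#' `f(t) = 2 ln2 2^(-t)` by inverting its CDF, and records each cell's
#' true phase from the configured cumulative boundaries.
#'
#' @param config A [simulation_config()].
#' @return Data frame with columns `t` (age fraction) and `phase`.
#' @export
sample_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  u <- stats::runif(config$n_cells)
  t <- cumulative_to_time(u)  # inverse-CDF sampling: u is a uniform CDF value
  b <- config$phase_boundaries
  edges <- c(0, cumulative_to_time(b))
  phase <- cut(t, breaks = c(edges, 1 + 1e-9),
               labels = c(names(b), "ungated"), right = FALSE,
               include.lowest = TRUE)
  phase <- as.character(phase)
  data.frame(t = t, phase = phase, stringsAsFactors = FALSE)
}

#' Assign cells to FACS sort gates
#'
#' Emulates gated sorting on the age axis. At purity 1 each gate contains
#' exactly the cells of its phase. At purity `p`, a fraction `1 - p` of
#' each gate's sample is replaced by cells drawn uniformly from the
#' adjacent phases (gate spillover), so the measured purity of every gate
#' is `p` in expectation.
#'
#' @param population Data frame from [sample_population()] (columns `t`,
#'   `phase`), or any data frame with a `t` column.
#' @param phase_boundaries Named cumulative frequencies defining the gate
#'   upper boundaries; a `lower_bound` cumulative frequency can restrict
#'   gating to a sub-window (used for the mitotic subphase sort).
#' @param gate_purity Purity in `(0.5, 1]`.
#' @param lower_bound Cumulative frequency of the first gate's lower edge
#'   (default 0).
#' @return A `gate_assignment`: list with `gates` (named list of cell index
#'   vectors), `confusion` (gate x true-phase count matrix) and `purity`
#'   (realized per-gate purity).
#' @export
assign_gates <- function(population, phase_boundaries, gate_purity = 1,
                         lower_bound = 0) {
  if (any(diff(phase_boundaries) <= 0)) {
    stop("gate boundaries overlap or are non-increasing", call. = FALSE)
  }
  if (lower_bound >= phase_boundaries[1]) {
    stop("`lower_bound` must precede the first gate boundary", call. = FALSE)
  }
  edges_t <- cumulative_to_time(c(lower_bound, phase_boundaries))
  labels <- names(phase_boundaries)
  tt <- population$t
  true_gate <- cut(tt, breaks = edges_t, labels = labels, right = FALSE,
                   include.lowest = FALSE)
  idx_by_phase <- split(seq_along(tt), true_gate)
  gates <- vector("list", length(labels))
  names(gates) <- labels
  for (g in seq_along(labels)) {
    own <- idx_by_phase[[labels[g]]]
    if (is.null(own) || !length(own)) {
      stop("empty gate: ", labels[g], call. = FALSE)
    }
    if (gate_purity >= 1) {
      gates[[g]] <- own
      next
    }
    adj <- unlist(idx_by_phase[labels[c(g - 1, g + 1)[c(g - 1, g + 1) %in%
                                          seq_along(labels)]]],
                  use.names = FALSE)
    swap <- stats::runif(length(own)) > gate_purity
    samp <- own
    if (any(swap) && length(adj)) {
      samp[swap] <- adj[sample.int(length(adj), sum(swap), replace = TRUE)]
    }
    gates[[g]] <- samp
  }
  truth <- factor(as.character(true_gate), levels = labels)
  confusion <- t(vapply(labels, function(g) {
    table(factor(as.character(truth[gates[[g]]]), levels = labels))
  }, integer(length(labels))))
  dimnames(confusion) <- list(gate = labels, true_phase = labels)
  structure(list(gates = gates, confusion = confusion,
                 purity = diag(confusion) / rowSums(confusion)),
            class = "gate_assignment")
}

#' Build a default trajectory set from class counts
#'
#' @param n_proteins Named integer vector of proteins per trajectory class.
#' @param baseline_meanlog,baseline_sdlog Lognormal spread of per-protein
#'   baselines (abundance heterogeneity across the proteome).
#' @param class_args Optional named list: per-class argument lists passed
#'   to [trajectory()] (e.g. `list(anaphase_degraded = list(residual = 0.3))`).
#' @return Named list of [trajectory()] objects (`P0001`, `P0002`, ...).
#' @export
make_trajectory_set <- function(n_proteins, baseline_meanlog = 0,
                                baseline_sdlog = 1, class_args = list()) {
  classes <- rep(names(n_proteins), n_proteins)
  n <- length(classes)
  baselines <- stats::rlnorm(n, baseline_meanlog, baseline_sdlog)
  trajs <- lapply(seq_len(n), function(i) {
    do.call(trajectory, c(list(class_label = classes[i],
                               baseline = baselines[i]),
                          class_args[[classes[i]]]))
  })
  names(trajs) <- sprintf("P%04d", seq_len(n))
  trajs
}

#' Simulate SILAC ratios of sorted fractions against an asynchronous standard
#'
#' The forward model of the sorted-fraction SILAC measurement. Each sorted
#' gate is mixed 1:1 *by cell number* with an asynchronous labelled
#' standard, so the measured ratio for a protein is the mean per-cell
#' abundance over the gated cells divided by the mean over the whole
#' population; per-cell averaging embodies the equal-cell-number mixing.
#' Each (fraction, replicate) value then acquires multiplicative lognormal
#' noise and may drop out (each fraction is a separate MS run).
#'
#' `measure = "position"` replaces the gate average by the trajectory
#' evaluated at the gate's single ergodic timeline position (its cumulative
#' upper boundary), divided by the quadrature population mean. The two
#' conventions differ for accumulating proteins: a doubling protein's G1
#' gate average is t_G1/F_G1 = 0.76, while the position value is
#' 2^0.16/(2 ln2) = 0.81 — the position convention is the one the ergodic
#' timeline model predicts for a fraction "at" t, and is used when data are
#' to sit exactly on the model curve.
#'
#' @param population From [sample_population()].
#' @param gates From [assign_gates()].
#' @param trajectories Named list of [trajectory()] objects.
#' @param config A [simulation_config()].
#' @param measure `"gate_mean"` (default, Monte-Carlo gate average) or
#'   `"position"` (timeline-position evaluation).
#' @param gate_positions Named normalized times per gate, required for
#'   `measure = "position"`; defaults to the cumulative upper boundaries of
#'   `config$phase_boundaries`.
#' @return A list: `matrix` (a [profile_matrix()]) and `ground_truth`
#'   (data frame of protein, class label and true noise-free per-fraction
#'   ratios).
#' @export
simulate_silac_matrix <- function(population, gates, trajectories, config,
                                  measure = c("gate_mean", "position"),
                                  gate_positions = NULL) {
  measure <- match.arg(measure)
  stopifnot(inherits(gates, "gate_assignment"))
  labels <- names(gates$gates)
  if (any(!vapply(gates$gates, length, 1L))) stop("empty gate", call. = FALSE)
  n_prot <- length(trajectories)
  ids <- names(trajectories)

  if (measure == "position" && is.null(gate_positions)) {
    gate_positions <- cumulative_to_time(config$phase_boundaries)
    names(gate_positions) <- names(config$phase_boundaries)
  }

  true_ratio <- matrix(NA_real_, n_prot, length(labels),
                       dimnames = list(ids, labels))
  for (i in seq_len(n_prot)) {
    tr <- trajectories[[i]]
    if (measure == "gate_mean") {
      a <- trajectory_abundance(tr, population$t)
      standard <- mean(a)
      for (g in seq_along(labels)) {
        true_ratio[i, g] <- mean(a[gates$gates[[g]]]) / standard
      }
    } else {
      standard <- population_mean_abundance(tr)
      true_ratio[i, ] <-
        trajectory_abundance(tr, gate_positions[labels]) / standard
    }
  }

  nrep <- config$n_replicates
  sdlog <- lognormal_sdlog(config$noise_cv)
  cols <- expand.grid(fraction = labels, replicate = seq_len(nrep),
                      stringsAsFactors = FALSE)
  ratios <- matrix(NA_real_, n_prot, nrow(cols), dimnames = list(ids, NULL))
  for (j in seq_len(nrow(cols))) {
    v <- true_ratio[, cols$fraction[j]]
    noise <- if (sdlog > 0) stats::rlnorm(n_prot, 0, sdlog) else 1
    ratios[, j] <- v * noise
  }
  ratios <- apply_dropout(ratios, trajectories, config)

  gt <- data.frame(
    protein_id = ids,
    class_label = vapply(trajectories, `[[`, "", "class_label"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  gt <- cbind(gt, as.data.frame(true_ratio))

  list(
    matrix = profile_matrix(ratios, cols$fraction, cols$replicate,
                            peptide_count = pmax(1L, stats::rpois(n_prot, 8)),
                            annotation = gt$class_label,
                            source = "silac"),
    ground_truth = gt
  )
}

# Inject missingness: MCAR per cell, or logistic in log baseline abundance
# (data-dependent acquisition preferentially misses low-abundance proteins).
apply_dropout <- function(ratios, trajectories, config) {
  if (config$dropout_rate <= 0) return(ratios)
  n <- nrow(ratios)
  if (config$dropout_mode == "mcar") {
    drop <- matrix(stats::runif(length(ratios)) < config$dropout_rate,
                   nrow = n)
  } else {
    la <- log(vapply(trajectories, `[[`, 1, "baseline"))
    # centre the logistic so the marginal dropout matches dropout_rate
    p <- stats::plogis(-(la - stats::median(la)) / stats::sd(la))
    p <- p * config$dropout_rate / mean(p)
    p <- pmin(p, 0.99)
    drop <- matrix(stats::runif(length(ratios)) <
                     rep(p, times = ncol(ratios)), nrow = n)
  }
  ratios[drop] <- NA_real_
  ratios
}

#' Simulate raw TMT reporter intensities
#'
#' Forward model of isobaric quantitation: the true per-channel signals are
#' ratio-compressed (co-isolation pulls ratios toward 1:
#' observed ratio = true ratio ^ compression, applied about each protein's
#' geometric mean), scaled, noised, and mixed through the label's isotope
#' impurity matrix (column j of the matrix distributes channel j's signal
#' across observed channels).
#'
#' @param true_abundances Numeric matrix, proteins x channels (>= 0),
#'   rownames = protein identifiers.
#' @param impurity_matrix Square channel x channel matrix; entries >= 0,
#'   column sums <= 1.
#' @param compression Ratio-compression factor in `(0, 1]`.
#' @param config A [simulation_config()] (noise CV and seed are honoured;
#'   pass `noise_cv = 0` for a deterministic forward model).
#' @param intensity_scale Overall reporter intensity scale.
#' @return Matrix of observed reporter intensities, proteins x channels.
#' @export
simulate_tmt_reporters <- function(true_abundances, impurity_matrix,
                                   compression = 1, config = NULL,
                                   intensity_scale = 1) {
  true_abundances <- as.matrix(true_abundances)
  if (any(true_abundances < 0)) {
    stop("negative intensities in input", call. = FALSE)
  }
  check_impurity_matrix(impurity_matrix, ncol(true_abundances))
  if (compression <= 0 || compression > 1) {
    stop("`compression` must lie in (0, 1]", call. = FALSE)
  }
  comp <- t(apply(true_abundances, 1, function(v) {
    pos <- v > 0
    if (!any(pos)) return(v)
    gm <- exp(mean(log(v[pos])))
    out <- v
    out[pos] <- gm * (v[pos] / gm)^compression
    out
  }))
  comp <- comp * intensity_scale
  cv <- if (is.null(config)) 0 else config$noise_cv
  if (cv > 0) {
    comp <- comp * matrix(stats::rlnorm(length(comp), 0, lognormal_sdlog(cv)),
                          nrow = nrow(comp))
  }
  observed <- t(impurity_matrix %*% t(comp))
  dimnames(observed) <- dimnames(true_abundances)
  observed
}

check_impurity_matrix <- function(m, nchan) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("impurity matrix must be square", call. = FALSE)
  }
  if (nrow(m) != nchan) {
    stop("impurity matrix dimension (", nrow(m),
         ") does not match channel count (", nchan, ")", call. = FALSE)
  }
  if (any(m < 0)) stop("impurity matrix entries must be >= 0", call. = FALSE)
  if (any(colSums(m) > 1 + 1e-8)) {
    stop("impurity matrix columns must sum to <= 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Default TMT isotope impurity matrix
#'
#' A plausible +/-1 Da spill pattern of a few percent for a 6-channel plex
#' (the true lot-specific values are reagent-certificate inputs); used only
#' by the simulator and as a documented default.
#'
#' @param n_channels Number of channels.
#' @param spill Fraction spilling into each neighbouring channel.
#' @return Column-stochastic-up-to-retention square matrix.
#' @export
default_impurity_matrix <- function(n_channels = 6, spill = 0.03) {
  m <- diag(1 - 2 * spill, n_channels)
  for (j in seq_len(n_channels)) {
    if (j > 1) m[j - 1, j] <- m[j - 1, j] + spill
    if (j < n_channels) m[j + 1, j] <- m[j + 1, j] + spill
  }
  # edge channels only lose one neighbour's worth
  m[1, 1] <- 1 - spill
  m[n_channels, n_channels] <- 1 - spill
  m
}

#' Simulate a phosphosite table with planted dynamics classes
#'
#' Generates sites in three planted classes over the G1/S/G2/M fractions:
#' `early_riser` (already elevated in the G2-enriched fraction, maximal in
#' M, sequence windows enriched for the full CDK consensus \[S/T\]-P-x-\[K/R\]),
#' `late_riser` (flat until M, then maximal) and `flat`. Residue identities
#' (pS/pT/pY) are drawn from configurable frequencies; each site carries a
#' +/-7-residue sequence window centred on the phosphoacceptor.
#'
#' @param config A [simulation_config()] (noise CV, replicates, seed).
#' @param n_sites Named counts per class.
#' @param residue_freq Frequencies of S/T/Y phosphoacceptors.
#' @param g2_fold Fold elevation of early risers in G2 over the G1/S
#'   baseline (default 2.5).
#' @param m_fold Fold elevation of early risers in M (default 8).
#' @param late_m_fold Fold elevation of late risers in M (default 4):
#'   early risers reach higher mitotic phosphorylation levels on average
#'   than sites that only rise at M.
#' @param cdk_motif_prob Probability that a site's window carries the full
#'   CDK consensus, per class.
#' @param fractions Fraction labels, default G1/S/G2/M.
#' @return List: `sites` (data frame with window, residue, position,
#'   localization probability and fraction x replicate quantitation
#'   columns) and `ground_truth` (site id + planted class).
#' @export
simulate_phosphosites <- function(config,
                                  n_sites = c(early_riser = 60,
                                              late_riser = 120, flat = 320),
                                  residue_freq = c(S = 0.832, T = 0.158,
                                                   Y = 0.010),
                                  g2_fold = 2.5, m_fold = 8,
                                  late_m_fold = 4,
                                  cdk_motif_prob = c(early_riser = 0.7,
                                                     late_riser = 0.3,
                                                     flat = 0.1),
                                  fractions = c("G1", "S", "G2", "M")) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 7L)
  classes <- rep(names(n_sites), n_sites)
  n <- length(classes)
  aa_pool <- strsplit("ACDEFGHIKLMNQRVWY", "")[[1]]  # no S/T/P/other specials

  residues <- sample(names(residue_freq), n, replace = TRUE,
                     prob = residue_freq)
  windows <- vapply(seq_len(n), function(i) {
    w <- sample(aa_pool, 15, replace = TRUE)
    w[8] <- residues[i]
    if (stats::runif(1) < cdk_motif_prob[[classes[i]]] &&
        residues[i] %in% c("S", "T")) {
      w[9] <- "P"; w[11] <- sample(c("K", "R"), 1)
    } else if (stats::runif(1) < 0.25) {
      w[9] <- "P"  # proline-directed but not full consensus
    }
    paste(w, collapse = "")
  }, character(1))

  base_profile <- rbind(
    early_riser = c(1, 1, g2_fold, m_fold),
    late_riser  = c(1, 1, 1, late_m_fold),
    flat        = c(1, 1, 1, 1)
  )
  colnames(base_profile) <- fractions

  nrep <- config$n_replicates
  sdlog <- lognormal_sdlog(config$noise_cv)
  cols <- expand.grid(fraction = fractions, replicate = seq_len(nrep),
                      stringsAsFactors = FALSE)
  quant <- matrix(NA_real_, n, nrow(cols))
  for (j in seq_len(nrow(cols))) {
    v <- base_profile[classes, cols$fraction[j]]
    noise <- if (sdlog > 0) stats::rlnorm(n, 0, sdlog) else 1
    quant[, j] <- v * noise
  }
  colnames(quant) <- paste0(cols$fraction, ".R", cols$replicate)

  site_id <- sprintf("PS%04d_%s%d", seq_len(n), residues,
                     pos <- sample(8:800, n, replace = TRUE))
  sites <- data.frame(
    site_id = site_id,
    protein_id = sprintf("P%04d", sample.int(max(50, n %/% 3), n,
                                             replace = TRUE)),
    position = pos,
    amino_acid = residues,
    sequence_window = windows,
    localization_prob = round(stats::runif(n, 0.75, 1), 3),
    stringsAsFactors = FALSE
  )
  sites <- cbind(sites, as.data.frame(quant))
  list(sites = sites,
       ground_truth = data.frame(site_id = site_id, class_label = classes,
                                 stringsAsFactors = FALSE))
}

#' Extract the quantitation matrix from a phosphosite table
#'
#' @param sites Data frame from [simulate_phosphosites()] (or read from a
#'   site TSV) with `fraction.R<rep>` quantitation columns.
#' @return A [profile_matrix()] keyed by site id.
#' @export
site_profile_matrix <- function(sites) {
  qcols <- grep("^[A-Za-z0-9]+\\.R[0-9]+$", names(sites), value = TRUE)
  if (!length(qcols)) stop("no quantitation columns found", call. = FALSE)
  parts <- strsplit(qcols, ".R", fixed = TRUE)
  m <- as.matrix(sites[, qcols])
  rownames(m) <- sites$site_id
  profile_matrix(m,
                 fractions = vapply(parts, `[`, "", 1),
                 replicates = as.integer(vapply(parts, `[`, "", 2)),
                 source = "tmt")
}
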