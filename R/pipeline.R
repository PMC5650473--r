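#' Simulate a complete interphase sorted-fraction dataset
#'
#' The interphase study design: an asynchronous population sorted into
#' G1/S/G2/M gates, quantified as SILAC ratios against the asynchronous
#' internal standard in four biological replicates, plus a phosphosite
#' table over the same fractions in duplicate. Protein class composition
#' defaults to a mostly-accumulating proteome with histone-like,
#' mitotic-peaking and constant-per-cell minorities.
#'
#' @param config A [simulation_config()]; `n_proteins` gives the class
#'   composition.
#' @param measure Measurement convention passed to
#'   [simulate_silac_matrix()].
#' @param phospho Also simulate a phosphosite table (duplicate
#'   measurement).
#' @return List: `matrix`, `ground_truth`, `timeline`, `population`,
#'   `gates`, and (optionally) `sites`, `site_truth`.
#' @export
simulate_interphase_dataset <- function(
    config = simulation_config(
      n_proteins = c(bulk_exponential = 1500, histone_plateau = 60,
                     mitotic_peak = 60, constant_per_cell = 380),
      n_replicates = 4),
    measure = "gate_mean",
    phospho = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  pft <- phase_frequency_table(names(config$phase_boundaries),
                               config$phase_boundaries,
                               config$doubling_time)
  timeline <- build_timeline(pft)
  population <- sample_population(config)
  gates <- assign_gates(population, config$phase_boundaries,
                        config$gate_purity)
  trajs <- make_trajectory_set(config$n_proteins)
  sim <- simulate_silac_matrix(population, gates, trajs, config,
                               measure = measure)
  out <- list(matrix = sim$matrix, ground_truth = sim$ground_truth,
              timeline = timeline, population = population, gates = gates,
              trajectories = trajs)
  if (phospho) {
    pconf <- config
    pconf$n_replicates <- 2L
    ph <- simulate_phosphosites(pconf)
    out$sites <- ph$sites
    out$site_truth <- ph$ground_truth
  }
  out
}

#' Simulate a complete mitotic subpopulation dataset
#'
#' The intra-mitotic study design: mitotic cells sorted into prophase
#' (Pro), cyclin A+ prometaphase (PM1), cyclin A- prometaphase (PM2) and
#' anaphase (Ana) gates, quantified across three biological replicates —
#' two SILAC replicates plus one TMT 6-plex replicate whose reporters pass
#' through the isotope-impurity/compression forward model. The proteome is
#' mostly unchanged across mitosis (`n_flat` constant-per-cell proteins)
#' with planted degradation: proteins degraded from PM1, from PM2 or at
#' anaphase, at the configured residual levels.
#'
#' @param config A [simulation_config()] (noise, purity, dropout, seed;
#'   `n_replicates` is the total replicate count, default 3).
#' @param n_flat Number of unregulated proteins.
#' @param n_degraded Named counts of degraded proteins per trough
#'   subphase, default `c(PM1 = 47, PM2 = 3, Ana = 10)` (the 79/5/16%
#'   split observed among mitotically degraded proteins).
#' @param residual_pm,residual_ana Residual level after degradation for
#'   prometaphase- and anaphase-degraded proteins.
#' @param impurity_matrix TMT impurity matrix (6 channels), default
#'   [default_impurity_matrix()].
#' @param include_tmt Simulate the TMT replicate (default). With
#'   `FALSE`, all replicates are SILAC-labelled and the TMT stream is
#'   absent; note a TMT fraction ratio carries roughly twice the noise
#'   variance of a SILAC ratio (reporter over reference channel).
#' @return List: `silac`, `tmt_raw` (reporters), `tmt` (inverted to
#'   ratios), `merged`, `ground_truth`, `population`, `gates`,
#'   `channel_map`, `impurity_matrix`.
#' @export
simulate_mitotic_dataset <- function(
    config = simulation_config(n_replicates = 3),
    n_flat = 2000,
    n_degraded = c(PM1 = 47, PM2 = 3, Ana = 10),
    residual_pm = 0.4, residual_ana = 0.3,
    impurity_matrix = default_impurity_matrix(),
    include_tmt = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  sub <- mitotic_subphase_times()
  population <- sample_population(config)

  # gates over the mitotic window: cumulative frequencies at subphase edges
  edges_f <- age_cdf(sub[, "end"])
  names(edges_f) <- rownames(sub)
  gates <- assign_gates(population, edges_f, config$gate_purity,
                        lower_bound = age_cdf(sub["Pro", "start"]))

  trajs <- c(
    make_trajectory_set(c(constant_per_cell = n_flat)),
    make_trajectory_set(
      c(prometaphase_degraded = unname(n_degraded["PM1"])),
      class_args = list(prometaphase_degraded =
                          list(degrade_start = sub["PM1", "start"],
                               residual = residual_pm))),
    make_trajectory_set(
      c(prometaphase_degraded = unname(n_degraded["PM2"])),
      class_args = list(prometaphase_degraded =
                          list(degrade_start = sub["PM2", "start"],
                               residual = residual_pm))),
    make_trajectory_set(
      c(anaphase_degraded = unname(n_degraded["Ana"])),
      class_args = list(anaphase_degraded =
                          list(degrade_start = sub["Ana", "start"],
                               residual = residual_ana)))
  )
  names(trajs) <- sprintf("P%04d", seq_along(trajs))
  trough <- c(rep(NA_character_, n_flat),
              rep(names(n_degraded), n_degraded))

  nrep_silac <- if (include_tmt) max(1L, config$n_replicates - 1L)
                else config$n_replicates
  sconf <- config
  sconf$n_replicates <- nrep_silac
  sim <- simulate_silac_matrix(population, gates, trajs, sconf)

  # TMT replicate: 6-plex over G2, M, Pro, PM2, PM1, Ana
  cmap <- mitotic_channel_map()
  tmt_raw <- NULL
  tmt_pm <- NULL
  if (include_tmt) {
  g2_gate <- assign_gates(population,
                          c(G2 = age_cdf(sub["Pro", "start"]),
                            M = age_cdf(1)),
                          config$gate_purity,
                          lower_bound = 0.65)
  ids <- names(trajs)
  true6 <- matrix(NA_real_, length(ids), 6,
                  dimnames = list(ids, names(cmap)))
  for (i in seq_along(trajs)) {
    a <- trajectory_abundance(trajs[[i]], population$t)
    standard <- mean(a)
    vals <- c(
      G2 = mean(a[g2_gate$gates[["G2"]]]),
      M = mean(a[g2_gate$gates[["M"]]]),
      Pro = mean(a[gates$gates[["Pro"]]]),
      PM2 = mean(a[gates$gates[["PM2"]]]),
      PM1 = mean(a[gates$gates[["PM1"]]]),
      Ana = mean(a[gates$gates[["Ana"]]])
    ) / standard
    true6[i, ] <- vals[unname(cmap[colnames(true6)])]
  }
  tmt_raw <- simulate_tmt_reporters(true6, impurity_matrix,
                                    compression = config$compression,
                                    config = config,
                                    intensity_scale = 1e5)
  corrected <- correct_isotope_impurities(tmt_raw, impurity_matrix)
  ratios6 <- reference_ratios(normalize_reporters(corrected), cmap, "Pro")
  ratios6[ratios6 <= 0] <- NA_real_  # clamped channels are missing, not zero
  mit <- c("Pro", "PM1", "PM2", "Ana")
  tmt_pm <- profile_matrix(ratios6[, mit, drop = FALSE],
                           fractions = mit,
                           replicates = rep(1L, 4),
                           source = "tmt")
  }

  silac_norm <- normalize_silac(sim$matrix, "pro1",
                                reference_fraction = "Pro")
  merged <- if (include_tmt) merge_datasets(silac_norm, tmt_pm)
            else silac_norm

  gt <- sim$ground_truth
  gt$trough <- trough
  gt$regulated <- !is.na(trough)

  list(silac = sim$matrix, silac_norm = silac_norm, tmt_raw = tmt_raw,
       tmt = tmt_pm, merged = merged, ground_truth = gt,
       population = population, gates = gates, channel_map = cmap,
       impurity_matrix = impurity_matrix, trajectories = trajs)
}

stage_log <- function(log_lines, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  c(log_lines, line)
}

#' Run the interphase analysis pipeline end to end
#'
#' Stage order: simulate (or read) -> normalize to G1 -> ergodic timeline
#' -> bulk accumulation profile and exponential growth fit -> candidate
#' selection (fold cutoff + ANOVA) -> phosphosite dynamics (residue and
#' motif statistics, early-riser classification). Every stage failure
#' aborts with a stage-named error; outputs and a provenance record are
#' written under `out_dir`.
#'
#' @param config Named list: `seed`, optionally `n_proteins`, `noise_cv`,
#'   `dropout_rate`, `z_multiplier`, `p_cutoff`, `out_dir`. Pass the
#'   result of [read_run_config()] or a plain list.
#' @param out_dir Output directory (created if needed).
#' @return Invisible list of all stage results.
#' @export
run_interphase_pipeline <- function(config = list(seed = 1L),
                                    out_dir = tempfile("interphase_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  simc <- simulation_config(
    n_proteins = config$n_proteins %||%
      c(bulk_exponential = 1500, histone_plateau = 60,
        mitotic_peak = 60, constant_per_cell = 380),
    noise_cv = config$noise_cv %||% 0.15,
    dropout_rate = config$dropout_rate %||% 0.02,
    n_replicates = config$n_replicates %||% 4L,
    seed = config$seed %||% 1L)

  ds <- run_stage("simulate", simulate_interphase_dataset(simc))
  log_lines <- stage_log(log_lines, "simulate",
                         sprintf("%d proteins x %d columns, %d sites",
                                 nrow(ds$matrix$ratios),
                                 ncol(ds$matrix$ratios), nrow(ds$sites)))

  norm <- run_stage("normalize", normalize_silac(ds$matrix, "g1",
                                                 reference_fraction = "G1"))
  log_lines <- stage_log(log_lines, "normalize",
                         sprintf("normalized to G1; %d replicate rows excluded",
                                 nrow(attr(norm, "excluded"))))

  timeline <- ds$timeline
  utils::write.csv(as.data.frame(timeline),
                   file.path(out_dir, "timeline.csv"), row.names = FALSE)

  med <- replicate_median_profile(norm)
  bulk_ids <- ds$ground_truth$protein_id[
    ds$ground_truth$class_label == "bulk_exponential"]
  bulk <- run_stage("accumulation",
                    bulk_mean_profile(med[bulk_ids, , drop = FALSE], "G1"))
  fit <- run_stage("accumulation",
                   fit_exponential(timeline$t, bulk$ratio_rel))
  log_lines <- stage_log(log_lines, "accumulation",
                         sprintf("growth fit m=%.4f fold=%.3f R2=%.4f",
                                 fit$m, fit$fold_over_cycle, fit$r2))
  utils::write.csv(bulk, file.path(out_dir, "bulk_profile.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(m = fit$m, r2 = fit$r2,
                            fold_over_cycle = fit$fold_over_cycle),
                       file.path(out_dir, "growth_fit.json"),
                       auto_unbox = TRUE, digits = NA)

  selc <- selection_config("interphase",
                           z_multiplier = config$z_multiplier %||% 1.96,
                           p_cutoff = config$p_cutoff %||% 0.05)
  verdicts <- run_stage("select", select_candidates(norm, selc))
  log_lines <- stage_log(log_lines, "select",
                         sprintf("%d/%d significant (fold cutoff %.3f)",
                                 sum(verdicts$significant), nrow(verdicts),
                                 attr(verdicts, "z_threshold")))
  utils::write.csv(verdicts, file.path(out_dir, "verdicts.csv"),
                   row.names = FALSE)

  phr <- run_stage("phospho", phospho_dynamics_report(ds$sites))
  log_lines <- stage_log(log_lines, "phospho",
                         sprintf("%d sites; %d early risers, %d late",
                                 nrow(ds$sites),
                                 sum(phr$risers$label == "early"),
                                 sum(phr$risers$label == "late")))
  utils::write.csv(phr$risers, file.path(out_dir, "early_risers.csv"),
                   row.names = FALSE)
  jsonlite::write_json(phr$summary,
                       file.path(out_dir, "phospho_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  write_provenance(out_dir, config, simc$seed)
  invisible(list(dataset = ds, normalized = norm, timeline = timeline,
                 bulk = bulk, fit = fit, verdicts = verdicts,
                 phospho = phr, out_dir = out_dir))
}

#' Phosphosite dynamics report
#'
#' Residue frequencies, CDK motif statistics, k-means clustering of the
#' site dynamics and early/late riser classification. Sites are clustered
#' on per-row mean-centred log2 profiles into `k` groups (k = 6 is the
#' published choice for phosphosite dynamics); sites belonging to clusters
#' whose centroid peaks in the mitotic fraction are the mitotically rising
#' set, which is then split into early risers (already significantly
#' elevated in G2) and late risers.
#'
#' @param sites Phosphosite data frame (see [simulate_phosphosites()]).
#' @param k Number of site clusters.
#' @param m_fraction Mitotic fraction label.
#' @param seed Seed for the clustering restarts.
#' @return List: `risers` (per-site classification), `clusters`, `motifs`,
#'   `summary` (residue frequencies, motif fractions, riser counts).
#' @export
phospho_dynamics_report <- function(sites, k = 6, m_fraction = "M",
                                    seed = 1L) {
  spm <- site_profile_matrix(sites)
  lm2 <- log2(spm$ratios)
  complete <- !apply(is.na(lm2), 1, any)
  lp <- lm2[complete, , drop = FALSE]
  lp <- lp - rowMeans(lp)
  cl <- kmeans_cluster(lp, min(k, nrow(lp)), seed = seed)
  # clusters whose centroid peaks in the mitotic fraction
  fr <- spm$fractions
  cent_by_fr <- vapply(unique(fr), function(f) {
    rowMeans(cl$centers[, fr == f, drop = FALSE])
  }, numeric(nrow(cl$centers)))
  m_peaking <- which(max.col(cent_by_fr, ties.method = "first") ==
                       match(m_fraction, unique(fr)))
  sig <- stats::setNames(rep(FALSE, nrow(spm$ratios)),
                         rownames(spm$ratios))
  sig[names(cl$cluster)[cl$cluster %in% m_peaking]] <- TRUE
  risers <- classify_early_risers(spm, sig, m_fraction = m_fraction)
  motifs <- motif_match(sites$sequence_window)
  rf <- residue_frequencies(sites)
  list(
    risers = risers,
    clusters = cl,
    m_peaking_clusters = m_peaking,
    motifs = motifs,
    summary = list(
      residue_freq = as.list(rf),
      proline_directed_fraction = mean(motifs$proline_directed),
      full_cdk_fraction = mean(motifs$full_cdk_consensus),
      n_early = sum(risers$label == "early"),
      n_late = sum(risers$label == "late")
    )
  )
}

#' Run the mitotic subpopulation pipeline end to end
#'
#' Stage order: simulate (or read) both quantitation streams -> normalize
#' (SILAC to the prophase fraction of replicate 1; TMT impurity-corrected,
#' sum-normalized, referenced to Pro) -> merge on the leading razor
#' protein identifier -> candidate selection (fold cutoff + replicate
#' correlation + missing-value rescue) -> k-means clustering of the
#' significant profiles -> trough-phase agglomeration. Outputs, a stage
#' log and a provenance record are written under `out_dir`.
#'
#' @param config Named list; honoured fields: `seed`, `n_flat`,
#'   `n_degraded`, `noise_cv`, `dropout_rate`, `z_multiplier`, `k`
#'   (cluster count; `NULL` selects by WSS elbow over `k_scan`), `k_scan`.
#' @param out_dir Output directory.
#' @return Invisible list of stage results.
#' @export
run_mitotic_pipeline <- function(config = list(seed = 1L),
                                 out_dir = tempfile("mitotic_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  simc <- simulation_config(
    noise_cv = config$noise_cv %||% 0.15,
    dropout_rate = config$dropout_rate %||% 0.02,
    n_replicates = config$n_replicates %||% 3L,
    seed = config$seed %||% 1L)
  include_tmt <- config$include_tmt %||% TRUE
  if (!include_tmt) warning("TMT absent: running on the SILAC stream only")
  ds <- run_stage("simulate", simulate_mitotic_dataset(
    simc,
    n_flat = config$n_flat %||% 2000,
    n_degraded = config$n_degraded %||% c(PM1 = 47, PM2 = 3, Ana = 10),
    include_tmt = include_tmt))
  log_lines <- stage_log(log_lines, "simulate",
                         sprintf("%d proteins; overlap SILAC/TMT %.0f%%",
                                 nrow(ds$merged$ratios),
                                 100 * (attr(ds$merged, "overlap_fraction")
                                        %||% 1)))

  selc <- selection_config("mitotic",
                           z_multiplier = config$z_multiplier %||% 1.96)
  verdicts <- run_stage("select", select_candidates(ds$merged, selc))
  log_lines <- stage_log(
    log_lines, "select",
    sprintf("fold cutoff %.3f-fold; %d pass fold, %d significant, %d rescued",
            attr(verdicts, "z_threshold"), sum(verdicts$passes_fold),
            sum(verdicts$significant), sum(verdicts$rescued)))
  utils::write.csv(verdicts, file.path(out_dir, "verdicts.csv"),
                   row.names = FALSE)

  med <- replicate_median_profile(ds$merged)
  sig_ids <- verdicts$protein_id[verdicts$significant & !verdicts$rescued]
  prof <- med[sig_ids, , drop = FALSE]
  prof <- prof[!apply(is.na(prof), 1, any), , drop = FALSE]
  lp <- log2(prof)
  lp <- lp - rowMeans(lp)  # per-row mean-centred log2 profiles

  k <- config$k %||% NULL
  if (is.null(k)) {
    scan <- run_stage("cluster",
                      choose_k_wss(lp, config$k_scan %||% 1:8,
                                   seed = simc$seed))
    k <- scan$k
    utils::write.csv(scan$wss, file.path(out_dir, "wss_scan.csv"),
                     row.names = FALSE)
  }
  k <- min(k, nrow(lp))
  cl <- run_stage("cluster", kmeans_cluster(lp, k, seed = simc$seed))
  log_lines <- stage_log(log_lines, "cluster",
                         sprintf("k = %d over %d profiles", k, nrow(lp)))

  groups <- run_stage("agglomerate", agglomerate_by_trough(cl, prof))
  pg <- attr(groups, "protein_groups")
  log_lines <- stage_log(
    log_lines, "agglomerate",
    paste(utils::capture.output(print(table(pg))), collapse = " | "))
  utils::write.csv(
    data.frame(protein_id = names(cl$cluster), cluster = cl$cluster,
               trough_group = unname(pg[names(cl$cluster)])),
    file.path(out_dir, "clusters.csv"), row.names = FALSE)
  utils::write.csv(groups, file.path(out_dir, "trough_groups.csv"),
                   row.names = FALSE)

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  write_provenance(out_dir, config, simc$seed)
  invisible(list(dataset = ds, verdicts = verdicts, clusters = cl,
                 trough_groups = groups, out_dir = out_dir))
}
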