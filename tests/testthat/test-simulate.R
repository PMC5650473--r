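test_that("sampled ages follow the exponential-growth age distribution", {
  cfg <- simulation_config(n_cells = 1e5, seed = 1)
  pop <- sample_population(cfg)
  expect_equal(mean(pop$t <= 1), 1)                       # CDF endpoint
  # fraction of cells before the G1 boundary ~ the printed 21%
  expect_equal(mean(pop$t <= 0.16), 0.21, tolerance = 0.02)
  # mean per-cell content of a doubling protein ~ 2 ln 2 = 1.386
  expect_equal(mean(2^pop$t), 2 * log(2), tolerance = 0.01)
  expect_error(sample_population(simulation_config(n_cells = 0)), "positive")
})

test_that("gate assignment is deterministic at purity 1 with a diagonal confusion", {
  cfg <- simulation_config(n_cells = 2e4, gate_purity = 1, seed = 2)
  pop <- sample_population(cfg)
  ga <- assign_gates(pop, cfg$phase_boundaries, 1)
  expect_true(all(ga$confusion[upper.tri(ga$confusion)] == 0))
  expect_true(all(ga$confusion[lower.tri(ga$confusion)] == 0))
  expect_equal(unname(ga$purity), rep(1, 4))
  # a cell at t = 0.05 is in G1
  expect_true(0.05 < cumulative_to_time(0.21))
  expect_true(all(pop$t[ga$gates$G1] < cumulative_to_time(0.21)))
  # empirical gate frequencies converge to differences of cumulative freqs
  sizes <- vapply(ga$gates, length, 1L)
  expect_lt(max(abs(sizes / nrow(pop) - diff(c(0, cfg$phase_boundaries)))),
            0.02)
  expect_error(assign_gates(pop, c(G1 = 0.5, S = 0.4), 1), "overlap")
})

test_that("gate purity sets the measured mitotic index of the M gate", {
  cfg <- simulation_config(n_cells = 1e5, gate_purity = 0.96, seed = 3)
  pop <- sample_population(cfg)
  ga <- assign_gates(pop, cfg$phase_boundaries, 0.96)
  expect_equal(unname(ga$purity["M"]), 0.96, tolerance = 0.01)
})

test_that("noise-free SILAC gate ratios match the quadrature oracle", {
  cfg <- simulation_config(
    n_cells = 1e5, noise_cv = 0, dropout_rate = 0, n_replicates = 1,
    gate_purity = 1, seed = 4)
  pop <- sample_population(cfg)
  ga <- assign_gates(pop, cfg$phase_boundaries, 1)
  trajs <- list(
    bulk = trajectory("bulk_exponential"),
    flat = trajectory("constant_per_cell", baseline = 5)
  )
  sim <- simulate_silac_matrix(pop, ga, trajs, cfg)
  m <- replicate_profile(sim$matrix, 1)
  # oracle: gate-mean of 2^t over [0, t(0.21)] relative to async mean.
  # Closed form t_G1 / F_G1 = 0.762 (NOT the position value 0.806).
  g1_oracle <- oracle_gate_ratio(function(t) 2^t, 0, cumulative_to_time(0.21))
  expect_equal(g1_oracle, cumulative_to_time(0.21) / 0.21, tolerance = 1e-9)
  expect_equal(unname(m["bulk", "G1"]), g1_oracle, tolerance = 0.01)
  # constant-per-cell protein: ratio 1 in every gate
  expect_equal(unname(m["flat", ]), rep(1, 4), tolerance = 0.01)
})

test_that("position-mode measurement sits on the ergodic model curve", {
  cfg <- simulation_config(n_cells = 1e3, noise_cv = 0, dropout_rate = 0,
                           n_replicates = 1, gate_purity = 1, seed = 5)
  pop <- sample_population(cfg)
  ga <- assign_gates(pop, cfg$phase_boundaries, 1)
  sim <- simulate_silac_matrix(pop, ga,
                               list(bulk = trajectory("bulk_exponential")),
                               cfg, measure = "position")
  m <- replicate_profile(sim$matrix, 1)
  t_gates <- cumulative_to_time(cfg$phase_boundaries)
  expect_equal(unname(m["bulk", ]),
               unname(expected_relative_content(t_gates)), tolerance = 1e-8)
  expect_equal(unname(m["bulk", "G1"]), 0.81, tolerance = 0.005)
})

test_that("anaphase-degraded proteins read out their residual against prophase", {
  cfg <- simulation_config(n_cells = 1e5, noise_cv = 0, dropout_rate = 0,
                           n_replicates = 1, gate_purity = 1, seed = 6)
  sub <- mitotic_subphase_times()
  pop <- sample_population(cfg)
  edges_f <- age_cdf(sub[, "end"]); names(edges_f) <- rownames(sub)
  ga <- assign_gates(pop, edges_f, 1, lower_bound = age_cdf(sub["Pro", "start"]))
  tr <- list(ana = trajectory("anaphase_degraded", residual = 0.3))
  sim <- simulate_silac_matrix(pop, ga, tr, cfg)
  m <- replicate_profile(sim$matrix, 1)
  expect_equal(unname(m["ana", "Ana"] / m["ana", "Pro"]), 0.30,
               tolerance = 1e-9)
})

test_that("content conservation: a doubling proteome self-normalizes", {
  # population-weighted mean relative content of a bulk protein is 1:
  # the asynchronous standard IS the population mean
  cfg <- simulation_config(n_cells = 5e4, seed = 7)
  pop <- sample_population(cfg)
  tr <- trajectory("bulk_exponential", baseline = 4)
  rel <- trajectory_abundance(tr, pop$t) /
    mean(trajectory_abundance(tr, pop$t))
  expect_equal(mean(rel), 1, tolerance = 1e-12)
})

test_that("simulation is bit-identical under a fixed seed", {
  run <- function() {
    cfg <- simulation_config(n_cells = 5e3,
                             n_proteins = c(bulk_exponential = 20),
                             dropout_rate = 0.1, seed = 11)
    simulate_interphase_dataset(cfg, phospho = TRUE)
  }
  a <- run(); b <- run()
  expect_identical(a$matrix$ratios, b$matrix$ratios)
  expect_identical(a$sites, b$sites)
})

test_that("dropout injects missingness at the configured rate", {
  cfg <- simulation_config(n_cells = 5e3,
                           n_proteins = c(constant_per_cell = 400),
                           dropout_rate = 0.2, n_replicates = 3, seed = 8)
  ds <- simulate_interphase_dataset(cfg, phospho = FALSE)
  expect_equal(mean(is.na(ds$matrix$ratios)), 0.2, tolerance = 0.02)
  # abundance-dependent mode misses low-abundance proteins preferentially
  cfg2 <- cfg; cfg2$dropout_mode <- "abundance"
  ds2 <- simulate_interphase_dataset(cfg2, phospho = FALSE)
  base <- vapply(ds2$trajectories, `[[`, 1, "baseline")
  miss <- rowMeans(is.na(ds2$matrix$ratios))
  expect_lt(cor(log(base), miss), 0)
})

test_that("TMT forward model: impurity mixing and ratio compression", {
  # identity matrix, no compression, no noise: reporters equal true values
  x <- matrix(c(100, 50, 25, 10, 5, 1), 1,
              dimnames = list("P1", paste0("ch", 1:6)))
  expect_equal(simulate_tmt_reporters(x, diag(6)), x)
  # 2-channel cross-contamination: direct matrix product
  m2 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2)
  obs <- simulate_tmt_reporters(matrix(c(100, 0), 1,
                                       dimnames = list("P1", NULL)), m2)
  expect_equal(unname(obs[1, ]), c(90, 10))
  # compression halves log-ratios: true 4:1 observed as 2:1
  y <- matrix(c(4, 1), 1, dimnames = list("P1", NULL))
  comp <- simulate_tmt_reporters(y, diag(2), compression = 0.5)
  expect_equal(unname(comp[1, 1] / comp[1, 2]), 2, tolerance = 1e-12)
  expect_error(simulate_tmt_reporters(matrix(-1, 1, 1,
                                             dimnames = list("P1", NULL)),
                                      diag(1)), "negative")
})

test_that("simulated phosphosites carry windows, residues and planted dynamics", {
  cfg <- simulation_config(n_replicates = 2, noise_cv = 0, seed = 9)
  ph <- simulate_phosphosites(cfg, n_sites = c(early_riser = 50,
                                               late_riser = 50, flat = 50))
  expect_true(all(nchar(ph$sites$sequence_window) == 15))
  expect_true(all(substr(ph$sites$sequence_window, 8, 8) ==
                    ph$sites$amino_acid))
  spm <- site_profile_matrix(ph$sites)
  m <- replicate_profile(spm, 1)
  early <- ph$ground_truth$site_id[ph$ground_truth$class_label == "early_riser"]
  flat <- ph$ground_truth$site_id[ph$ground_truth$class_label == "flat"]
  # noise-free construction: G1 <= S <= G2 < M with G2 > G1
  expect_true(all(m[early, "G1"] <= m[early, "S"]))
  expect_true(all(m[early, "S"] <= m[early, "G2"]))
  expect_true(all(m[early, "G2"] < m[early, "M"]))
  expect_true(all(m[early, "G2"] > m[early, "G1"]))
  # flat sites: max/min fold exactly 1 at zero noise
  expect_equal(unname(apply(m[flat, ], 1, max) / apply(m[flat, ], 1, min)),
               rep(1, length(flat)), tolerance = 1e-12)
})

test_that("configured residue frequencies are recovered at large n", {
  cfg <- simulation_config(n_replicates = 1, seed = 10)
  ph <- simulate_phosphosites(cfg, n_sites = c(flat = 20000),
                              residue_freq = c(S = 0.832, T = 0.158,
                                               Y = 0.010))
  f <- residue_frequencies(ph$sites)
  expect_equal(unname(f), c(0.832, 0.158, 0.010), tolerance = 0.01)
})
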