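test_that("isotope impurity correction inverts the forward model", {
  set.seed(1)
  truth <- matrix(rlnorm(60 * 6, 2, 1), 60,
                  dimnames = list(sprintf("P%02d", 1:60), NULL))
  m <- default_impurity_matrix(6, spill = 0.04)
  observed <- simulate_tmt_reporters(truth, m)      # zero noise
  recovered <- correct_isotope_impurities(observed, m)
  expect_equal(unname(recovered), unname(truth), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_false(any(attr(recovered, "clamped")))
  # identity: output equals input
  expect_equal(unname(correct_isotope_impurities(truth, diag(6))),
               unname(truth), ignore_attr = TRUE)
  # hand-checkable 2-channel solve
  obs2 <- matrix(c(90, 10), 1, dimnames = list("P1", NULL))
  m2 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2)
  expect_equal(unname(correct_isotope_impurities(obs2, m2)[1, ]),
               c(100, 0), tolerance = 1e-9)
  # all-zero observation stays zero
  expect_equal(unname(correct_isotope_impurities(
    matrix(0, 1, 2, dimnames = list("P1", NULL)), m2)[1, ]), c(0, 0))
  expect_error(correct_isotope_impurities(obs2, matrix(0.5, 2, 2)),
               "singular")
  expect_error(correct_isotope_impurities(obs2, diag(3)), "dimension")
})

test_that("negative solutions are clamped to zero and flagged", {
  m2 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2)
  # observation impossible under the mixing model -> negative solve
  obs <- matrix(c(1, 100), 1, dimnames = list("P1", NULL))
  out <- correct_isotope_impurities(obs, m2)
  expect_true(attr(out, "clamped")[1])
  expect_true(all(out >= 0))
})

test_that("sum normalization makes every row a unit distribution", {
  x <- rbind(a = c(2, 2, 2, 2, 2, 2), b = c(10, 0, 0, 0, 0, 0),
             c = 1:6)
  n <- normalize_reporters(x)
  expect_equal(unname(rowSums(n)), c(1, 1, 1))
  expect_equal(unname(n["a", ]), rep(1 / 6, 6))
  expect_equal(unname(n["b", ]), c(1, 0, 0, 0, 0, 0))
  expect_equal(unname(n["c", ]), (1:6) / 21)
  expect_error(normalize_reporters(rbind(z = rep(0, 6))), "all-zero")
})

test_that("reference ratios fix the reference fraction at 1 via the channel map", {
  cmap <- mitotic_channel_map()
  x <- matrix(rep(c(0.1, 0.15, 0.2, 0.25, 0.25, 0.05), 2), 2, byrow = TRUE,
              dimnames = list(c("P1", "P2"), names(cmap)))
  x["P2", ] <- rep(1 / 6, 6)
  rr <- reference_ratios(x, cmap, "Pro")
  expect_equal(unname(rr["P1", "Pro"]), 1)
  expect_equal(unname(rr["P2", ]), rep(1, 6))
  # Pro channel 0.2, Ana channel 0.05 -> Ana ratio 0.25
  expect_equal(unname(rr["P1", "Ana"]), 0.05 / 0.2)
  # zero reference is flagged missing, not dropped
  x["P1", "128C"] <- 0
  rr2 <- reference_ratios(x, cmap, "Pro")
  expect_true(all(is.na(rr2["P1", ])))
  expect_identical(attr(rr2, "missing_reference"), "P1")
  expect_error(reference_ratios(x, cmap, "G0"), "absent")
})

test_that("SILAC normalization to G1 is per replicate, exact and idempotent", {
  vals <- matrix(c(0.8, 1.0, 1.2, 1.3,   # replicate 1
                   0.5, 0.6, 0.7, 0.8),  # replicate 2
                 1, 8, dimnames = list("P1", NULL))
  pm <- make_pm(vals, c("G1", "S", "G2", "M"), 2)
  norm <- normalize_silac(pm, "g1")
  expect_equal(unname(norm$ratios[1, 1:4]), c(1, 1.25, 1.5, 1.625))
  expect_equal(unname(norm$ratios[1, 5:8]), c(0.5, 0.6, 0.7, 0.8) / 0.5)
  # idempotence: already-normalized input is unchanged
  norm2 <- normalize_silac(norm, "g1")
  expect_identical(norm2$ratios, norm$ratios)
  expect_true(all(norm$ratios[, c(1, 5)] == 1))
})

test_that("a replicate missing its reference is excluded and logged", {
  vals <- matrix(c(NA, 1.0, 1.2, 1.3,
                   0.5, 0.6, 0.7, 0.8), 1, 8, dimnames = list("P1", NULL))
  pm <- make_pm(vals, c("G1", "S", "G2", "M"), 2)
  norm <- normalize_silac(pm, "g1")
  expect_true(all(is.na(norm$ratios[1, 1:4])))
  expect_false(anyNA(norm$ratios[1, 5:8]))
  log <- attr(norm, "excluded")
  expect_equal(log$protein_id, "P1")
  expect_equal(log$replicate, 1)
})

test_that("mitotic-mode normalization divides all replicates by Pro of replicate 1", {
  vals <- matrix(c(2, 1, 0.8, 0.6,    # rep 1, Pro first
                   4, 2, 1.6, 1.2),   # rep 2 (global 2x offset)
                 1, 8, dimnames = list("P1", NULL))
  pm <- make_pm(vals, c("Pro", "PM1", "PM2", "Ana"), 2)
  norm <- normalize_silac(pm, "pro1", reference_fraction = "Pro")
  expect_equal(unname(norm$ratios[1, ]), c(vals / 2))
  # between-replicate offset is preserved (unlike per-replicate mode)
  expect_equal(unname(norm$ratios[1, 5] / norm$ratios[1, 1]), 2)
})

test_that("replicate medians follow the textbook definition", {
  vals <- matrix(c(1, 2, 3), 1, 3, dimnames = list("P1", NULL))
  pm <- make_pm(vals, "G1", 3)
  expect_equal(unname(replicate_median_profile(pm)[1, "G1"]), 2)
  pm2 <- make_pm(matrix(c(1, 4), 1, 2, dimnames = list("P1", NULL)), "G1", 2)
  expect_equal(unname(replicate_median_profile(pm2)[1, "G1"]), 2.5)
  # single replicate: identity; all-missing fraction: NA
  pm3 <- make_pm(matrix(c(7, NA), 1, 2, dimnames = list("P1", NULL)),
                 c("G1", "S"), 1)
  med <- replicate_median_profile(pm3)
  expect_equal(unname(med[1, "G1"]), 7)
  expect_true(is.na(med[1, "S"]))
})

test_that("merging datasets is a lossless outer join with overlap accounting", {
  a <- make_pm(matrix(1:8 / 4, 2, 4,
                      dimnames = list(c("P1", "P2"), NULL)),
               c("Pro", "PM1", "PM2", "Ana"), 1)
  b <- make_pm(matrix(2:9 / 4, 2, 4,
                      dimnames = list(c("P2", "P3"), NULL)),
               c("Pro", "PM1", "PM2", "Ana"), 1, source = "tmt")
  m <- merge_datasets(a, b)
  expect_equal(nrow(m$ratios), 3)
  expect_equal(attr(m, "overlap"), 1)
  expect_equal(attr(m, "overlap_fraction"), 1 / 3)
  # split by source recovers both inputs without value mutation
  silac_cols <- m$source == "silac"
  expect_equal(unname(m$ratios[c("P1", "P2"), silac_cols]),
               unname(a$ratios))
  expect_equal(unname(m$ratios[c("P2", "P3"), !silac_cols]),
               unname(b$ratios))
  # TMT replicate indices are shifted past the SILAC ones
  expect_equal(unique(m$replicates[!silac_cols]), 2L)

  disj <- merge_datasets(a, make_pm(b$ratios[, ],
                                    c("Pro", "PM1", "PM2", "Ana"), 1,
                                    ids = c("Q1", "Q2"), source = "tmt"))
  expect_equal(nrow(disj$ratios), 4)
  expect_equal(attr(disj, "overlap"), 0)
  ident <- merge_datasets(a, make_pm(a$ratios[, ],
                                     c("Pro", "PM1", "PM2", "Ana"), 1,
                                     source = "tmt"))
  expect_equal(attr(ident, "overlap_fraction"), 1)
})

test_that("duplicate identifiers are rejected with the offenders listed", {
  vals <- matrix(1, 2, 2)
  rownames(vals) <- c("P1", "P1")
  expect_error(profile_matrix(vals, c("G1", "S"), c(1, 1)), "P1")
})
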