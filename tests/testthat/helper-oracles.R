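# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths wherever they check one.

# Quadrature oracle for the expected SILAC ratio of a sorted gate:
# mean trajectory abundance over cells with age in [t_lo, t_hi], weighted by
# the ergodic age density, divided by the population-mean abundance.
oracle_gate_ratio <- function(abundance_fn, t_lo, t_hi) {
  dens <- function(t) 2 * log(2) * 2^(-t)
  num <- stats::integrate(function(t) abundance_fn(t) * dens(t),
                          t_lo, t_hi, rel.tol = 1e-12)$value
  mass <- stats::integrate(dens, t_lo, t_hi, rel.tol = 1e-12)$value
  pop <- stats::integrate(function(t) abundance_fn(t) * dens(t),
                          0, 1, rel.tol = 1e-12)$value
  (num / mass) / pop
}

# Exact two-sided hypergeometric p for a 2x2 table, by direct enumeration
# of the conditional distribution (sum of point probabilities not exceeding
# the observed one).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c          # total with the label
  n <- b + d          # total without
  k <- a + b          # candidate-set size
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random 15-mer windows, occasionally '_'-padded at the ends as at protein
# termini, with S/T centres and prolines frequent enough to exercise both
# motif flags.
oracle_random_windows <- function(n) {
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    w <- sample(alphabet, 15, replace = TRUE)
    w[8] <- sample(c("S", "T", "Y", "A"), 1, prob = c(.4, .25, .15, .2))
    if (stats::runif(1) < 0.4) w[9] <- "P"
    if (stats::runif(1) < 0.4) w[11] <- sample(c("K", "R", "Q"), 1)
    npad <- sample(0:3, 1)
    if (npad && stats::runif(1) < 0.5) w[seq_len(npad)] <- "_"
    else if (npad) w[15 - seq_len(npad) + 1] <- "_"
    paste(w, collapse = "")
  }, character(1))
}

# Quick builder for small profile matrices in tests: `values` is a
# proteins x (fraction x replicate) matrix laid out fraction-fastest.
make_pm <- function(values, fractions, n_rep, ids = NULL, source = "silac") {
  values <- as.matrix(values)
  if (is.null(ids)) {
    ids <- rownames(values)
    if (is.null(ids)) ids <- sprintf("P%03d", seq_len(nrow(values)))
  }
  rownames(values) <- ids
  profile_matrix(values,
                 fractions = rep(fractions, times = n_rep),
                 replicates = rep(seq_len(n_rep), each = length(fractions)),
                 source = source)
}

# Flat-proteome null profile matrix under the package's lognormal noise
# model (CV on ratios), built directly rather than through the simulator.
make_null_pm <- function(n, fractions, n_rep, cv = 0.15) {
  sdlog <- sqrt(log(1 + cv^2))
  vals <- matrix(stats::rlnorm(n * length(fractions) * n_rep, 0, sdlog), n)
  make_pm(vals, fractions, n_rep)
}
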