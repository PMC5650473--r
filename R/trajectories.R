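#' Per-cell protein abundance trajectories across the cell cycle
#'
#' A trajectory model describes a protein's per-cell abundance `a(t)` as a
#' function of normalized cell-cycle position `t` in `[0, 1]`. Six classes
#' cover the behaviours seen in sorted-fraction proteomics:
#'
#' * `bulk_exponential` — the typical protein accumulates with cell mass
#'   and doubles exactly over one cycle: `a(t) = baseline * 2^t`.
#' * `histone_plateau` — synthesized during S phase alongside DNA
#'   replication, then flat through G2/M at twice the G1 level.
#' * `mitotic_peak` — low in interphase, rising sharply into mitosis to
#'   `peak_fold` times baseline (AURKA-like; default 8-fold).
#' * `prometaphase_degraded` — degraded at prometaphase onset to a residual
#'   fraction of the prophase level (cyclin-A/RRM2-like; default residual
#'   0.4).
#' * `anaphase_degraded` — degraded at anaphase onset (cyclin-B-like;
#'   default residual 0.3, i.e. anaphase levels fall to ~30% of prophase).
#' * `constant_per_cell` — flat on a per-cell basis; its ratio to the
#'   asynchronous standard is 1 in every sorted fraction.
#'
#' The mitotic subphases (Pro, PM1, PM2, Ana) have no published numeric
#' positions; they are modelled as four equal, ordered sub-intervals of the
#' M window (see [mitotic_subphase_times()]). Degradation is a step drop at
#' the start of the stated subphase, so trajectories are non-increasing
#' across their degradation window and strictly positive everywhere.
#'
#' @param class_label One of the six class labels above.
#' @param baseline Abundance at `t = 0` (arbitrary units, > 0).
#' @param ... Class-specific shape parameters: `s_start`, `s_end`
#'   (histone_plateau S-phase window, defaults from the NB4 timeline);
#'   `rise_start`, `peak_fold` (mitotic_peak); `degrade_start`, `residual`
#'   (degraded classes).
#' @return A `trajectory` object; evaluate it with
#'   [trajectory_abundance()].
#' @examples
#' tr <- trajectory("bulk_exponential")
#' trajectory_abundance(tr, c(0, 1))  # doubles over one cycle
#' @export
trajectory <- function(class_label = c("bulk_exponential", "histone_plateau",
                                       "mitotic_peak", "prometaphase_degraded",
                                       "anaphase_degraded", "constant_per_cell"),
                       baseline = 1, ...) {
  class_label <- match.arg(class_label)
  if (!is.numeric(baseline) || baseline <= 0) {
    stop("`baseline` must be > 0", call. = FALSE)
  }
  dots <- list(...)
  sub <- mitotic_subphase_times()
  params <- switch(class_label,
    bulk_exponential = list(),
    histone_plateau = list(
      s_start = dots$s_start %||% 0.16,
      s_end   = dots$s_end   %||% 0.57
    ),
    mitotic_peak = list(
      rise_start = dots$rise_start %||% 0.57,
      peak_fold  = dots$peak_fold  %||% 8
    ),
    prometaphase_degraded = list(
      degrade_start = dots$degrade_start %||% sub["PM1", "start"],
      residual      = dots$residual      %||% 0.4
    ),
    anaphase_degraded = list(
      degrade_start = dots$degrade_start %||% sub["Ana", "start"],
      residual      = dots$residual      %||% 0.3
    ),
    constant_per_cell = list()
  )
  if (!is.null(params$residual) &&
      (params$residual <= 0 || params$residual > 1)) {
    stop("`residual` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(class_label = class_label, baseline = baseline,
                 shape_params = params),
            class = "trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a trajectory's per-cell abundance
#'
#' @param traj A [trajectory()] object.
#' @param t Normalized cell-cycle position(s) in `[0, 1]`.
#' @return Per-cell abundance, strictly positive.
#' @export
trajectory_abundance <- function(traj, t) {
  stopifnot(inherits(traj, "trajectory"))
  if (any(t < 0 | t > 1, na.rm = TRUE)) {
    stop("`t` must lie in [0, 1]", call. = FALSE)
  }
  b <- traj$baseline
  p <- traj$shape_params
  switch(traj$class_label,
    bulk_exponential = b * 2^t,
    constant_per_cell = rep(b, length(t)),
    histone_plateau = {
      # doubles linearly across S phase (DNA-templated synthesis), flat elsewhere
      frac <- pmin(pmax((t - p$s_start) / (p$s_end - p$s_start), 0), 1)
      b * (1 + frac)
    },
    mitotic_peak = {
      frac <- pmin(pmax((t - p$rise_start) / (1 - p$rise_start), 0), 1)
      b * p$peak_fold^frac
    },
    prometaphase_degraded = ifelse(t < p$degrade_start, b, b * p$residual),
    anaphase_degraded = ifelse(t < p$degrade_start, b, b * p$residual)
  )
}

#' Normalized time windows of the mitotic subphases
#'
#' Prophase, cyclin A+ prometaphase (PM1), cyclin A- prometaphase (PM2) and
#' anaphase are modelled as four equal, ordered sub-intervals of the M
#' window on the ergodic timeline (from the G2 boundary t(0.92) to
#' division at t = 1); no numeric within-mitosis times are published, so
#' equal spacing is the package's convention.
#'
#' @param m_start Normalized time of mitosis onset; default is the G2/M
#'   boundary of the NB4 timeline, `cumulative_to_time(0.92)`.
#' @param m_end Normalized time of division, default 1.
#' @return A matrix with rows Pro, PM1, PM2, Ana and columns `start`, `end`.
#' @export
mitotic_subphase_times <- function(m_start = cumulative_to_time(0.92),
                                   m_end = 1) {
  stopifnot(m_start < m_end)
  edges <- seq(m_start, m_end, length.out = 5)
  out <- cbind(start = edges[1:4], end = edges[2:5])
  rownames(out) <- c("Pro", "PM1", "PM2", "Ana")
  out
}

#' Mean abundance of a trajectory over the asynchronous population
#'
#' Quadrature of `a(t) f(t)` over one cycle, where `f` is the ergodic age
#' density: the expected per-cell abundance in an asynchronous culture,
#' i.e. the value the internal standard reports for this protein.
#'
#' @param traj A [trajectory()] object.
#' @return Scalar population-mean abundance.
#' @export
population_mean_abundance <- function(traj) {
  stats::integrate(function(t) trajectory_abundance(traj, t) * age_density(t),
                   0, 1, rel.tol = 1e-10, subdivisions = 500L)$value
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", x$class_label, "baseline", x$baseline, "\n")
  if (length(x$shape_params)) {
    cat("  ", paste(names(x$shape_params), unlist(x$shape_params),
                    sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
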