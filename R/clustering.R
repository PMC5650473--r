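#' Choose k by the within-groups sum-of-squares elbow
#'
#' Runs k-means across a range of k and selects the discrete inflection
#' point of the WSS curve: the k with the maximum second difference
#' `WSS(k-1) - 2 WSS(k) + WSS(k+1)` (interior k only). Identical rows give
#' WSS 0 everywhere and select k = 1.
#'
#' @param profiles Complete numeric matrix (rows to cluster).
#' @param k_range Candidate cluster counts, default `1:10`.
#' @param seed RNG seed for the restarts.
#' @param nstart Random restarts per k.
#' @return List: `k` (selected), `wss` (data frame of k and WSS).
#' @export
choose_k_wss <- function(profiles, k_range = 1:10, seed = 1L, nstart = 50L) {
  profiles <- as.matrix(profiles)
  if (anyNA(profiles)) stop("rows must be complete (no NA)", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) > nrow(profiles)) {
    stop("k_range exceeds the number of rows", call. = FALSE)
  }
  wss1 <- sum(sweep(profiles, 2, colMeans(profiles))^2)
  if (wss1 < 1e-12) {
    # all rows identical: every k fits perfectly, the scan is degenerate
    return(list(k = 1L,
                wss = data.frame(k = k_range, wss = rep(0, length(k_range)))))
  }
  wss <- vapply(k_range, function(k) {
    if (k == 1) {
      sum(sweep(profiles, 2, colMeans(profiles))^2)
    } else {
      kmeans_cluster(profiles, k, seed = seed, nstart = nstart)$tot_withinss
    }
  }, numeric(1))
  if (all(wss < 1e-12)) {
    return(list(k = 1L, wss = data.frame(k = k_range, wss = wss)))
  }
  if (length(k_range) < 3) {
    k_sel <- k_range[which.min(wss)]
  } else {
    d2 <- diff(wss, differences = 2)            # indexed by interior ks
    k_sel <- k_range[which.max(d2) + 1L]
  }
  list(k = as.integer(k_sel), wss = data.frame(k = k_range, wss = wss))
}

#' k-means clustering of abundance profiles
#'
#' Best-of-restarts k-means (Hartigan-Wong) with a deterministic seed
#' policy: rows are canonically ordered by identifier before seeding and
#' cluster labels are renumbered by centroid order, so the partition is
#' reproducible under a fixed seed and invariant to permutations of the
#' input rows. Rows with missing values must be removed beforehand.
#'
#' @param profiles Complete numeric matrix with rownames.
#' @param k Number of clusters (>= 1, <= rows).
#' @param seed RNG seed.
#' @param nstart Random restarts; the assignment with the lowest total
#'   within-groups sum of squares wins (ties broken by restart order,
#'   i.e. lowest index).
#' @return A `cluster_assignment` list: `cluster` (named index vector, in
#'   input row order), `centers` (k x p centroid matrix), `tot_withinss`,
#'   `k`, `sizes`.
#' @export
kmeans_cluster <- function(profiles, k, seed = 1L, nstart = 50L) {
  profiles <- as.matrix(profiles)
  if (anyNA(profiles)) stop("rows must be complete (no NA)", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > nrow(profiles)) stop("k exceeds the number of rows", call. = FALSE)
  ids <- rownames(profiles) %||% as.character(seq_len(nrow(profiles)))
  ord <- order(ids)
  px <- profiles[ord, , drop = FALSE]

  if (k == 1) {
    centers <- matrix(colMeans(px), 1, dimnames = list(NULL, colnames(px)))
    cl <- rep(1L, nrow(px))
    tw <- sum(sweep(px, 2, centers[1, ])^2)
  } else {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
    fit <- suppressWarnings(
      stats::kmeans(px, centers = k, nstart = nstart, iter.max = 100L))
    # canonical labels: order clusters lexicographically by centroid
    key <- do.call(order, as.data.frame(fit$centers))
    relabel <- integer(k); relabel[key] <- seq_len(k)
    cl <- relabel[fit$cluster]
    centers <- fit$centers[key, , drop = FALSE]
    rownames(centers) <- NULL
    tw <- fit$tot.withinss
  }
  names(cl) <- ids[ord]
  cl <- cl[ids]  # back to input order
  structure(list(cluster = cl, centers = centers, tot_withinss = tw,
                 k = as.integer(k), sizes = tabulate(cl, k)),
            class = "cluster_assignment")
}

get_rng_state <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  else NULL
}
restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' Agglomerate degradation clusters by trough fraction
#'
#' Focuses a k-means clustering of mitotic-subphase profiles
#' (Pro, PM1, PM2, Ana) on degradation: clusters whose mean profile does
#' not peak at prophase (i.e. increasing profiles) are removed, and the
#' remaining clusters are grouped by the *earliest* fraction at which the
#' cluster mean drops below `drop_threshold` times its prophase value.
#' Cluster means are computed on the supplied linear-ratio profiles, so
#' the grouping is independent of any transformation used for clustering.
#'
#' @param assignment A [kmeans_cluster()] result.
#' @param profiles The linear-ratio matrix the assignment refers to,
#'   columns ordered Pro, PM1, PM2, Ana.
#' A cluster counts as increasing (and is removed) when its centroid rises
#' above the prophase level by more than the reciprocal of
#' `drop_threshold`; small noise excursions above Pro in an otherwise
#' flat-then-falling centroid do not disqualify it.
#'
#' @param drop_threshold Relative level (of the Pro value) below which a
#'   fraction counts as decreased; default 0.75 (a > 25% drop). Its
#'   reciprocal is the rise tolerance for calling a cluster increasing.
#' @return Data frame: `cluster`, `trough_fraction`, `n_proteins`, plus a
#'   `"protein_groups"` attribute mapping each clustered row to its trough
#'   group.
#' @export
agglomerate_by_trough <- function(assignment, profiles,
                                  drop_threshold = 0.75) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  profiles <- as.matrix(profiles)
  fr <- colnames(profiles)
  if (fr[1] != "Pro") {
    stop("profiles must start at the Pro fraction", call. = FALSE)
  }
  cl <- assignment$cluster[rownames(profiles)]
  means <- t(vapply(seq_len(assignment$k), function(g) {
    colMeans(profiles[cl == g, , drop = FALSE])
  }, numeric(ncol(profiles))))
  colnames(means) <- fr

  rows <- lapply(seq_len(assignment$k), function(g) {
    m <- means[g, ]
    if (max(m) / m["Pro"] > 1 / drop_threshold) return(NULL)  # increasing
    dropped <- which(m / m["Pro"] < drop_threshold)
    if (!length(dropped)) return(NULL)           # never decreases: flat
    data.frame(cluster = g, trough_fraction = fr[min(dropped)],
               n_proteins = sum(cl == g))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) stop("no decreasing clusters", call. = FALSE)
  groups <- rows$trough_fraction[match(cl, rows$cluster)]
  names(groups) <- names(cl)
  attr(rows, "protein_groups") <- groups[!is.na(groups)]
  attr(rows, "cluster_means") <- means
  rows
}
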