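## From-scratch k-means++ on 1-D pixel intensities.
##
## The feature space is intensity only: MPI voxel values are clustered into
## signal tiers, and spatial structure is handled afterwards by connected
## components.  This is a deliberate re-implementation (D^2-weighted seeding
## plus Lloyd iterations with restarts) rather than a call to stats::kmeans,
## because the seeding scheme and the empty-cluster / tie-breaking contracts
## are part of the method being provided.

#' k-means++ seeding of initial centroids
#'
#' Draws `k` distinct initial centroids from the data: the first uniformly
#' at random, each subsequent one with probability proportional to the
#' squared distance to the nearest centroid already chosen (D² weighting).
#'
#' @param values Numeric vector of intensities.
#' @param k Number of centroids; must not exceed the number of distinct
#'   values.
#' @return Numeric vector of `k` distinct centroid values.  Uses the
#'   current RNG state; call `set.seed()` first for reproducibility.
#' @export
seed_centroids <- function(values, k) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("`values` must be finite")
  k <- as.integer(k)
  n_distinct <- length(unique(values))
  if (k < 1L) stop("`k` must be >= 1")
  if (k > n_distinct)
    stop(sprintf("k = %d exceeds the %d distinct values", k, n_distinct))
  centers <- numeric(k)
  centers[1] <- values[sample.int(length(values), 1L)]
  if (k > 1L) {
    d2 <- (values - centers[1])^2
    for (j in 2:k) {
      centers[j] <- values[sample.int(length(values), 1L, prob = d2)]
      d2 <- pmin(d2, (values - centers[j])^2)
    }
  }
  centers
}

## Nearest-centroid assignment; ties go to the lower cluster index.
assign_clusters <- function(values, centers) {
  d <- abs(outer(values, centers, "-"))
  max.col(-d, ties.method = "first")
}

## Local search over contiguous partitions of the sorted data.  For squared
## loss in 1-D the optimal clusters are contiguous in sorted order, so a
## partition is encoded by k-1 cut points; each is nudged one point at a
## time while the within-cluster sum of squares improves.  O(1) segment
## costs come from prefix sums.  Returns the cut vector b (length k+1,
## b[1] = 0, b[k+1] = n).
refine_cuts_1d <- function(p1, p2, b) {
  k <- length(b) - 1L
  n <- b[k + 1L]
  ss <- function(lo, hi)
    (p2[hi + 1L] - p2[lo]) - (p1[hi + 1L] - p1[lo])^2 / (hi - lo + 1L)
  if (k < 2L) return(b)
  for (pass in seq_len(4L * n)) {
    improved <- FALSE
    for (j in 2:k) {
      bl <- b[j - 1L]; br <- b[j + 1L]; cur <- b[j]
      base <- ss(bl + 1L, cur) + ss(cur + 1L, br)
      for (cand in c(cur - 1L, cur + 1L)) {
        if (cand <= bl || cand >= br) next
        alt <- ss(bl + 1L, cand) + ss(cand + 1L, br)
        if (alt < base - 1e-12 * (base + 1)) {
          b[j] <- cand
          improved <- TRUE
          break
        }
      }
    }
    if (!improved) break
  }
  b
}

#' Fit k-means++ to a vector of intensities
#'
#' Runs Lloyd iterations (assign each point to its nearest centroid,
#' recompute centroid means) from a k-means++ seeding, keeping the best of
#' `n_init` restarts by within-cluster sum of squares (WCSS).  Clusters that
#' empty during iteration are re-seeded at the point farthest from its
#' current centroid.  Because the feature space is 1-D intensity, each
#' restart is finished with a boundary-refinement pass (`refine = TRUE`):
#' optimal 1-D clusters are contiguous in sorted order, so the cut points of
#' the converged partition are locally searched until no single-point move
#' lowers the WCSS — this escapes the classic Lloyd trap where an isolated
#' bright point captures a centroid.
#'
#' @inheritParams seed_centroids
#' @param max_iter Maximum Lloyd iterations per restart.
#' @param tol Convergence tolerance on the maximum centroid shift, relative
#'   to the data range.
#' @param n_init Number of k-means++ restarts.
#' @param seed Optional integer seed set before the restarts; `NULL` uses
#'   the current RNG state.
#' @param refine Run the 1-D boundary-refinement pass after Lloyd
#'   convergence in each restart (default `TRUE`).
#' @return An object of class `mpi_kmeans` with elements `k`, `centroids`
#'   (sorted ascending, so cluster `k` is always the brightest), `labels`
#'   (1-based cluster index per value, consistent with the sorted
#'   centroids), `wcss`, `n_iter`, `converged` and `seed`.
#' @examples
#' fit_kmeans(c(1, 1, 1, 9, 9, 9), k = 2, seed = 1)
#' @export
fit_kmeans <- function(values, k = 4, max_iter = 300L, tol = 1e-6,
                       n_init = 10L, seed = NULL, refine = TRUE) {
  values <- as.numeric(values)
  if (max_iter < 1L) stop("`max_iter` must be >= 1")
  if (n_init < 1L) stop("`n_init` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  scale <- max(diff(range(values)), .Machine$double.eps)
  ord <- order(values)
  xs <- values[ord]
  p1 <- c(0, cumsum(xs))
  p2 <- c(0, cumsum(xs * xs))
  best <- NULL
  for (init in seq_len(n_init)) {
    centers <- seed_centroids(values, k)
    iter <- 0L
    converged <- FALSE
    repeat {
      iter <- iter + 1L
      lab <- assign_clusters(values, centers)
      new_centers <- centers
      for (j in seq_len(k)) {
        inj <- lab == j
        if (any(inj)) {
          new_centers[j] <- mean(values[inj])
        } else {
          # re-seed an empty cluster at the farthest point from its centroid
          new_centers[j] <- values[which.max(abs(values - centers[j]))]
        }
      }
      shift <- max(abs(new_centers - centers)) / scale
      centers <- new_centers
      if (shift < tol) { converged <- TRUE; break }
      if (iter >= max_iter) break
    }
    lab <- assign_clusters(values, centers)
    wcss <- sum((values - centers[lab])^2)
    cand <- list(centers = centers, labels = lab, wcss = wcss,
                 n_iter = iter, converged = converged)
    if (refine && k > 1L && !anyNA(match(seq_len(k), lab))) {
      # contiguous cuts implied by the converged centroids, then local search
      mids <- (sort(centers)[-k] + sort(centers)[-1]) / 2
      b <- c(0L, findInterval(mids, xs), length(xs))
      if (all(diff(b) >= 1L)) {
        b <- refine_cuts_1d(p1, p2, b)
        sizes <- diff(b)
        means <- (p1[b[-1] + 1L] - p1[b[-length(b)] + 1L]) / sizes
        lab_sorted <- rep(seq_len(k), sizes)
        rlab <- integer(length(values))
        rlab[ord] <- lab_sorted
        rwcss <- sum((xs - rep(means, sizes))^2)
        if (rwcss < cand$wcss)
          cand <- list(centers = means, labels = rlab, wcss = rwcss,
                       n_iter = iter, converged = converged)
      }
    }
    if (is.null(best) || cand$wcss < best$wcss) best <- cand
  }
  cord <- order(best$centers)
  centroids <- best$centers[cord]
  labels <- match(best$labels, cord)
  structure(list(k = as.integer(k), centroids = centroids, labels = labels,
                 wcss = best$wcss, n_iter = best$n_iter,
                 converged = best$converged, seed = seed),
            class = "mpi_kmeans")
}

#' @export
print.mpi_kmeans <- function(x, ...) {
  cat(sprintf("k-means++ fit: k = %d, wcss = %.6g, %d iteration(s)%s\n",
              x$k, x$wcss, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  cat("centroids:", format(x$centroids, digits = 6), "\n")
  invisible(x)
}

#' Select the number of clusters by the elbow method
#'
#' Fits k-means for each `k` in `k_min:k_max` and returns the `k` with the
#' greatest curvature of the WCSS-vs-k curve, measured by the second
#' difference of `log(wcss)` (defined for interior `k` only, so the range
#' must span at least three values).  The log scale makes the criterion
#' scale-invariant and sensitive to *relative* drops: for data in `G`
#' well-separated intensity tiers the WCSS falls by orders of magnitude up
#' to `k = G` and only marginally beyond, so the curvature peaks at `G`
#' (a raw second difference would instead always favor the huge absolute
#' drop at small `k`).  Ties go to the smaller `k`.
#'
#' @inheritParams fit_kmeans
#' @param k_min,k_max Range of cluster counts to evaluate.
#' @return An object of class `mpi_elbow`: `k` (the selection), `k_grid`,
#'   `wcss` and `curvature` (second differences, `NA` at the endpoints).
#' @export
elbow_select_k <- function(values, k_min = 1L, k_max = 8L, n_init = 5L,
                           seed = NULL, max_iter = 300L, tol = 1e-6) {
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (k_min < 1L || k_max <= k_min) stop("need 1 <= k_min < k_max")
  if (k_max - k_min < 2L)
    stop("elbow selection needs a k range of width >= 3 (second difference)")
  n_distinct <- length(unique(values))
  if (k_max > n_distinct)
    stop(sprintf("k_max = %d exceeds the %d distinct values", k_max, n_distinct))
  if (!is.null(seed)) set.seed(seed)
  ks <- k_min:k_max
  wcss <- vapply(ks, function(k)
    fit_kmeans(values, k, max_iter = max_iter, tol = tol, n_init = n_init)$wcss,
    numeric(1))
  # guard exactly-separable fits (wcss 0) before taking logs
  lw <- log(pmax(wcss, max(wcss[1], .Machine$double.eps) * 1e-12))
  curv <- rep(NA_real_, length(ks))
  inner <- 2:(length(ks) - 1L)
  curv[inner] <- lw[inner - 1L] - 2 * lw[inner] + lw[inner + 1L]
  k_sel <- ks[inner][which.max(curv[inner])]
  structure(list(k = k_sel, k_grid = ks, wcss = wcss, curvature = curv),
            class = "mpi_elbow")
}

#' @export
print.mpi_elbow <- function(x, ...) {
  cat(sprintf("elbow selection: k = %d over range %d..%d\n",
              x$k, min(x$k_grid), max(x$k_grid)))
  print(data.frame(k = x$k_grid, wcss = x$wcss, curvature = x$curvature),
        row.names = FALSE)
  invisible(x)
}
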