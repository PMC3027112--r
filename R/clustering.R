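# Clustering in curve-feature space
#
# Probes are clustered on their standardized feature vectors with k-means
# (Lloyd iterations, k-means++ seeding, multiple restarts) or PAM
# (partitioning around medoids: BUILD then SWAP), under Euclidean or
# Manhattan distance.  Quality is judged by per-probe silhouettes,
# homogeneity (mean distance to the cluster representative; lower is
# tighter) and separation (size-weighted mean distance between
# representatives; higher is better).  The number of clusters is chosen
# by scanning k and taking the highest average silhouette.

#' Standardize a feature matrix
#'
#' Centers every feature column to mean 0 and scales it to unit standard
#' deviation, so that features with different units (times, log2 levels,
#' slopes) contribute comparably to distances.  Zero-variance columns are
#' dropped with a warning.
#'
#' @param fm a `feature_matrix` (or plain numeric matrix) on the raw scale.
#' @return A `feature_matrix` with `scaling = "standardized"`.
#' @export
standardize_features <- function(fm) {
  if (nrow(fm) < 2L) stop("standardization needs at least 2 probes",
                          call. = FALSE)
  sds <- apply(fm, 2L, stats::sd)
  drop <- sds == 0
  if (all(drop)) stop("all feature columns have zero variance", call. = FALSE)
  if (any(drop))
    warning("dropping zero-variance feature column(s): ",
            paste(colnames(fm)[drop], collapse = ", "), call. = FALSE)
  kept <- fm[, !drop, drop = FALSE]
  out <- scale(kept)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  structure(out, class = c("feature_matrix", "matrix", "array"),
            scaling = "standardized", excluded = attr(fm, "excluded"))
}

#' Distance between two feature vectors
#' @param x,y numeric vectors of equal length.
#' @param metric `"euclidean"` or `"manhattan"`.
#' @return The L2 or L1 distance.
#' @export
feature_dist <- function(x, y, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  if (length(x) != length(y))
    stop("feature vectors must have equal dimension", call. = FALSE)
  if (metric == "euclidean") sqrt(sum((x - y)^2)) else sum(abs(x - y))
}

# rows-to-centers distance matrix (n x k)
dist_to_centers <- function(x, centers, metric) {
  k <- nrow(centers)
  out <- matrix(0, nrow(x), k)
  for (j in seq_len(k)) {
    dif <- sweep(x, 2L, centers[j, ], "-")
    out[, j] <- if (metric == "euclidean") sqrt(rowSums(dif^2))
                else rowSums(abs(dif))
  }
  out
}

kmeanspp_init <- function(x, k, metric) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- dist_to_centers(x, x[centers[1L], , drop = FALSE], metric)[, 1L]
  if (metric == "euclidean") d2 <- d2^2
  for (j in seq_len(k - 1L)) {
    if (sum(d2) <= 0) {
      # remaining points coincide with chosen centers; pick first unused
      centers[j + 1L] <- setdiff(seq_len(n), centers[seq_len(j)])[1L]
    } else {
      centers[j + 1L] <- sample.int(n, 1L, prob = d2)
    }
    dn <- dist_to_centers(x, x[centers[j + 1L], , drop = FALSE], metric)[, 1L]
    if (metric == "euclidean") dn <- dn^2
    d2 <- pmin(d2, dn)
  }
  x[centers, , drop = FALSE]
}

kmeans_objective <- function(x, centers, assign, metric) {
  d <- dist_to_centers(x, centers, metric)
  dd <- d[cbind(seq_len(nrow(x)), assign)]
  if (metric == "euclidean") sum(dd^2) else sum(dd)
}

lloyd_run <- function(x, k, metric, max_iter) {
  centers <- kmeanspp_init(x, k, metric)
  assign <- rep(0L, nrow(x))
  for (it in seq_len(max_iter)) {
    d <- dist_to_centers(x, centers, metric)
    new_assign <- max.col(-d, ties.method = "first")
    # repair empty clusters with the point farthest from its centroid
    for (j in which(tabulate(new_assign, k) == 0L)) {
      cur <- d[cbind(seq_len(nrow(x)), new_assign)]
      far <- which.max(cur)
      new_assign[far] <- j
      d[far, ] <- Inf   # pin: do not move it again this pass
    }
    if (identical(new_assign, assign)) break
    assign <- new_assign
    for (j in seq_len(k))
      centers[j, ] <- colMeans(x[assign == j, , drop = FALSE])
  }
  list(assignments = assign, centers = centers,
       objective = kmeans_objective(x, centers, assign, metric))
}

#' K-means clustering of a feature matrix
#'
#' Lloyd iterations from k-means++ seeding, repeated `n_init` times with
#' the best run kept (lowest within-cluster sum of squared Euclidean
#' distances, or of Manhattan distances under that metric).  Centroids are
#' arithmetic means under both metrics; the metric governs assignment and
#' evaluation.  Deterministic for a given `seed`.
#'
#' @param fm standardized `feature_matrix` (see [standardize_features()]).
#' @param k number of clusters, `1 <= k <= n`.
#' @param metric `"euclidean"` or `"manhattan"`.
#' @param seed RNG seed (default 1).
#' @param n_init number of restarts (default 10).
#' @param max_iter Lloyd iteration cap per restart (default 100).
#' @return List: `assignments` (named by probe), `centers`, `objective`,
#'   `algorithm`, `metric`, `k`.
#' @export
st_kmeans <- function(fm, k, metric = c("euclidean", "manhattan"),
                      seed = 1L, n_init = 10L, max_iter = 100L) {
  metric <- match.arg(metric)
  x <- unclass(fm)
  if (k < 1L || k > nrow(x))
    stop("k must lie between 1 and the number of probes", call. = FALSE)
  best <- with_seed(seed, {
    runs <- lapply(seq_len(n_init), function(i) lloyd_run(x, k, metric,
                                                          max_iter))
    runs[[which.min(vapply(runs, `[[`, 0, "objective"))]]
  })
  names(best$assignments) <- rownames(x)
  c(best, list(algorithm = "kmeans", metric = metric, k = k))
}

pam_assign <- function(dmat, medoids) {
  d <- dmat[, medoids, drop = FALSE]
  max.col(-d, ties.method = "first")
}

pam_objective <- function(dmat, medoids) {
  best <- dmat[, medoids[1L]]
  for (j in medoids[-1L]) best <- pmin(best, dmat[, j])
  sum(best)
}

pam_build <- function(dmat, k) {
  n <- nrow(dmat)
  medoids <- which.min(colSums(dmat))
  nearest <- dmat[, medoids]
  while (length(medoids) < k) {
    cand <- setdiff(seq_len(n), medoids)
    totals <- vapply(cand, function(j) sum(pmin(nearest, dmat[, j])), 0)
    pick <- cand[which.min(totals)]
    medoids <- c(medoids, pick)
    nearest <- pmin(nearest, dmat[, pick])
  }
  medoids
}

# best-improvement SWAP refinement; the objective never increases
pam_swap <- function(dmat, medoids) {
  n <- nrow(dmat)
  obj <- pam_objective(dmat, medoids)
  repeat {
    best_gain <- 0; best_swap <- NULL
    non_med <- setdiff(seq_len(n), medoids)
    for (mi in seq_along(medoids)) {
      rest <- medoids[-mi]
      rest_min <- if (length(rest)) {
        rm_ <- dmat[, rest[1L]]
        for (j in rest[-1L]) rm_ <- pmin(rm_, dmat[, j])
        rm_
      } else rep(Inf, n)
      for (h in non_med) {
        gain <- obj - sum(pmin(rest_min, dmat[, h]))
        if (gain > best_gain + 1e-12) {
          best_gain <- gain; best_swap <- c(mi, h)
        }
      }
    }
    if (is.null(best_swap)) break
    medoids[best_swap[1L]] <- best_swap[2L]
    obj <- obj - best_gain
  }
  list(medoids = medoids, objective = obj)
}

#' PAM (k-medoids) clustering of a feature matrix
#'
#' Partitioning around medoids: BUILD greedily seeds k medoids (first the
#' point with the least total distance to all others, then the point
#' giving the largest drop in total distance) and SWAP repeatedly applies
#' the best strictly improving medoid/non-medoid exchange until none
#' exists.  Because best-improvement SWAP can terminate in a local
#' optimum, the refinement is additionally restarted from `n_init - 1`
#' random medoid sets (seeded, hence deterministic) and the best solution
#' is kept.  The objective is the sum of distances of every probe to its
#' medoid under the chosen metric; remaining ties are broken by the
#' lowest probe index.
#'
#' @param fm standardized `feature_matrix`.
#' @param k number of clusters, `1 <= k <= n`.
#' @param metric `"euclidean"` or `"manhattan"`.
#' @param seed RNG seed for the random restarts (default 1).
#' @param n_init total number of starts including the BUILD start
#'   (default 10).
#' @return List: `assignments` (named by probe), `medoids` (row indices),
#'   `medoid_ids`, `objective`, `algorithm`, `metric`, `k`.
#' @export
st_pam <- function(fm, k, metric = c("euclidean", "manhattan"),
                   seed = 1L, n_init = 10L) {
  metric <- match.arg(metric)
  x <- unclass(fm)
  n <- nrow(x)
  if (k < 1L || k > n)
    stop("k must lie between 1 and the number of probes", call. = FALSE)
  dmat <- as.matrix(stats::dist(x, method = metric))

  best <- pam_swap(dmat, pam_build(dmat, k))
  if (n_init > 1L && k < n) {
    best <- with_seed(seed, {
      for (i in seq_len(n_init - 1L)) {
        cand <- pam_swap(dmat, sample.int(n, k))
        if (cand$objective < best$objective - 1e-12) best <- cand
      }
      best
    })
  }
  medoids <- as.integer(sort(unname(best$medoids)))
  assign <- pam_assign(dmat, medoids)
  names(assign) <- rownames(x)
  list(assignments = assign, medoids = medoids,
       medoid_ids = rownames(x)[medoids],
       objective = pam_objective(dmat, medoids),
       algorithm = "pam", metric = metric, k = k)
}

#' Per-probe silhouette widths
#'
#' For each probe, `a` is the mean distance to the other members of its
#' cluster, `b` the smallest mean distance to any other cluster, and
#' `s = (b - a) / max(a, b)`.  Members of singleton clusters get `s = 0`
#' (Rousseeuw's convention).  The nearest neighbouring cluster is the one
#' attaining `b`.
#'
#' @param fm standardized `feature_matrix` (or a precomputed distance
#'   matrix via `dmat`).
#' @param assignments integer cluster labels per probe.
#' @param metric `"euclidean"` or `"manhattan"`.
#' @param dmat optional precomputed full distance matrix.
#' @return Data frame (`id`, `cluster`, `neighbor`, `sil_width`) with the
#'   average silhouette in attribute `"avg_silhouette"`.
#' @export
silhouette_widths <- function(fm, assignments,
                              metric = c("euclidean", "manhattan"),
                              dmat = NULL) {
  metric <- match.arg(metric)
  if (is.null(dmat)) dmat <- as.matrix(stats::dist(unclass(fm),
                                                   method = metric))
  n <- nrow(dmat)
  stopifnot(length(assignments) == n)
  ks <- sort(unique(assignments))
  if (length(ks) < 2L)
    stop("silhouettes need at least 2 clusters", call. = FALSE)
  sizes <- table(factor(assignments, levels = ks))
  # mean distance from each point to each cluster (including own)
  cl_mean <- vapply(ks, function(kk) {
    rowSums(dmat[, assignments == kk, drop = FALSE]) / sizes[[as.character(kk)]]
  }, numeric(n))
  s <- numeric(n); neighbor <- integer(n)
  for (i in seq_len(n)) {
    own <- match(assignments[i], ks)
    n_own <- sizes[[own]]
    others <- setdiff(seq_along(ks), own)
    jmin <- others[which.min(cl_mean[i, others])]
    neighbor[i] <- ks[jmin]
    b <- cl_mean[i, jmin]
    if (n_own == 1L) { s[i] <- 0; next }
    a <- cl_mean[i, own] * n_own / (n_own - 1L)   # exclude self (d(i,i)=0)
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  out <- data.frame(id = rownames(dmat) %||% seq_len(n),
                    cluster = assignments, neighbor = neighbor,
                    sil_width = s)
  attr(out, "avg_silhouette") <- mean(s)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cluster_representatives <- function(fm, fit) {
  if (fit$algorithm == "kmeans") fit$centers
  else unclass(fm)[fit$medoids, , drop = FALSE]
}

#' Cluster homogeneity
#'
#' Mean distance of probes to their own cluster representative (the
#' centroid for k-means, the medoid for PAM).  Lower values mean tighter
#' clusters.
#'
#' @param fm the standardized `feature_matrix` that was clustered.
#' @param fit a fit from [st_kmeans()] or [st_pam()].
#' @return A non-negative number.
#' @export
cluster_homogeneity <- function(fm, fit) {
  reps <- cluster_representatives(fm, fit)
  d <- dist_to_centers(unclass(fm), reps, fit$metric)
  mean(d[cbind(seq_len(nrow(fm)), fit$assignments)])
}

#' Cluster separation
#'
#' Size-weighted mean pairwise distance between cluster representatives:
#' `sum_{i<j} n_i n_j d(c_i, c_j) / sum_{i<j} n_i n_j`.  Higher values
#' mean better-separated clusters.  Requires at least 2 clusters.
#'
#' @inheritParams cluster_homogeneity
#' @return A non-negative number.
#' @export
cluster_separation <- function(fm, fit) {
  reps <- cluster_representatives(fm, fit)
  k <- nrow(reps)
  if (k < 2L) stop("separation needs at least 2 clusters", call. = FALSE)
  sizes <- tabulate(fit$assignments, k)
  num <- 0; den <- 0
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    w <- sizes[i] * sizes[j]
    num <- num + w * feature_dist(reps[i, ], reps[j, ], fit$metric)
    den <- den + w
  }
  num / den
}

#' Cluster a feature matrix and evaluate the result
#'
#' Convenience wrapper running [st_kmeans()] or [st_pam()] and attaching
#' silhouettes, homogeneity, separation and cluster sizes.
#'
#' @param fm standardized `feature_matrix`.
#' @param algorithm `"pam"` or `"kmeans"`.
#' @param metric `"euclidean"` or `"manhattan"`.
#' @param k number of clusters.
#' @param seed RNG seed (k-means only).
#' @param ... further arguments to the algorithm.
#' @return An object of class `st_clustering`.
#' @export
st_cluster <- function(fm, algorithm = c("pam", "kmeans"),
                       metric = c("euclidean", "manhattan"), k,
                       seed = 1L, ...) {
  algorithm <- match.arg(algorithm)
  metric <- match.arg(metric)
  fit <- if (algorithm == "pam") st_pam(fm, k, metric, seed = seed, ...)
         else st_kmeans(fm, k, metric, seed = seed, ...)
  sil <- if (k >= 2L) silhouette_widths(fm, fit$assignments, metric) else NULL
  structure(c(fit, list(
    silhouette = sil,
    avg_silhouette = if (!is.null(sil)) attr(sil, "avg_silhouette")
                     else NA_real_,
    homogeneity = cluster_homogeneity(fm, fit),
    separation = if (k >= 2L) cluster_separation(fm, fit) else NA_real_,
    sizes = tabulate(fit$assignments, k), seed = seed)),
    class = "st_clustering")
}

#' @export
print.st_clustering <- function(x, ...) {
  cat(sprintf(
    "st_clustering: %s/%s, k = %d, sizes [%s]\n  objective %.4g, avg silhouette %.3f, homogeneity %.3f, separation %.3f\n",
    x$algorithm, x$metric, x$k, paste(x$sizes, collapse = ", "),
    x$objective, x$avg_silhouette, x$homogeneity, x$separation))
  invisible(x)
}

#' Choose the number of clusters by average silhouette
#'
#' Clusters the data for every k in `k_range` (same seed policy for each)
#' and returns the k with the highest average silhouette; ties go to the
#' smallest k.
#'
#' @param fm standardized `feature_matrix`.
#' @param k_range candidate cluster counts, each within `[2, n - 1]`.
#' @param algorithm,metric,seed,... passed to [st_cluster()].
#' @return List: `best_k`, `avg_silhouettes` (named by k), `results`
#'   (per-k `st_clustering` objects).
#' @export
choose_k <- function(fm, k_range = 2:6, algorithm = c("pam", "kmeans"),
                     metric = c("euclidean", "manhattan"), seed = 1L, ...) {
  if (length(k_range) < 1L) stop("k_range is empty", call. = FALSE)
  n <- nrow(fm)
  if (any(k_range < 2L | k_range > n - 1L))
    stop("every k must lie in [2, n - 1] for silhouettes to be defined",
         call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  results <- lapply(k_range, function(k)
    st_cluster(fm, algorithm, metric, k = k, seed = seed, ...))
  sils <- vapply(results, `[[`, 0, "avg_silhouette")
  names(sils) <- k_range
  names(results) <- k_range
  list(best_k = k_range[which.max(sils)], avg_silhouettes = sils,
       results = results)
}
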