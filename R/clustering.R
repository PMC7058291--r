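#' Principal component analysis of the trait matrix
#'
#' Exact SVD-based PCA (via [stats::prcomp()]) on the centered trait matrix.
#' Loading columns follow the sign convention that their largest-magnitude
#' entry is positive; scores are flipped consistently, so
#' `scores %*% t(loadings)` still reconstructs the centered input exactly at
#' full rank.
#'
#' @param cohort a `cohort_table` (normalized and pruned) or numeric matrix.
#' @return An object of class `pca_model`: `loadings` (traits x components,
#'   orthonormal), `scores` (subjects x components), `explained_variance`
#'   (fractions, non-increasing), `center`.
#' @export
run_pca <- function(cohort) {
  X <- if (inherits(cohort, "cohort_table")) trait_matrix(cohort) else as.matrix(cohort)
  if (anyNA(X)) stop("NaN/NA in input to PCA; impute first", call. = FALSE)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  structure(list(loadings = pc$rotation, scores = pc$x,
                 explained_variance = pc$sdev^2 / sum(pc$sdev^2),
                 center = pc$center),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              ncol(x$loadings), 100 * x$explained_variance[1],
              100 * (x$explained_variance[2] %||% NA)))
  invisible(x)
}

#' Fit k-means clusters
#'
#' Lloyd's algorithm with Euclidean distance and uniform-random initial
#' centers (rows of the data), `nstart` restarts keeping the lowest inertia,
#' at most 300 iterations. If an initialization collapses to an empty cluster
#' the fit is retried with a derived seed (up to 20 times).
#'
#' @param cohort a `cohort_table` or numeric matrix.
#' @param k number of clusters (2 <= k <= n).
#' @param seed integer seed; fixed seed gives identical assignments.
#' @param nstart number of random restarts.
#' @param compute_silhouette also compute the mean silhouette width
#'   (subsampled, see [mean_silhouette()]).
#' @return An object of class `cluster_model`: `k`, `centers`, `assignment`
#'   (labels 1..k), `inertia` (total within-cluster sum of squares),
#'   `silhouette_mean`, `seed`.
#' @export
kmeans_fit <- function(cohort, k, seed = 1L, nstart = 10L,
                       compute_silhouette = FALSE) {
  X <- if (inherits(cohort, "cohort_table")) trait_matrix(cohort) else as.matrix(cohort)
  n <- nrow(X)
  if (k < 1 || k > n) stop("k must lie in [1, n]", call. = FALSE)
  fit <- NULL
  for (try in 0:20) {
    fit <- try(withCallingHandlers(
      with_seed_(child_seed(seed, try),
                 kmeans(X, centers = k, iter.max = 300L,
                        nstart = nstart, algorithm = "Lloyd")),
      warning = function(w) {
        # an empty-cluster restart is handled by the retry loop, not the user
        if (grepl("empty cluster", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }), silent = TRUE)
    if (!inherits(fit, "try-error")) break
  }
  if (inherits(fit, "try-error"))
    stop("k-means failed to produce k non-empty clusters", call. = FALSE)
  sil <- if (compute_silhouette && k >= 2 && k < n)
    mean_silhouette(X, fit$cluster, seed = seed) else NA_real_
  structure(list(k = as.integer(k), centers = fit$centers,
                 assignment = unname(fit$cluster), inertia = fit$tot.withinss,
                 silhouette_mean = sil, seed = as.integer(seed)),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k=%d, inertia %.4g, sizes %s\n", x$k,
              x$inertia, paste(tabulate(x$assignment, x$k), collapse = "/")))
  invisible(x)
}

#' Mean silhouette width of a partition
#'
#' Silhouette s(i) = (b(i) - a(i)) / max(a(i), b(i)) averaged over subjects,
#' computed with [cluster::silhouette()]. For cohorts larger than
#' `max_points` the O(n^2) distance matrix is computed on a random subsample
#' of that size (points in singleton-in-subsample clusters are dropped by the
#' silhouette definition).
#'
#' @param X numeric matrix (subjects x traits).
#' @param labels integer cluster labels.
#' @param max_points subsample cap for the distance matrix (default 5000).
#' @param seed integer seed for the subsample.
#' @return mean silhouette width in [-1, 1].
#' @export
mean_silhouette <- function(X, labels, max_points = 5000L, seed = 1L) {
  n <- nrow(X)
  idx <- if (n > max_points)
    with_seed_(child_seed(seed, 97L), sample.int(n, max_points)) else seq_len(n)
  lab <- labels[idx]
  if (length(unique(lab)) < 2L) return(NA_real_)
  sil <- cluster::silhouette(lab, dist(X[idx, , drop = FALSE]))
  mean(sil[, "sil_width"])
}

#' Select the number of clusters by the average-silhouette method
#'
#' Fits k-means for every k in `k_range` and returns the k maximizing the
#' mean silhouette width (shared subsample across k). Ties return the
#' smallest k.
#'
#' @param cohort a `cohort_table` or matrix.
#' @param k_range candidate k values (within [2, n-1]).
#' @param seed integer seed.
#' @param nstart restarts per k.
#' @param max_points silhouette subsample cap.
#' @return list(k_best, silhouette): the selected k and the named per-k mean
#'   silhouette vector.
#' @export
select_k_silhouette <- function(cohort, k_range = 2:6, seed = 1L,
                                nstart = 10L, max_points = 5000L) {
  X <- if (inherits(cohort, "cohort_table")) trait_matrix(cohort) else as.matrix(cohort)
  n <- nrow(X)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("k_range must intersect [2, n-1]", call. = FALSE)
  idx <- if (n > max_points)
    with_seed_(child_seed(seed, 97L), sample.int(n, max_points)) else seq_len(n)
  D <- dist(X[idx, , drop = FALSE])
  sil <- vapply(k_range, function(k) {
    fit <- kmeans_fit(X, k, seed = child_seed(seed, k))
    lab <- fit$assignment[idx]
    if (length(unique(lab)) < 2L) return(NA_real_)
    mean(cluster::silhouette(lab, D)[, "sil_width"])
  }, numeric(1))
  names(sil) <- as.character(k_range)
  list(k_best = k_range[which.max(sil)], silhouette = sil)
}

#' Jaccard matching of two partitions
#'
#' Computes the k_ref x k_new matrix of Jaccard indices
#' J(A,B) = |A n B| / |A u B| between cluster member sets and matches
#' clusters greedily, largest Jaccard first (each reference and each new
#' cluster used at most once).
#'
#' @param ref_labels,new_labels integer label vectors over the same subjects.
#' @return named numeric vector: for each reference cluster, the Jaccard
#'   index of its greedy match.
#' @export
jaccard_match <- function(ref_labels, new_labels) {
  stopifnot(length(ref_labels) == length(new_labels))
  ref_ids <- sort(unique(ref_labels))
  new_ids <- sort(unique(new_labels))
  J <- matrix(0, length(ref_ids), length(new_ids),
              dimnames = list(ref_ids, new_ids))
  for (i in seq_along(ref_ids)) {
    A <- ref_labels == ref_ids[i]
    for (j in seq_along(new_ids)) {
      B <- new_labels == new_ids[j]
      J[i, j] <- sum(A & B) / sum(A | B)
    }
  }
  out <- setNames(rep(0, length(ref_ids)), ref_ids)
  M <- J
  for (step in seq_len(min(dim(J)))) {
    best <- which(M == max(M), arr.ind = TRUE)[1, , drop = TRUE]
    out[rownames(M)[best[1]]] <- M[best[1], best[2]]
    M <- M[-best[1], -best[2], drop = FALSE]
    if (!length(M)) break
  }
  out
}

#' Cluster stability by repeated k-means and the mean Jaccard index
#'
#' Re-runs the k-means procedure `n_repeats` times from different random
#' centers and matches each repeat's clusters to the reference partition by
#' greedy maximum Jaccard. Each repeat is a full fit with `nstart` restarts,
#' so the index measures the stability of the partition in the data rather
#' than single-start optimizer noise (set `nstart = 1` for the latter). Reports the per-reference-cluster mean Jaccard
#' over repeats, their mean (`overall_mean`), and the pooled mean over all
#' (cluster, repeat) pairs.
#'
#' @param cohort a `cohort_table` or matrix.
#' @param k number of clusters.
#' @param n_repeats number of re-clustering repeats (the reference analysis
#'   used 1000; scale down for quick checks).
#' @param seed integer seed.
#' @param reference optional `cluster_model` to use as the reference
#'   partition; fitted fresh when omitted.
#' @param nstart random restarts per repeat (default 10).
#' @return An object of class `stability_report`: `n_repeats`,
#'   `mean_jaccard` (per reference cluster), `overall_mean`, `pooled_mean`.
#' @export
assess_stability_jaccard <- function(cohort, k, n_repeats = 100L, seed = 1L,
                                     reference = NULL, nstart = 10L) {
  X <- if (inherits(cohort, "cohort_table")) trait_matrix(cohort) else as.matrix(cohort)
  reference <- reference %||% kmeans_fit(X, k, seed = seed)
  ref <- reference$assignment
  per_rep <- matrix(NA_real_, n_repeats, k)
  for (r in seq_len(n_repeats)) {
    fit <- kmeans_fit(X, k, seed = child_seed(seed, 1000L + r), nstart = nstart)
    per_rep[r, ] <- jaccard_match(ref, fit$assignment)
  }
  mj <- colMeans(per_rep)
  structure(list(n_repeats = as.integer(n_repeats),
                 mean_jaccard = setNames(mj, seq_len(k)),
                 overall_mean = mean(mj), pooled_mean = mean(per_rep)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d repeats; per-cluster mean Jaccard %s; overall %.3f\n",
              x$n_repeats, paste(sprintf("%.3f", x$mean_jaccard), collapse = "/"),
              x$overall_mean))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Permutation-model-corrected agreement between two labelings; 1 for
#' identical partitions, ~0 for independent ones.
#'
#' @param a,b integer label vectors over the same subjects.
#' @return scalar adjusted Rand index.
#' @export
ari <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxidx <- (si + sj) / 2
  if (maxidx == expected) return(1)
  (sij - expected) / (maxidx - expected)
}

#' Format a prevalence percentage from counts
#'
#' @param n_cases,n_total case and group counts.
#' @param digits decimal places (default 1, matching cohort summary tables).
#' @return numeric percentage rounded to `digits`.
#' @export
prevalence_pct <- function(n_cases, n_total, digits = 1) {
  round(100 * n_cases / n_total, digits)
}

#' Characterize clusters in original units
#'
#' Per cluster: size, mean (SD) of every trait in original units, and for
#' each disease the case count and prevalence percentage (one decimal).
#' Optionally a within-cluster diseased-vs-control comparison (any disease
#' vs none) of every quantitative trait by Welch's two-sided two-sample
#' t-test.
#'
#' @param cohort a `cohort_table` in original units (pre-normalization) with
#'   disease flags.
#' @param assignment integer cluster labels aligned with `cohort` rows (or a
#'   `cluster_model`).
#' @param compare_within compute the diseased-vs-control comparison.
#' @return list(summary, prevalence, comparison): `summary` is a trait x
#'   cluster character table of "mean (SD)" entries; `prevalence` a
#'   data.frame of per-cluster disease counts/percentages; `comparison`
#'   (optional) a per-cluster list of Welch test results (NULL columns where
#'   a cluster has no diseased subjects).
#' @export
summarize_clusters <- function(cohort, assignment, compare_within = FALSE) {
  if (inherits(assignment, "cluster_model")) assignment <- assignment$assignment
  stopifnot(length(assignment) == nrow(cohort))
  traits <- cohort_traits(cohort)
  diseases <- cohort_diseases(cohort)
  if (!length(diseases)) stop("cohort has no disease flags", call. = FALSE)
  ks <- sort(unique(assignment))
  summary_tab <- matrix("", length(traits), length(ks),
                        dimnames = list(traits, paste0("cluster", ks)))
  prev <- NULL
  for (j in seq_along(ks)) {
    idx <- assignment == ks[j]
    for (tr in traits)
      summary_tab[tr, j] <- sprintf("%.3g (%.3g)",
                                    mean(cohort[[tr]][idx], na.rm = TRUE),
                                    sd(cohort[[tr]][idx], na.rm = TRUE))
    for (dz in diseases) {
      cases <- sum(cohort[[dz]][idx], na.rm = TRUE)
      prev <- rbind(prev, data.frame(
        cluster = ks[j], disease = dz, n = sum(idx), n_cases = cases,
        prevalence_pct = prevalence_pct(cases, sum(idx)),
        stringsAsFactors = FALSE))
    }
  }
  out <- list(summary = summary_tab, prevalence = prev)
  if (compare_within) {
    any_disease <- Reduce(`|`, lapply(diseases, function(d) cohort[[d]]))
    out$comparison <- lapply(setNames(ks, paste0("cluster", ks)), function(k) {
      idx <- assignment == k
      dz <- any_disease[idx]
      if (!any(dz) || all(dz)) return(NULL)
      do.call(rbind, lapply(traits, function(tr) {
        x <- cohort[[tr]][idx]
        tt <- try(t.test(x[dz], x[!dz]), silent = TRUE)
        data.frame(trait = tr,
                   mean_control = mean(x[!dz], na.rm = TRUE),
                   mean_diseased = mean(x[dz], na.rm = TRUE),
                   p = if (inherits(tt, "try-error")) NA_real_ else tt$p.value,
                   stringsAsFactors = FALSE)
      }))
    })
  }
  out
}

#' Identify the low-disease-prevalence cluster
#'
#' The cluster minimizing the mean prevalence across all diseases; cluster
#' numbering from k-means is arbitrary, so the healthy stratum is found
#' programmatically.
#'
#' @param prevalence the `prevalence` data.frame from [summarize_clusters()].
#' @return the cluster label with minimal mean disease prevalence.
#' @export
find_low_prevalence_cluster <- function(prevalence) {
  m <- aggregate(prevalence_pct ~ cluster, data = prevalence, FUN = mean)
  m$cluster[which.min(m$prevalence_pct)]
}
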