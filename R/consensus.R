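#' Repeated NMF runs at a fixed rank
#'
#' Runs [run_nmf_once()] `n_runs` times with independent initialisations
#' (and, by default, independent Poisson-bootstrap perturbations of the
#' catalogue), collecting the per-run signature and exposure matrices for
#' consensus partitioning.
#'
#' @param cat A [mut_catalogue()].
#' @param k Rank.
#' @param n_runs Number of repetitions (the reference protocol uses 30; small
#'   values keep toy analyses fast).
#' @param resample Poisson-bootstrap each repetition's input?
#' @param seed Integer seed; run `r` uses `seed + r`.
#' @param ... Passed to [run_nmf_once()].
#' @return An `nmf_run_set`: list with `k`, `runs` (list of run results) and
#'   `n_runs`.
#' @export
repeat_nmf <- function(cat, k, n_runs = 30L, resample = TRUE, seed = 1L, ...) {
  stopifnot(n_runs >= 2L)
  runs <- lapply(seq_len(n_runs), function(r) {
    run_nmf_once(cat, k, resample = resample, seed = seed + r, ...)
  })
  structure(list(k = as.integer(k), runs = runs, n_runs = as.integer(n_runs)),
            class = "nmf_run_set")
}

cosine_cross <- function(A, B) {
  # rows of A vs rows of B
  An <- A / sqrt(rowSums(A^2))
  Bn <- B / sqrt(rowSums(B^2))
  tcrossprod(An, Bn)
}

#' Silhouette coefficients under cosine distance
#'
#' For each point, `c = (b - a) / max(a, b)` where `a` is the mean
#' distance to the other members of its own cluster and `b` the smallest
#' mean distance to another cluster. Singleton clusters, single-cluster
#' partitions, and points at zero distance from both their own and nearest
#' cluster score 0 (the standard convention).
#'
#' @param D Symmetric distance matrix.
#' @param labels Integer cluster labels.
#' @return Numeric vector of silhouette coefficients in `[-1, 1]`.
#' @export
silhouette_cosine <- function(D, labels) {
  n <- length(labels)
  stopifnot(nrow(D) == n, ncol(D) == n)
  ulab <- sort(unique(labels))
  if (length(ulab) < 2L) return(rep(0, n))
  vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1L) return(0)
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(ulab, labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1L)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1L))
}

#' Consensus partition of repeated NMF runs
#'
#' Matches the k signatures of every run to k clusters by minimum-cost
#' bipartite (Hungarian) assignment under cosine distance, iterating
#' assignment and centroid recomputation until the partition stabilises.
#' Cluster stability is scored by silhouette coefficients under cosine
#' distance: `C_k` per cluster, their mean `C_mean` and minimum `C_min`.
#' Because every cluster receives exactly one signature per run, the mean
#' over all run-signatures equals the mean of the per-cluster means.
#'
#' @param runs An `nmf_run_set` from [repeat_nmf()].
#' @param max_iter Maximum assignment/centroid iterations.
#' @return A `consensus_result`: list with `k`, `consensus_signatures`
#'   (k x 96, L1-normalised centroids), `labels` (cluster of each of the
#'   N*k run-signatures), `silhouettes`, `cluster_stability` (tibble of
#'   `C_k`), `C_mean`, `C_min`, `stable` (FALSE if the partition was still
#'   oscillating at `max_iter`).
#' @export
consensus_partition <- function(runs, max_iter = 100L) {
  stopifnot(inherits(runs, "nmf_run_set"))
  k <- runs$k
  N <- runs$n_runs
  sig_list <- lapply(runs$runs, function(r) r$signatures)
  centroids <- sig_list[[1L]]                       # k x 96
  assign_mat <- matrix(0L, nrow = N, ncol = k)      # run x position -> cluster
  stable <- FALSE
  for (iter in seq_len(max_iter)) {
    new_assign <- t(vapply(sig_list, function(S) {
      cost <- 1 - cosine_cross(S, centroids)
      solve_assignment(cost)
    }, integer(k)))
    if (k == 1L) new_assign <- matrix(new_assign, nrow = N)
    if (identical(new_assign, assign_mat)) {
      stable <- TRUE
      break
    }
    assign_mat <- new_assign
    for (cl in seq_len(k)) {
      members <- do.call(rbind, lapply(seq_len(N), function(r) {
        sig_list[[r]][assign_mat[r, ] == cl, , drop = FALSE]
      }))
      cen <- colMeans(members)
      centroids[cl, ] <- cen / sum(cen)
    }
  }
  all_sigs <- do.call(rbind, sig_list)              # (N*k) x 96
  labels <- as.integer(t(assign_mat))               # run-major, position order
  # labels currently per (run, position); reorder to match all_sigs rows
  labels <- unlist(lapply(seq_len(N), function(r) assign_mat[r, ]), use.names = FALSE)
  D <- 1 - cosine_cross(all_sigs, all_sigs)
  D <- pmax((D + t(D)) / 2, 0)
  diag(D) <- 0
  sil <- silhouette_cosine(D, labels)
  Ck <- vapply(seq_len(k), function(cl) mean(sil[labels == cl]), numeric(1L))
  rownames(centroids) <- paste0("consensus_", seq_len(k))
  structure(list(k = k,
                 consensus_signatures = centroids,
                 labels = labels,
                 silhouettes = sil,
                 cluster_stability = tibble::tibble(cluster = seq_len(k), C_k = Ck),
                 C_mean = mean(Ck),
                 C_min = min(Ck),
                 stable = stable),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result> k = ", x$k,
      "; C_mean = ", signif(x$C_mean, 3),
      ", C_min = ", signif(x$C_min, 3), "\n", sep = "")
  invisible(x)
}
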