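#' One non-negative matrix factorisation of a catalogue
#'
#' Factorises a 96 x n catalogue as `V ~ W H` with `W` 96 x k signature
#' profiles and `H` k x n exposures, minimising the generalised
#' Kullback-Leibler divergence (the Poisson-likelihood objective natural for
#' count catalogues, and the objective of the SigProfiler lineage) by
#' multiplicative updates. A Frobenius-objective variant is available.
#' Optionally the input is first Poisson-perturbed (each count replaced by a
#' Poisson draw with that mean) — the per-repetition bootstrap used by
#' consensus extraction.
#'
#' @param cat A [mut_catalogue()] (or a plain non-negative 96 x n matrix).
#' @param k Factorisation rank, `1 <= k < min(96, samples)`.
#' @param resample Poisson-perturb the input before factorising?
#' @param objective `"kl"` (default) or `"frobenius"`.
#' @param max_iter Maximum multiplicative updates.
#' @param tol Relative objective-change convergence tolerance.
#' @param seed Optional integer seed (initialisation and resampling).
#' @return List with `signatures` (k x 96, rows L1-normalised), `exposures`
#'   (k x n, scale absorbed so `t(signatures) %*% exposures` reconstructs the
#'   catalogue), `objective` (final divergence), `objective_trace` (the
#'   divergence after every update, non-increasing), `iterations`, and
#'   `converged` (FALSE carries a convergence warning).
#' @export
run_nmf_once <- function(cat, k, resample = FALSE,
                         objective = c("kl", "frobenius"),
                         max_iter = 2000L, tol = 1e-6, seed = NULL) {
  objective <- match.arg(objective)
  V <- as_plain(as.matrix(cat))
  storage.mode(V) <- "double"
  n <- ncol(V)
  if (!(k >= 1L && k <= min(96L, n))) stop("rank k out of range")
  if (!is.null(seed)) set.seed(seed)
  if (resample) {
    V <- matrix(stats::rpois(length(V), lambda = V), nrow = nrow(V),
                dimnames = dimnames(V))
    storage.mode(V) <- "double"
  }
  eps <- .Machine$double.eps
  W <- matrix(stats::runif(96L * k, 0.1, 1), nrow = 96L)
  H <- matrix(stats::runif(k * n, 0.1, 1), nrow = k)
  # scale H so WH matches the data in total mass
  H <- H * (sum(V) / sum(W %*% H))

  kl_div <- function(V, WH) {
    # generalised KL: sum(v log(v/wh) - v + wh), 0 log 0 = 0
    pos <- V > 0
    sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
  }
  obj <- function() {
    WH <- W %*% H
    if (objective == "kl") kl_div(V, pmax(WH, eps)) else sum((V - WH)^2)
  }

  prev <- obj()
  trace <- prev
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    if (objective == "kl") {
      WH <- pmax(W %*% H, eps)
      W <- W * ((V / WH) %*% t(H)) / rep(pmax(rowSums(H), eps), each = 96L)
      WH <- pmax(W %*% H, eps)
      H <- H * (t(W) %*% (V / WH)) / pmax(colSums(W), eps)
    } else {
      H <- H * (t(W) %*% V) / pmax(t(W) %*% W %*% H, eps)
      W <- W * (V %*% t(H)) / pmax(W %*% H %*% t(H), eps)
    }
    cur <- obj()
    trace <- c(trace, cur)
    if (is.finite(prev) && abs(prev - cur) <= tol * max(abs(prev), 1)) {
      prev <- cur
      converged <- TRUE
      break
    }
    prev <- cur
  }
  if (!converged) {
    warning("NMF did not converge within ", max_iter, " iterations")
  }
  scale <- colSums(W)
  W <- sweep(W, 2L, scale, "/")
  H <- H * scale
  sigs <- t(W)
  rownames(sigs) <- paste0("denovo_", seq_len(k))
  colnames(sigs) <- sbs96_contexts()
  rownames(H) <- rownames(sigs)
  colnames(H) <- colnames(V)
  list(signatures = sigs, exposures = H, objective = prev,
       objective_trace = trace, iterations = it, converged = converged)
}
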