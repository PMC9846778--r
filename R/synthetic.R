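#' Scenario configuration for catalogue simulation
#'
#' Bundles the parameters of one simulation scenario: how many samples, how
#' many mutations per sample (default 5,000, the median mutation burden of
#' PCAWG whole genomes), how many replicate catalogues (default 10, to
#' capture statistical fluctuation), and the seed. Replicate `r` derives its
#' own seed as `seed + r`, so replicates are independent yet reproducible.
#'
#' @param n_samples Number of tumour samples per catalogue.
#' @param mutations_per_sample Total mutations per sample.
#' @param n_replicates Number of replicate catalogues.
#' @param seed Integer seed.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_samples = 200L, mutations_per_sample = 5000L,
                            n_replicates = 10L, seed = 1L) {
  stopifnot(n_samples >= 1, mutations_per_sample >= 1, n_replicates >= 1)
  structure(list(n_samples = as.integer(n_samples),
                 mutations_per_sample = as.integer(mutations_per_sample),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Draw random signature exposures on the simplex
#'
#' Each sample's exposure vector is built from `k` independent Uniform(0, 1)
#' draws normalised to sum to 1 (the SigsPack convention for random mixture
#' weights; note this is not Dirichlet(1, ..., 1), which is offered via
#' `method = "dirichlet"`).
#'
#' @param k Number of signatures.
#' @param n Number of samples.
#' @param method `"uniform"` (normalised uniforms, default) or `"dirichlet"`
#'   (flat Dirichlet).
#' @return A k x n matrix with every column on the simplex.
#' @export
sample_exposures <- function(k, n, method = c("uniform", "dirichlet")) {
  method <- match.arg(method)
  stopifnot(k >= 1, n >= 1)
  u <- switch(method,
    uniform = matrix(stats::runif(k * n), nrow = k),
    dirichlet = matrix(-log(stats::runif(k * n)), nrow = k)  # Exp(1) draws
  )
  e <- u / rep(colSums(u), each = k)
  rownames(e) <- paste0("sig_", seq_len(k))
  colnames(e) <- paste0("sample_", seq_len(n))
  e
}

#' Simulate a mutational catalogue from known signatures
#'
#' For each sample, an exposure vector is drawn on the simplex, the mixture
#' profile `p = sum_k exposure_k * signature_k` is formed, and the sample's
#' mutation counts are one multinomial draw of `mutations_per_sample`
#' mutations from `p` (equivalent to sampling each mutation's context
#' independently).
#'
#' @param sig A [signature_matrix()] of generating signatures.
#' @param cfg A [scenario_config()]. Only `n_samples` and
#'   `mutations_per_sample` are used here.
#' @param exposures Optional fixed exposure matrix (signatures x samples,
#'   columns on the simplex); drawn via [sample_exposures()] when `NULL`.
#' @param seed Optional integer seed applied before drawing.
#' @return A `simulated_catalogue`: list with `catalogue` ([mut_catalogue()]),
#'   `true_signatures` (the input), and `true_exposures` (signatures x
#'   samples, columns summing to 1).
#' @export
simulate_catalogue <- function(sig, cfg = scenario_config(), exposures = NULL,
                               seed = NULL) {
  stopifnot(inherits(sig, "signature_matrix"))
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(sig); n <- cfg$n_samples
  if (is.null(exposures)) {
    exposures <- sample_exposures(k, n)
  } else {
    exposures <- as.matrix(exposures)
    stopifnot(nrow(exposures) == k, ncol(exposures) == n,
              all(exposures >= 0), all(abs(colSums(exposures) - 1) < 1e-8))
  }
  rownames(exposures) <- rownames(sig)
  S <- as_plain(sig)                                    # k x 96
  P <- t(S) %*% exposures                               # 96 x n mixture profiles
  if (any(colSums(P) <= 0)) stop("degenerate all-zero mixture profile")
  counts <- vapply(seq_len(n), function(j) {
    stats::rmultinom(1L, cfg$mutations_per_sample, P[, j])[, 1L]
  }, integer(96L))
  rownames(counts) <- sbs96_contexts()
  colnames(counts) <- colnames(exposures)
  structure(list(catalogue = mut_catalogue(counts),
                 true_signatures = sig,
                 true_exposures = exposures),
            class = "simulated_catalogue")
}

#' @export
print.simulated_catalogue <- function(x, ...) {
  cat("<simulated_catalogue> ", ncol(x$catalogue), " samples from ",
      nrow(x$true_signatures), " signatures\n", sep = "")
  invisible(x)
}

#' Generate replicate catalogues for an extraction scenario
#'
#' Produces `cfg$n_replicates` independent simulated catalogues from the same
#' generating signatures; replicate `r` uses seed `cfg$seed + r`, so the whole
#' scenario is bit-reproducible under a fixed configuration.
#'
#' @param sig A [signature_matrix()] of generating signatures.
#' @param cfg A [scenario_config()].
#' @return List of `simulated_catalogue` objects, length `cfg$n_replicates`.
#' @export
generate_scenario <- function(sig, cfg = scenario_config()) {
  lapply(seq_len(cfg$n_replicates), function(r) {
    simulate_catalogue(sig, cfg, seed = cfg$seed + r)
  })
}

#' Generate synthetic signatures with controlled flatness and similarity
#'
#' Download-free stand-in for reference signature sets: each profile is a
#' mixture `(1 - w) * sparse + w * uniform` of a sparse random profile and
#' the uniform profile, with the mixing weight `w` tuned by bisection until
#' the achieved flatness is within `flatness_tol` of `target_flatness`.
#' Pairwise-similarity constraints are enforced by rejection over fresh
#' sparse supports.
#'
#' @param k Number of signatures.
#' @param target_flatness Target flatness in `[1/sqrt(96), 1]`; recycled to
#'   length `k`.
#' @param max_pairwise_sim,min_pairwise_sim Optional bounds on every pairwise
#'   cosine similarity between generated profiles.
#' @param n_active Number of non-zero contexts in each sparse component
#'   (before uniform mixing); small values give near-orthogonal signatures.
#' @param flatness_tol Tolerance on achieved flatness (default 0.02).
#' @param max_tries Bounded retries for the similarity constraint.
#' @param seed Optional integer seed.
#' @return A [signature_matrix()] of `k` synthetic profiles named
#'   `synth_1 ... synth_k`.
#' @export
generate_synthetic_signatures <- function(k, target_flatness = 0.4,
                                          max_pairwise_sim = NULL,
                                          min_pairwise_sim = NULL,
                                          n_active = 4L, flatness_tol = 0.02,
                                          max_tries = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  target_flatness <- rep_len(target_flatness, k)
  lo <- 1 / sqrt(96)
  if (any(target_flatness < lo - 1e-12 | target_flatness > 1 + 1e-12)) {
    stop("target flatness must lie in [1/sqrt(96), 1]")
  }
  u <- rep(1 / 96, 96)
  mix_to_flatness <- function(p, target) {
    # flatness of (1-w) p + w u is continuous and increasing in w
    f <- function(w) flatness((1 - w) * p + w * u) - target
    if (f(0) >= 0) return(p)
    w <- stats::uniroot(f, c(0, 1), tol = 1e-10)$root
    prof <- (1 - w) * p + w * u
    prof / sum(prof)
  }
  sparse_profile <- function() {
    p <- numeric(96)
    idx <- sample.int(96, n_active)
    p[idx] <- stats::runif(n_active, 0.2, 1)
    p / sum(p)
  }
  best <- NULL; best_viol <- Inf
  for (try in seq_len(max_tries)) {
    profs <- t(vapply(seq_len(k), function(i) {
      mix_to_flatness(sparse_profile(), target_flatness[i])
    }, numeric(96L)))
    achieved <- apply(profs, 1L, flatness)
    if (any(abs(achieved - target_flatness) > flatness_tol)) next
    viol <- 0
    if (k >= 2L) {
      sims <- pairwise_similarity(signature_matrix(profs))$sim
      off <- sims[upper.tri(sims)]
      if (!is.null(max_pairwise_sim)) viol <- viol + max(0, max(off) - max_pairwise_sim)
      if (!is.null(min_pairwise_sim)) viol <- viol + max(0, min_pairwise_sim - min(off))
    }
    if (viol == 0) {
      return(signature_matrix(profs, names = paste0("synth_", seq_len(k))))
    }
    if (viol < best_viol) { best_viol <- viol; best <- profs }
  }
  stop("could not satisfy similarity constraints after ", max_tries,
       " tries; best constraint violation ", signif(best_viol, 3))
}
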