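#' Refit signature exposures by non-negative least squares
#'
#' Each sample's count column is fitted against the signature profiles by
#' NNLS, the standard refitting step for a fixed signature set. Also reports
#' per-sample reconstruction quality: cosine similarity and mean absolute
#' error between the observed and reconstructed columns.
#'
#' @param cat A [mut_catalogue()] (or plain 96 x n matrix).
#' @param sig A [signature_matrix()] (or plain k x 96 matrix, rows =
#'   signatures).
#' @return List with `exposures` (k x n, non-negative), `reconstruction`
#'   (96 x n), and `per_sample`, a tibble with columns `sample`, `cosine`,
#'   `mae`.
#' @export
refit_exposures <- function(cat, sig) {
  V <- as_plain(as.matrix(cat))
  S <- as_plain(as.matrix(sig))
  if (nrow(S) == 0L) stop("empty signature matrix")
  A <- t(S)                       # 96 x k design
  n <- ncol(V); k <- nrow(S)
  E <- matrix(0, nrow = k, ncol = n,
              dimnames = list(rownames(S), colnames(V)))
  for (j in seq_len(n)) {
    E[, j] <- pracma::lsqnonneg(A, V[, j])$x
  }
  R <- A %*% E
  per_sample <- tibble::tibble(
    sample = if (is.null(colnames(V))) paste0("sample_", seq_len(n)) else colnames(V),
    cosine = vapply(seq_len(n), function(j) cosine_similarity(V[, j], R[, j]), numeric(1L)),
    mae = vapply(seq_len(n), function(j) mean(abs(V[, j] - R[, j])), numeric(1L))
  )
  list(exposures = E, reconstruction = R, per_sample = per_sample)
}

#' Mean square error between two catalogues
#'
#' `MSE = sum((x - xhat)^2) / (n * m)` over all matrix elements, computed on
#' raw counts.
#'
#' @param x,xhat Matrices of identical dimension (observed and
#'   reconstructed catalogues).
#' @return A single non-negative number.
#' @export
catalogue_mse <- function(x, xhat) {
  x <- as_plain(as.matrix(x)); xhat <- as.matrix(xhat)
  stopifnot(all(dim(x) == dim(xhat)))
  sum((x - xhat)^2) / length(x)
}

#' Match extracted signatures to ground truth
#'
#' Optimal one-to-one assignment (Hungarian algorithm) maximising total
#' cosine similarity between extracted and true signatures. The extraction
#' is a success when the numbers of signatures agree and every matched pair
#' reaches the cosine threshold.
#'
#' @param extracted,truth Signature matrices (rows = profiles).
#' @param threshold Cosine similarity a matched pair must reach (default
#'   0.8, the conventional similarity criterion for calling two profiles
#'   the same signature).
#' @return List with `matches`, a tibble (`extracted`, `truth`, `cosine`),
#'   and `success` (logical).
#' @export
match_to_truth <- function(extracted, truth, threshold = 0.8) {
  E <- as_plain(as.matrix(extracted))
  Tm <- as_plain(as.matrix(truth))
  ke <- nrow(E); kt <- nrow(Tm)
  sim <- cosine_cross(E, Tm)          # ke x kt
  if (ke <= kt) {
    asg <- solve_assignment(1 - sim)
    matches <- tibble::tibble(
      extracted = if (is.null(rownames(E))) paste0("E", seq_len(ke)) else rownames(E),
      truth = if (is.null(rownames(Tm))) paste0("T", asg) else rownames(Tm)[asg],
      cosine = sim[cbind(seq_len(ke), asg)]
    )
  } else {
    asg <- solve_assignment(1 - t(sim))
    matches <- tibble::tibble(
      extracted = if (is.null(rownames(E))) paste0("E", asg) else rownames(E)[asg],
      truth = if (is.null(rownames(Tm))) paste0("T", seq_len(kt)) else rownames(Tm),
      cosine = sim[cbind(asg, seq_len(kt))]
    )
  }
  success <- (ke == kt) && all(matches$cosine >= threshold)
  list(matches = matches, success = success)
}

#' Choose the number of de novo signatures
#'
#' Runs repeated-NMF consensus extraction over a range of ranks and applies
#' a stability-plus-fit rule: among ranks whose minimum cluster stability
#' `C_min` reaches `stability_threshold`, the largest rank whose
#' reconstruction error still improves on the previous rank by more than
#' `error_tol` (relative) is chosen. If no rank qualifies, the rank with the
#' best `C_min` is returned flagged as unstable. All per-rank diagnostics
#' are returned so other selection rules can be applied downstream.
#'
#' @param cat A [mut_catalogue()].
#' @param k_range Integer vector of candidate ranks.
#' @param n_runs NMF repetitions per rank.
#' @param resample Poisson-bootstrap each repetition?
#' @param stability_threshold Minimum acceptable `C_min` (default 0.7).
#' @param error_tol Relative reconstruction-error improvement required to
#'   prefer a larger rank (default 0.01).
#' @param seed Integer seed.
#' @param ... Passed to [run_nmf_once()].
#' @return A `rank_selection`: list with `chosen_k`, `stable_selection`
#'   (logical), `diagnostics` (tibble of k, C_mean, C_min, mse), and
#'   `results` (named list of `consensus_result` per rank).
#' @export
select_rank <- function(cat, k_range, n_runs = 10L, resample = TRUE,
                        stability_threshold = 0.7, error_tol = 0.01,
                        seed = 1L, ...) {
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(length(k_range) >= 1L)
  results <- list()
  diags <- purrr::map_dfr(seq_along(k_range), function(idx) {
    k <- k_range[idx]
    runs <- repeat_nmf(cat, k, n_runs = n_runs, resample = resample,
                       seed = seed + 1000L * k, ...)
    cons <- consensus_partition(runs)
    fit <- refit_exposures(cat, cons$consensus_signatures)
    mse <- catalogue_mse(cat, fit$reconstruction)
    results[[as.character(k)]] <<- cons
    tibble::tibble(k = k, C_mean = cons$C_mean, C_min = cons$C_min, mse = mse)
  })
  if (length(k_range) == 1L) {
    return(structure(list(chosen_k = k_range, stable_selection = TRUE,
                          diagnostics = diags, results = results),
                     class = "rank_selection"))
  }
  stable <- diags$C_min >= stability_threshold
  improves <- c(TRUE, diff(diags$mse) < -error_tol * utils::head(diags$mse, -1L))
  eligible <- which(stable & improves)
  if (length(eligible) > 0L) {
    chosen <- diags$k[max(eligible)]
    flag <- TRUE
  } else {
    chosen <- diags$k[which.max(diags$C_min)]
    flag <- FALSE
  }
  structure(list(chosen_k = chosen, stable_selection = flag,
                 diagnostics = diags, results = results),
            class = "rank_selection")
}

#' @export
print.rank_selection <- function(x, ...) {
  cat("<rank_selection> chosen k = ", x$chosen_k,
      if (!x$stable_selection) " (unstable selection)" else "", "\n", sep = "")
  print(x$diagnostics)
  invisible(x)
}

#' Extract signatures de novo from one catalogue
#'
#' Convenience wrapper: rank selection followed by consensus extraction at
#' the chosen rank, with exposures refit by NNLS.
#'
#' @inheritParams select_rank
#' @return An `extraction_result`: list with `signatures` (signature_matrix
#'   of consensus profiles), `exposures`, `selection` (the `rank_selection`),
#'   and `consensus` (the chosen rank's `consensus_result`).
#' @export
extract_signatures <- function(cat, k_range, n_runs = 10L, resample = TRUE,
                               seed = 1L, ...) {
  sel <- select_rank(cat, k_range, n_runs = n_runs, resample = resample,
                     seed = seed, ...)
  cons <- sel$results[[as.character(sel$chosen_k)]]
  fit <- refit_exposures(cat, cons$consensus_signatures)
  structure(list(signatures = signature_matrix(cons$consensus_signatures),
                 exposures = fit$exposures,
                 selection = sel,
                 consensus = cons),
            class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  cat("<extraction_result> ", nrow(x$signatures), " consensus signatures; C_mean = ",
      signif(x$consensus$C_mean, 3), "\n", sep = "")
  invisible(x)
}

#' Evaluate de novo extraction over scenario replicates
#'
#' Runs the extractor on each replicate catalogue, matches the consensus
#' signatures to the generating truth, and summarises performance as the
#' success frequency `F` (fraction of replicates where all signatures were
#' correctly identified), the reconstruction `MSE` (median and
#' inter-quartile range across replicates; reconstruction = consensus
#' signatures x NNLS-refit exposures), and the stability scores `C_mean`
#' and `C_min` (medians across replicates).
#'
#' @param replicates List of `simulated_catalogue` objects
#'   (from [generate_scenario()]).
#' @param k_range Candidate ranks for [select_rank()].
#' @param threshold Cosine threshold for a correct identification.
#' @param n_runs,resample,seed,... Extractor settings, see [select_rank()].
#' @return An `extraction_evaluation`: list with `F`, `mse` (tibble: median,
#'   q1, q3), `stability` (tibble: C_mean and C_min medians), and
#'   `per_replicate`, a tibble with one row per replicate (`replicate`,
#'   `chosen_k`, `success`, `mse`, `C_mean`, `C_min`, `min_match_cosine`).
#' @export
evaluate_scenario <- function(replicates, k_range, threshold = 0.8,
                              n_runs = 10L, resample = TRUE, seed = 1L, ...) {
  stopifnot(length(replicates) >= 1L)
  rows <- purrr::map_dfr(seq_along(replicates), function(r) {
    simcat <- replicates[[r]]
    res <- extract_signatures(simcat$catalogue, k_range, n_runs = n_runs,
                              resample = resample, seed = seed + 77L * r, ...)
    m <- match_to_truth(res$signatures, simcat$true_signatures,
                        threshold = threshold)
    fit <- refit_exposures(simcat$catalogue, res$signatures)
    tibble::tibble(
      replicate = r,
      chosen_k = res$selection$chosen_k,
      success = m$success,
      mse = catalogue_mse(simcat$catalogue, fit$reconstruction),
      C_mean = res$consensus$C_mean,
      C_min = res$consensus$C_min,
      min_match_cosine = min(m$matches$cosine)
    )
  })
  structure(list(
    F = mean(rows$success),
    mse = tibble::tibble(median = stats::median(rows$mse),
                         q1 = stats::quantile(rows$mse, 0.25, names = FALSE),
                         q3 = stats::quantile(rows$mse, 0.75, names = FALSE)),
    stability = tibble::tibble(C_mean = stats::median(rows$C_mean),
                               C_min = stats::median(rows$C_min)),
    per_replicate = rows
  ), class = "extraction_evaluation")
}

#' @export
print.extraction_evaluation <- function(x, ...) {
  cat("<extraction_evaluation> F = ", x$F,
      "; MSE median ", signif(x$mse$median, 4),
      " (IQR ", signif(x$mse$q1, 4), "-", signif(x$mse$q3, 4), ")\n", sep = "")
  invisible(x)
}
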