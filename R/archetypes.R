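# Archetypal analysis (principal convex hull) of a signature catalogue.
#
# Model: X (p x q) ~ A Z with Z = B X, rows of A (p x r) and B (r x p) on the
# probability simplex, so every archetype is a convex combination of observed
# profiles and every profile is reconstructed as a convex combination of
# archetypes. Fitting alternates two blocks of simplex-constrained least
# squares, each solved by projected gradient with a Lipschitz step, which
# keeps the residual sum of squares non-increasing and the constraints
# exactly feasible.

# Euclidean projection of each row of M onto the probability simplex
# (sort-based algorithm).
project_simplex_rows <- function(M) {
  n <- nrow(M); k <- ncol(M)
  if (k == 1L) return(matrix(1, n, 1L))
  S <- matrix(M[order(row(M), -M)], n, k, byrow = TRUE)   # row-wise descending sort
  CS <- S %*% upper.tri(diag(k), diag = TRUE)              # row-wise cumulative sums
  cond <- S + (1 - CS) %*% diag(1 / seq_len(k)) > 0        # TRUE on a prefix of each row
  rho <- rowSums(cond)
  tau <- (CS[cbind(seq_len(n), rho)] - 1) / rho
  pmax(M - tau, 0)
}

# Minimise ||X - A G_half|| style block: rows of A on the simplex.
# f(A) = ||X - A Z||_F^2 ; grad = 2 (A G - C) with G = Z Z', C = X Z'.
# Projected gradient with step 1/L, L = 2 * ||G||_2; monotone per row.
pg_simplex_ls <- function(A, G, C, max_iter = 200L, tol = 1e-10) {
  L <- 2 * max(abs(eigen(G, symmetric = TRUE, only.values = TRUE)$values), 1e-12)
  step <- 1 / L
  for (it in seq_len(max_iter)) {
    grad <- 2 * (A %*% G - C)
    A_new <- project_simplex_rows(A - step * grad)
    if (max(abs(A_new - A)) < tol) {
      A <- A_new
      break
    }
    A <- A_new
  }
  A
}

# Furthest-sum initialisation: greedily pick data rows maximally spread out,
# re-picking the arbitrary first choice (standard principal-convex-hull
# seeding).
furthest_sum_init <- function(X, r) {
  p <- nrow(X)
  if (r >= p) return(rep(seq_len(p), length.out = r))
  D <- as.matrix(stats::dist(X))
  chosen <- sample.int(p, 1L)
  for (i in seq_len(r)) {
    sums <- colSums(D[chosen, -chosen, drop = FALSE])
    nxt <- setdiff(seq_len(p), chosen)[which.max(sums)]
    chosen <- c(chosen, nxt)
  }
  chosen[-1L]  # drop the arbitrary seed point
}

#' Fit an archetypal-analysis model
#'
#' Decomposes a signature matrix `X` (p signatures x 96 contexts) into `r`
#' archetypes lying on the convex hull of the data: `X ~ alpha %*% Z` with
#' `Z = beta %*% X`, where the rows of `alpha` (p x r) and `beta` (r x p)
#' are non-negative and sum to 1. Minimises the residual sum of squares by
#' alternating simplex-constrained least squares; SSE is non-increasing
#' across iterations and the simplex constraints hold to machine tolerance
#' at every step.
#'
#' @param X A [signature_matrix()] (or plain rows-are-profiles matrix).
#' @param r Number of archetypes, at least 1. Values of `r` at or above the
#'   number of data rows are allowed (duplicate archetypes reproduce the
#'   data exactly).
#' @param max_iter Maximum alternating iterations.
#' @param tol Relative SSE-change convergence tolerance.
#' @param seed Optional integer seed (furthest-sum initialisation start).
#' @param ev_baseline Baseline for explained variance: `"mean"` (total sum
#'   of squares about the mean profile, default) or `"zero"` (about the
#'   origin).
#' @return An `archetype_model`: list with `r`, `Z` (r x 96 archetype
#'   profiles), `alpha` (p x r), `beta` (r x p), `sse`, `sse_trace` (the SSE
#'   after every alternating iteration, non-increasing),
#'   `explained_variance`, `converged`, `iterations`, `ev_baseline`.
#' @export
fit_archetypes <- function(X, r, max_iter = 200L, tol = 1e-8, seed = NULL,
                           ev_baseline = c("mean", "zero")) {
  ev_baseline <- match.arg(ev_baseline)
  Xm <- as_plain(as.matrix(X))
  p <- nrow(Xm); q <- ncol(Xm)
  stopifnot(r >= 1L)
  if (!is.null(seed)) set.seed(seed)

  init_idx <- furthest_sum_init(Xm, r)
  B <- matrix(0, nrow = r, ncol = p)
  B[cbind(seq_len(r), init_idx)] <- 1
  Z <- B %*% Xm
  if (r >= p) {
    # each data row is its own archetype: start at the exact solution
    A <- matrix(0, nrow = p, ncol = r)
    A[cbind(seq_len(p), seq_len(p))] <- 1
  } else {
    A <- matrix(1 / r, nrow = p, ncol = r)
  }

  sse <- function(A, Z) sum((Xm - A %*% Z)^2)
  prev <- sse(A, Z)
  sse_trace <- prev
  converged <- FALSE
  it <- 0L
  XtX <- tcrossprod(Xm)            # p x p Gram of data rows
  xtx_lmax <- max(abs(eigen(XtX, symmetric = TRUE, only.values = TRUE)$values))
  for (it in seq_len(max_iter)) {
    # alpha step: rows of A on simplex, G = Z Z', C = X Z'
    A <- pg_simplex_ls(A, tcrossprod(Z), tcrossprod(Xm, Z))
    # beta step: f(B) = ||X - A B X||^2, grad_B = 2 A'(A B X - X) X'
    # projected gradient with L = 2 ||A'A||_2 ||X X'||_2
    AtA <- crossprod(A)
    L <- 2 * max(abs(eigen(AtA, symmetric = TRUE, only.values = TRUE)$values)) * xtx_lmax
    step <- 1 / max(L, 1e-12)
    for (inner in seq_len(50L)) {
      grad <- 2 * AtA %*% B %*% XtX - 2 * crossprod(A, XtX)
      B_new <- project_simplex_rows(B - step * grad)
      if (max(abs(B_new - B)) < 1e-10) { B <- B_new; break }
      B <- B_new
    }
    Z <- B %*% Xm
    cur <- sse(A, Z)
    sse_trace <- c(sse_trace, cur)
    if (abs(prev - cur) <= tol * max(prev, 1e-12)) {
      prev <- cur
      converged <- TRUE
      break
    }
    prev <- cur
  }
  tss <- switch(ev_baseline,
    mean = sum(sweep(Xm, 2L, colMeans(Xm))^2),
    zero = sum(Xm^2)
  )
  ev <- if (tss > 0) 1 - prev / tss else 1
  rn <- rownames(Xm); if (is.null(rn)) rn <- paste0("S", seq_len(p))
  dimnames(Z) <- list(paste0("A", seq_len(r)), colnames(Xm))
  dimnames(A) <- list(rn, rownames(Z))
  dimnames(B) <- list(rownames(Z), rn)
  structure(list(r = as.integer(r), Z = Z, alpha = A, beta = B,
                 sse = prev, sse_trace = sse_trace,
                 explained_variance = ev,
                 converged = converged, iterations = it,
                 ev_baseline = ev_baseline),
            class = "archetype_model")
}

#' @export
print.archetype_model <- function(x, ...) {
  cat("<archetype_model> r = ", x$r,
      "; SSE = ", signif(x$sse, 4),
      ", explained variance = ", signif(x$explained_variance, 4), "\n", sep = "")
  invisible(x)
}

#' Explained-variance curve over a range of archetype numbers
#'
#' Fits archetypal models for each `r` with several random restarts and
#' keeps the best (lowest-SSE) model per `r`. The curve is non-decreasing
#' in `r` up to optimisation noise.
#'
#' @param X A [signature_matrix()].
#' @param r_range Increasing integer vector of candidate archetype numbers.
#' @param restarts Random restarts per `r` (default 5).
#' @param seed Integer seed; restart `s` at rank `r` uses `seed + 131*r + s`.
#' @param ... Passed to [fit_archetypes()].
#' @return An `ev_curve`: tibble with columns `r`, `explained_variance`,
#'   `sse`, plus attribute `models` (best model per r).
#' @export
explained_variance_curve <- function(X, r_range, restarts = 5L, seed = 1L, ...) {
  r_range <- sort(unique(as.integer(r_range)))
  models <- vector("list", length(r_range))
  rows <- purrr::map_dfr(seq_along(r_range), function(i) {
    r <- r_range[i]
    fits <- lapply(seq_len(restarts), function(s) {
      fit_archetypes(X, r, seed = seed + 131L * r + s, ...)
    })
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1L), "sse"))]]
    models[[i]] <<- best
    tibble::tibble(r = r, explained_variance = best$explained_variance,
                   sse = best$sse)
  })
  names(models) <- as.character(r_range)
  structure(rows, models = models, class = c("ev_curve", class(rows)))
}

#' Select the number of archetypes from an explained-variance curve
#'
#' @param curve An `ev_curve` (or any data frame with columns `r` and
#'   `explained_variance`).
#' @param threshold Explained-variance target (default 0.95).
#' @return List with `r` (smallest `r` reaching the threshold, or the
#'   largest available when none does) and `reached` (logical).
#' @export
select_num_archetypes <- function(curve, threshold = 0.95) {
  stopifnot(nrow(curve) >= 1L)
  ok <- which(curve$explained_variance >= threshold)
  if (length(ok) > 0L) {
    list(r = curve$r[min(ok)], reached = TRUE)
  } else {
    list(r = max(curve$r), reached = FALSE)
  }
}

#' Reconstruction report for an archetypal model
#'
#' Scores how well each signature is reconstructed from the archetypes
#' (cosine between `x_i` and `sum_k alpha_ik z_k`) and how closely each
#' archetype corresponds to an observed signature (its best cosine match).
#'
#' @param model An `archetype_model`.
#' @param X The signature matrix the model was fitted on.
#' @param correspondence_threshold Cosine above which an archetype is
#'   counted as corresponding to a signature (default 0.97).
#' @return An `archetype_report`: list with `per_signature` (tibble:
#'   `signature`, `reconstruction_cosine`), `per_archetype` (tibble:
#'   `archetype`, `best_signature`, `cosine`), and
#'   `n_corresponding` (archetypes at or above the threshold).
#' @export
reconstruction_report <- function(model, X, correspondence_threshold = 0.97) {
  Xm <- as_plain(as.matrix(X))
  stopifnot(nrow(Xm) == nrow(model$alpha))
  R <- model$alpha %*% model$Z
  rn <- rownames(Xm); if (is.null(rn)) rn <- paste0("S", seq_len(nrow(Xm)))
  per_sig <- tibble::tibble(
    signature = rn,
    reconstruction_cosine = vapply(seq_len(nrow(Xm)), function(i) {
      cosine_similarity(Xm[i, ], R[i, ])
    }, numeric(1L))
  )
  sim <- cosine_cross(model$Z, Xm)     # r x p
  best <- apply(sim, 1L, which.max)
  per_arch <- tibble::tibble(
    archetype = rownames(model$Z),
    best_signature = rn[best],
    cosine = sim[cbind(seq_len(nrow(sim)), best)]
  )
  structure(list(per_signature = per_sig,
                 per_archetype = per_arch,
                 n_corresponding = sum(per_arch$cosine >= correspondence_threshold),
                 correspondence_threshold = correspondence_threshold),
            class = "archetype_report")
}

#' @export
print.archetype_report <- function(x, ...) {
  cat("<archetype_report> ", x$n_corresponding, "/", nrow(x$per_archetype),
      " archetypes correspond to a signature at cosine >= ",
      x$correspondence_threshold, "\n", sep = "")
  invisible(x)
}

#' Group signatures by their archetype coefficients
#'
#' Signatures sharing a reconstruction pattern are found by hierarchically
#' clustering their full alpha rows (cosine distance, average linkage) and
#' cutting the tree. Each group is annotated with its dominant archetype
#' (largest mean alpha). For display, coefficients below
#' `display_threshold` are masked (set to NA) — clustering always uses the
#' full values.
#'
#' @param model An `archetype_model`.
#' @param distance_cut Tree cut height on cosine distance of alpha rows
#'   (default 0.5).
#' @param display_threshold Alpha below which the display table masks the
#'   value (default 0.2).
#' @return List with `groups`, a tibble (`signature`, `group`,
#'   `dominant_archetype`), `display`, the masked alpha matrix in cluster
#'   leaf order, and `linkage`, the `hclust` tree.
#' @export
alpha_grouping <- function(model, distance_cut = 0.5, display_threshold = 0.2) {
  A <- model$alpha
  norms <- sqrt(rowSums(A^2))
  An <- A / norms
  D <- pmax(1 - tcrossprod(An), 0)
  D <- (D + t(D)) / 2; diag(D) <- 0
  h <- stats::hclust(stats::as.dist(D), method = "average")
  grp <- stats::cutree(h, h = distance_cut)
  dom <- vapply(sort(unique(grp)), function(g) {
    colnames(A)[which.max(colMeans(A[grp == g, , drop = FALSE]))]
  }, character(1L))
  groups <- tibble::tibble(
    signature = rownames(A),
    group = as.integer(grp),
    dominant_archetype = dom[grp]
  )
  display <- A[h$order, , drop = FALSE]
  display[display < display_threshold] <- NA_real_
  list(groups = groups, display = display, linkage = h)
}

#' Consistency of profile similarity and alpha similarity
#'
#' For every pair of signatures, emits the cosine similarity of their
#' profiles alongside the cosine similarity of their alpha coefficient
#' rows, with a Spearman rank-correlation summary. A faithful compact
#' representation shows alpha similarity increasing with profile
#' similarity.
#'
#' @param model An `archetype_model`.
#' @param X The signature matrix the model was fitted on.
#' @return List with `pairs`, a tibble (`sig_a`, `sig_b`,
#'   `profile_cosine`, `alpha_cosine`), and `spearman_rho`.
#' @export
alpha_similarity_consistency <- function(model, X) {
  Xm <- as_plain(as.matrix(X))
  sim_x <- cosine_cross(Xm, Xm)
  A <- model$alpha
  # alpha rows can be one-hot; zero rows cannot occur (simplex)
  sim_a <- cosine_cross(A, A)
  ij <- which(upper.tri(sim_x), arr.ind = TRUE)
  rn <- rownames(Xm); if (is.null(rn)) rn <- paste0("S", seq_len(nrow(Xm)))
  pairs <- tibble::tibble(
    sig_a = rn[ij[, 1L]],
    sig_b = rn[ij[, 2L]],
    profile_cosine = sim_x[ij],
    alpha_cosine = sim_a[ij]
  )
  rho <- stats::cor(pairs$profile_cosine, pairs$alpha_cosine, method = "spearman")
  list(pairs = pairs, spearman_rho = rho)
}
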