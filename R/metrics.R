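#' Cosine similarity between two mutation-context profiles
#'
#' `cos(a, b) = (a . b) / (||a|| ||b||)`, the standard similarity measure for
#' comparing SBS-96 profiles. For non-negative profiles the value lies in
#' \[0, 1\].
#'
#' @param a,b Numeric vectors of equal length, not all zero.
#' @return A single number in \[-1, 1\].
#' @examples
#' cosine_similarity(rep(1, 96), rep(2, 96))  # 1: scale-invariant
#' @export
cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Flatness of a signature profile
#'
#' Flatness is the cosine similarity between a profile and the uniform
#' distribution over the 96 mutational classes. It ranges from
#' `1/sqrt(96)` (a one-hot profile, ~0.102) to 1 (a perfectly flat profile)
#' and is invariant to rescaling of the profile.
#'
#' @param s Non-negative, non-zero numeric vector (length 96 for SBS use,
#'   but any length is accepted).
#' @return Flatness score in \[0, 1\].
#' @examples
#' flatness(rep(1, 96))       # 1
#' flatness(c(1, rep(0, 95))) # 1/sqrt(96)
#' @export
flatness <- function(s) {
  s <- as.numeric(s)
  if (any(s < 0)) stop("flatness is defined for non-negative profiles")
  cosine_similarity(s, rep(1, length(s)))
}

#' Per-signature flatness of a signature matrix
#'
#' @param sig A [signature_matrix()].
#' @return A tibble with columns `signature`, `flatness`.
#' @export
signature_flatness <- function(sig) {
  stopifnot(inherits(sig, "signature_matrix"))
  tibble::tibble(
    signature = rownames(sig),
    flatness = unname(apply(as_plain(sig), 1L, flatness))
  )
}

#' Pairwise cosine similarity of a signature catalogue
#'
#' Computes the d x d cosine-similarity matrix over signature rows and the
#' associated distance matrix `dist = 1 - sim` used for cluster-map
#' construction.
#'
#' @param sig A [signature_matrix()] with at least two rows, or a plain
#'   rows-are-profiles matrix.
#' @return A `similarity_matrix` object: list with elements `names`, `sim`
#'   (symmetric, unit diagonal), and `dist` (`1 - sim`).
#' @export
pairwise_similarity <- function(sig) {
  m <- as_plain(as.matrix(sig))
  if (nrow(m) < 2L) stop("need at least two signatures")
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) stop("cosine similarity undefined for a zero profile")
  mn <- m / norms
  sim <- tcrossprod(mn)
  sim <- (sim + t(sim)) / 2          # enforce exact symmetry
  diag(sim) <- 1
  nm <- rownames(m)
  if (is.null(nm)) nm <- paste0("S", seq_len(nrow(m)))
  dimnames(sim) <- list(nm, nm)
  structure(list(names = nm, sim = sim, dist = 1 - sim),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  d <- length(x$names)
  off <- x$sim[upper.tri(x$sim)]
  cat("<similarity_matrix> ", d, " x ", d,
      "; median off-diagonal similarity ", signif(stats::median(off), 3), "\n", sep = "")
  invisible(x)
}

#' Tidy a similarity matrix into pair rows
#'
#' @param x A `similarity_matrix`.
#' @param ... Unused.
#' @return A tibble of unordered pairs (strict upper triangle) with columns
#'   `sig_a`, `sig_b`, `similarity`, `distance`.
#' @export
tidy.similarity_matrix <- function(x, ...) {
  d <- length(x$names)
  ij <- which(upper.tri(x$sim), arr.ind = TRUE)
  tibble::tibble(
    sig_a = x$names[ij[, 1L]],
    sig_b = x$names[ij[, 2L]],
    similarity = x$sim[ij],
    distance = x$dist[ij]
  )
}

#' Hierarchical cluster map of a signature catalogue
#'
#' Average-linkage agglomerative clustering of the cosine-distance matrix,
#' the construction used to identify groups of mutually similar signatures.
#'
#' @param simm A `similarity_matrix` from [pairwise_similarity()].
#' @return A `cluster_map`: list with the `stats::hclust` merge tree
#'   (`linkage`), the leaf order (`leaf_order`), and the signature `names`.
#' @export
build_cluster_map <- function(simm) {
  stopifnot(inherits(simm, "similarity_matrix"))
  h <- stats::hclust(stats::as.dist(simm$dist), method = "average")
  structure(list(linkage = h, leaf_order = h$order, names = simm$names),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat("<cluster_map> average-linkage tree over ", length(x$names),
      " signatures\n", sep = "")
  invisible(x)
}

#' Cut a cluster map into signature groups
#'
#' @param cmap A `cluster_map`.
#' @param similarity_cut Signatures are grouped when their merge similarity
#'   exceeds this value; i.e. the tree is cut at distance
#'   `1 - similarity_cut`. Defaults to 0.8, the conventional
#'   "cosine similarity > 0.8" grouping criterion.
#' @return A tibble with columns `signature`, `group` (integer id).
#' @export
cut_cluster_map <- function(cmap, similarity_cut = 0.8) {
  stopifnot(inherits(cmap, "cluster_map"))
  grp <- stats::cutree(cmap$linkage, h = 1 - similarity_cut)
  tibble::tibble(signature = names(grp), group = as.integer(grp))
}

#' Export a cluster map as Newick text
#'
#' @param cmap A `cluster_map`.
#' @param path Optional file path; when given the string is also written there.
#' @return A Newick string (branch lengths are cosine distances).
#' @export
cluster_map_newick <- function(cmap, path = NULL) {
  stopifnot(inherits(cmap, "cluster_map"))
  h <- cmap$linkage
  heights <- h$height
  build <- function(node, parent_h) {
    if (node < 0) {
      lab <- h$labels[-node]
      paste0(gsub("[ ,:;()]", "_", lab), ":", format(parent_h / 2, digits = 8))
    } else {
      hh <- heights[node]
      kids <- vapply(h$merge[node, ], build, character(1L), parent_h = hh)
      paste0("(", paste(kids, collapse = ","), "):",
             format(max(parent_h - hh, 0) / 2, digits = 8))
    }
  }
  n <- length(heights)
  root_h <- heights[n]
  kids <- vapply(h$merge[n, ], build, character(1L), parent_h = root_h)
  nwk <- paste0("(", paste(kids, collapse = ","), ");")
  if (!is.null(path)) writeLines(nwk, path)
  nwk
}

#' Similarity and flatness summary of a signature set
#'
#' The quantities used to characterise an extraction scenario: the median
#' pairwise cosine similarity (strict upper triangle, each unordered pair
#' counted once), the most similar pair, and the median flatness.
#'
#' @param sig A [signature_matrix()] with at least two rows.
#' @return A one-row tibble with columns `n_signatures`, `median_similarity`,
#'   `max_similarity`, `max_pair_a`, `max_pair_b`, `median_flatness`. Ties in
#'   the maximum pair are broken by lexicographic signature-name order.
#' @export
scenario_summary <- function(sig) {
  stopifnot(inherits(sig, "signature_matrix"))
  simm <- pairwise_similarity(sig)
  pairs <- tidy(simm) |>
    dplyr::arrange(dplyr::desc(.data$similarity), pmin(.data$sig_a, .data$sig_b),
                   pmax(.data$sig_a, .data$sig_b))
  fl <- signature_flatness(sig)
  tibble::tibble(
    n_signatures = nrow(sig),
    median_similarity = stats::median(pairs$similarity),
    max_similarity = pairs$similarity[1L],
    max_pair_a = pairs$sig_a[1L],
    max_pair_b = pairs$sig_b[1L],
    median_flatness = stats::median(fl$flatness)
  )
}
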