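# In-code fixtures: everything is generated at test time, no stored data.

# k simple block signatures: signature i concentrated on its own block of
# contexts, mutually orthogonal by construction.
block_signatures <- function(k, block = floor(96 / k)) {
  m <- matrix(0, nrow = k, ncol = 96)
  for (i in seq_len(k)) {
    m[i, ((i - 1L) * block + 1L):(i * block)] <- 1
  }
  signature_matrix(m, names = paste0("block_", seq_len(k)))
}

# write a signature matrix as a COSMIC-dialect TSV, optionally with
# scrambled row order and/or percentage scaling
write_toy_cosmic <- function(sig, path = tempfile(fileext = ".tsv"),
                             scramble = FALSE, scale = 1) {
  df <- data.frame(Type = sbs96_contexts(), t(unclass(sig)) * scale,
                   check.names = FALSE)
  if (scramble) df <- df[sample.int(96L), ]
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# exhaustive minimum-cost assignment for small square matrices
brute_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- Inf; bestp <- NULL
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < best) { best <- cc; bestp <- p }
  }
  list(cost = best, assignment = bestp)
}

# cosine distance matrix between rows, as plain matrix
cos_dist <- function(M) {
  Mn <- M / sqrt(rowSums(M^2))
  D <- 1 - tcrossprod(Mn)
  D <- pmax((D + t(D)) / 2, 0)
  diag(D) <- 0
  D
}
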