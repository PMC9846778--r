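# toy hull: 3 synthetic extreme profiles plus interior convex mixtures
triangle_data <- function(n_interior = 40, seed = 101) {
  verts <- generate_synthetic_signatures(3, target_flatness = 0.3,
                                         max_pairwise_sim = 0.3, seed = seed)
  V <- unclass(verts)
  set.seed(seed + 1)
  W <- matrix(rexp(n_interior * 3), n_interior)
  W <- W / rowSums(W)
  X <- rbind(V, W %*% V)
  rownames(X) <- c(paste0("vertex_", 1:3), paste0("mix_", seq_len(n_interior)))
  list(X = signature_matrix(X), vertices = V)
}

test_that("archetypes recover the vertices of a convex hull", {
  td <- triangle_data()
  fit <- fit_archetypes(td$X, 3, seed = 7)
  expect_lt(fit$sse, 1e-6)
  best <- vapply(1:3, function(k) {
    max(vapply(1:3, function(j) cosine_similarity(fit$Z[k, ], td$vertices[j, ]),
               numeric(1)))
  }, numeric(1))
  expect_true(all(best >= 0.99))
})

test_that("SSE is non-increasing and the simplex constraints hold throughout", {
  set.seed(102)
  X <- signature_matrix(matrix(runif(12 * 96), 12))
  fit <- fit_archetypes(X, 4, seed = 3)
  expect_true(all(diff(fit$sse_trace) <= 1e-10))
  expect_true(all(fit$alpha >= -1e-9))
  expect_lt(max(abs(rowSums(fit$alpha) - 1)), 1e-9)
  expect_true(all(fit$beta >= -1e-9))
  expect_lt(max(abs(rowSums(fit$beta) - 1)), 1e-9)
  # archetypes are exactly convex combinations of the data rows
  expect_identical(fit$Z, fit$beta %*% unclass(X))
})

test_that("r equal to the number of rows reproduces the data", {
  set.seed(103)
  X <- signature_matrix(matrix(runif(5 * 96), 5))
  fit <- fit_archetypes(X, 5, seed = 4)
  expect_lt(fit$sse, 1e-8)
  expect_gt(fit$explained_variance, 1 - 1e-6)
})

test_that("alternating solver is no worse than a dense grid-search oracle", {
  # r = 1, p = 4, q = 3: alpha is forced to 1, so SSE(beta) can be scanned
  # exhaustively over the simplex at resolution 0.02
  set.seed(104)
  Xm <- matrix(runif(12), 4, 3)
  comps <- expand.grid(i = 0:50, j = 0:50)
  comps <- comps[comps$i + comps$j <= 50, ]
  grid <- cbind(comps$i, comps$j, 50 - comps$i - comps$j,
                rep(0, nrow(comps)))
  # all placements of the zero column
  grids <- do.call(rbind, lapply(1:4, function(pos) {
    g <- grid
    g[, c(pos, 4)] <- g[, c(4, pos)]
    g
  })) / 50
  Zs <- grids %*% Xm                       # candidate archetypes
  sse_grid <- vapply(seq_len(nrow(Zs)), function(g) {
    sum(sweep(Xm, 2, Zs[g, ])^2)
  }, numeric(1))
  oracle <- min(sse_grid)
  fit <- fit_archetypes(Xm, 1, seed = 5)
  expect_lte(fit$sse, oracle + 1e-3)
})

test_that("explained variance is nondecreasing in r and selection picks the threshold", {
  td <- triangle_data(n_interior = 25, seed = 105)
  curve <- explained_variance_curve(td$X, 1:3, restarts = 2, seed = 9)
  expect_true(all(diff(curve$explained_variance) >= -1e-6))
  expect_gt(curve$explained_variance[3], 0.999)

  sel <- select_num_archetypes(curve, threshold = 0.95)
  expect_equal(sel$r, 3L)
  expect_true(sel$reached)
  toy <- tibble::tibble(r = 1:2, explained_variance = c(0.5, 0.96))
  expect_equal(select_num_archetypes(toy, 0.95)$r, 2L)
  expect_equal(select_num_archetypes(toy, 0)$r, 1L)
  unreached <- select_num_archetypes(toy, 0.99)
  expect_equal(unreached$r, 2L)
  expect_false(unreached$reached)
})

test_that("reconstruction report scores signatures and archetype correspondence", {
  td <- triangle_data(n_interior = 20, seed = 106)
  perfect <- fit_archetypes(td$X, nrow(td$X), seed = 2)
  rep_perfect <- reconstruction_report(perfect, td$X)
  expect_true(all(rep_perfect$per_signature$reconstruction_cosine > 1 - 1e-9))

  fit <- fit_archetypes(td$X, 3, seed = 2)
  rep3 <- reconstruction_report(fit, td$X, correspondence_threshold = 0.97)
  expect_true(all(rep3$per_signature$reconstruction_cosine > 0.99))
  expect_equal(rep3$n_corresponding, 3L)    # archetypes sit on the vertices
  expect_true(all(rep3$per_archetype$cosine <= 1 + 1e-12))
})

test_that("alpha grouping assigns one-hot signatures to their dominant archetype", {
  td <- triangle_data(n_interior = 10, seed = 107)
  fit <- fit_archetypes(td$X, 3, seed = 6)
  grouping <- alpha_grouping(fit)
  expect_setequal(grouping$groups$signature, rownames(td$X))
  # each vertex row has a one-hot alpha; its group's dominant archetype is
  # the archetype carrying that weight
  for (v in 1:3) {
    a <- fit$alpha[paste0("vertex_", v), ]
    expect_gt(max(a), 0.99)
    row <- grouping$groups[grouping$groups$signature == paste0("vertex_", v), ]
    expect_equal(row$dominant_archetype, names(which.max(a)))
  }
  # signatures with identical alpha rows land in the same group
  X2 <- signature_matrix(rbind(unclass(td$X), twin = unclass(td$X)["vertex_1", ]))
  fit2 <- fit_archetypes(X2, 3, seed = 6)
  g2 <- alpha_grouping(fit2)$groups
  expect_equal(g2$group[g2$signature == "twin"],
               g2$group[g2$signature == "vertex_1"])
  # display masks small coefficients but groups reflect full values
  expect_true(all(is.na(grouping$display) | grouping$display >= 0.2))
})

test_that("alpha similarity tracks profile similarity", {
  td <- triangle_data(n_interior = 30, seed = 108)
  fit <- fit_archetypes(td$X, 3, seed = 8)
  cons <- alpha_similarity_consistency(fit, td$X)
  expect_equal(nrow(cons$pairs), choose(nrow(td$X), 2))
  expect_gt(cons$spearman_rho, 0.3)
  # identical profiles: both cosines 1
  X2 <- signature_matrix(rbind(unclass(td$X), dup = unclass(td$X)[1, ]))
  fit2 <- fit_archetypes(X2, 3, seed = 8)
  cons2 <- alpha_similarity_consistency(fit2, X2)
  pair <- cons2$pairs[cons2$pairs$sig_a == "vertex_1" & cons2$pairs$sig_b == "dup", ]
  expect_equal(pair$profile_cosine, 1, tolerance = 1e-9)
  expect_equal(pair$alpha_cosine, 1, tolerance = 1e-3)
})
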