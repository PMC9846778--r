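test_that("cosine similarity has the expected closed-form values", {
  v <- runif(96)
  expect_equal(cosine_similarity(v, v), 1)
  e1 <- c(1, rep(0, 95)); e2 <- c(0, 1, rep(0, 94))
  expect_equal(cosine_similarity(e1, e2), 0)
  expect_equal(cosine_similarity(v, 3.7 * v), 1)
  expect_error(cosine_similarity(rep(0, 96), v), "zero")
})

test_that("flatness matches closed forms and is scale invariant", {
  expect_equal(flatness(rep(1, 96)), 1)
  expect_equal(flatness(c(1, rep(0, 95))), 1 / sqrt(96))
  set.seed(21)
  for (i in 1:20) {
    s <- runif(96)
    c0 <- runif(1, 0.01, 100)
    expect_equal(flatness(c0 * s), flatness(s), tolerance = 1e-12)
  }
  expect_error(flatness(rep(0, 96)), "zero")
  expect_error(flatness(c(-1, rep(1, 95))), "non-negative")
})

test_that("pairwise similarity equals the brute-force double loop", {
  set.seed(22)
  sig <- signature_matrix(matrix(runif(6 * 96), 6))
  simm <- pairwise_similarity(sig)
  brute <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    brute[i, j] <- cosine_similarity(unclass(sig)[i, ], unclass(sig)[j, ])
  }
  expect_lt(max(abs(simm$sim - brute)), 1e-12)
  expect_equal(simm$dist, 1 - simm$sim)
  expect_equal(unname(diag(simm$sim)), rep(1, 6), tolerance = 1e-12)
  expect_identical(simm$sim, t(simm$sim))
})

test_that("degenerate similarity inputs behave as specified", {
  same <- signature_matrix(matrix(rep(runif(96), 3), 3, byrow = TRUE))
  simm <- pairwise_similarity(same)
  expect_equal(unname(simm$sim), matrix(1, 3, 3), tolerance = 1e-12)
  orth <- block_signatures(2)
  expect_equal(pairwise_similarity(orth)$sim[1, 2], 0)
  expect_error(pairwise_similarity(block_signatures(2)[1, , drop = FALSE]),
               "at least two")
})

test_that("average-linkage cluster map merges identical pairs first, heights nondecreasing", {
  set.seed(23)
  base <- runif(96)
  m <- rbind(base, base, c(rep(0, 95), 1) + runif(96) * 1e-3)
  sig <- signature_matrix(m, names = c("dupA", "dupB", "far"))
  cm <- build_cluster_map(pairwise_similarity(sig))
  expect_equal(sort(cm$linkage$merge[1, ]), c(-2, -1))  # identical pair joins first
  expect_lt(cm$linkage$height[1], 1e-12)
  expect_true(all(diff(cm$linkage$height) >= -1e-12))

  rand <- signature_matrix(matrix(runif(5 * 96), 5))
  cm5 <- build_cluster_map(pairwise_similarity(rand))
  expect_true(all(diff(cm5$linkage$height) >= -1e-12))
  groups <- cut_cluster_map(cm5, similarity_cut = 1)  # cut at distance 0
  expect_equal(dplyr::n_distinct(groups$group), 5L)
  expect_setequal(groups$signature, rownames(rand))
})

test_that("scenario summary matches brute-force enumeration of pairs", {
  set.seed(24)
  sig <- signature_matrix(matrix(runif(3 * 96), 3),
                          names = c("s1", "s2", "s3"))
  s <- scenario_summary(sig)
  m <- unclass(sig)
  sims <- c(cosine_similarity(m[1, ], m[2, ]),
            cosine_similarity(m[1, ], m[3, ]),
            cosine_similarity(m[2, ], m[3, ]))
  fl <- c(flatness(m[1, ]), flatness(m[2, ]), flatness(m[3, ]))
  expect_equal(s$median_similarity, median(sims))
  expect_equal(s$max_similarity, max(sims))
  expect_equal(s$median_flatness, median(fl))
  expect_equal(s$n_signatures, 3L)

  dup <- signature_matrix(matrix(rep(runif(96), 2), 2, byrow = TRUE))
  sdup <- scenario_summary(dup)
  expect_equal(sdup$median_similarity, 1, tolerance = 1e-12)
  expect_equal(sdup$max_similarity, 1, tolerance = 1e-12)
})

test_that("cluster map exports parseable Newick", {
  set.seed(25)
  sig <- signature_matrix(matrix(runif(4 * 96), 4))
  cm <- build_cluster_map(pairwise_similarity(sig))
  nwk <- cluster_map_newick(cm)
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, rownames(sig))
})
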