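test_that("truth matching equals exhaustive permutation search", {
  set.seed(81)
  for (k in c(2, 4, 6)) {
    truth <- signature_matrix(matrix(runif(k * 96), k))
    perm <- sample(k)
    extracted <- signature_matrix(unclass(truth)[perm, , drop = FALSE],
                                  names = paste0("E", seq_len(k)))
    m <- match_to_truth(extracted, truth)
    expect_true(m$success)
    expect_equal(unname(m$matches$cosine), rep(1, k), tolerance = 1e-12)
    # optimal total cosine equals brute-force assignment optimum
    sim <- matrix(0, k, k)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      sim[i, j] <- cosine_similarity(unclass(extracted)[i, ], unclass(truth)[j, ])
    }
    expect_equal(sum(m$matches$cosine), -brute_assignment(-sim)$cost,
                 tolerance = 1e-12)
  }
})

test_that("truth matching flags wrong counts and poor matches", {
  sig <- block_signatures(3)
  self <- match_to_truth(sig, sig)
  expect_true(self$success)
  noisy <- unclass(sig)
  set.seed(82)
  noisy[2, ] <- runif(96)
  bad <- match_to_truth(signature_matrix(noisy), sig, threshold = 0.95)
  expect_false(bad$success)
  fewer <- match_to_truth(signature_matrix(unclass(sig)[1:2, ]), sig)
  expect_false(fewer$success)
  expect_equal(nrow(fewer$matches), 2L)
})

test_that("catalogue MSE equals elementwise brute force", {
  x <- matrix(c(1, 2, 3, 4), 2)
  xhat <- matrix(c(1.5, 2, 2, 6), 2)
  expect_equal(catalogue_mse(x, xhat),
               (0.5^2 + 0 + 1 + 4) / 4)
  set.seed(83)
  a <- matrix(rpois(96 * 5, 50), 96)
  b <- a + matrix(rnorm(96 * 5), 96)
  expect_equal(catalogue_mse(a, b), sum((a - b)^2) / (96 * 5), tolerance = 1e-12)
  expect_equal(catalogue_mse(a, a), 0)
})

test_that("NNLS refitting recovers exact exposures on noiseless data", {
  set.seed(84)
  sig <- block_signatures(3)
  E <- matrix(runif(3 * 8, 10, 100), 3)
  V <- t(unclass(sig)) %*% E
  V <- round(V)             # integer counts, still exactly representable? keep raw
  fit <- refit_exposures(t(unclass(sig)) %*% E, sig)
  expect_lt(max(abs(fit$exposures - E)), 1e-6)
  expect_equal(fit$per_sample$cosine, rep(1, 8), tolerance = 1e-9)
  expect_equal(fit$per_sample$mae, rep(0, 8), tolerance = 1e-9)
})

test_that("single-signature refit equals the NNLS scalar projection", {
  set.seed(85)
  sig <- signature_matrix(matrix(runif(96), 1))
  a <- t(unclass(sig))[, 1]
  x <- rpois(96, 30)
  fit <- refit_exposures(matrix(x, 96), sig)
  # scalar NNLS: argmin_{e >= 0} ||x - e a||^2 via fine grid search
  grid <- seq(0, 2 * sum(x), length.out = 200001)
  sse <- vapply(grid, function(e) sum((x - e * a)^2), numeric(1))
  expect_equal(unname(fit$exposures[1, 1]), grid[which.min(sse)],
               tolerance = 1e-3)
  expect_equal(unname(fit$exposures[1, 1]), max(0, sum(a * x) / sum(a^2)),
               tolerance = 1e-8)
})

test_that("rank selection recovers the true rank on separable toys", {
  set.seed(86)
  sig <- block_signatures(2)
  sim <- simulate_catalogue(sig, scenario_config(n_samples = 60), seed = 86)
  sel <- select_rank(sim$catalogue, 1:4, n_runs = 4, resample = FALSE, seed = 5)
  expect_equal(sel$chosen_k, 2L)
  expect_named(sel$diagnostics, c("k", "C_mean", "C_min", "mse"))
  only <- select_rank(sim$catalogue, 3, n_runs = 3, resample = FALSE, seed = 5)
  expect_equal(only$chosen_k, 3L)
  expect_true(only$stable_selection)
})

test_that("scenario evaluation aggregates per-replicate outcomes per the metric definitions", {
  set.seed(87)
  sig <- block_signatures(2)
  reps <- generate_scenario(sig, scenario_config(n_samples = 40,
                                                 mutations_per_sample = 2000,
                                                 n_replicates = 3, seed = 87))
  ev <- evaluate_scenario(reps, k_range = 1:3, threshold = 0.9,
                          n_runs = 4, resample = FALSE, seed = 6)
  expect_equal(ev$F, mean(ev$per_replicate$success))
  expect_true(ev$F %in% ((0:3) / 3))
  expect_equal(ev$mse$median, median(ev$per_replicate$mse))
  expect_equal(ev$mse$q1, quantile(ev$per_replicate$mse, 0.25, names = FALSE))
  expect_gte(ev$mse$median, 0)
  expect_equal(nrow(ev$per_replicate), 3L)
  # separable scenario: the extractor should succeed throughout
  expect_equal(ev$F, 1)
})

test_that("success frequency counts replicates where every signature is identified", {
  set.seed(88)
  sig <- block_signatures(2)
  # constructed outcomes: 3 perfect extractions, 1 with a corrupted signature
  extractions <- c(replicate(3, sig, simplify = FALSE),
                   list(signature_matrix(rbind(unclass(sig)[1, ], runif(96)))))
  successes <- vapply(extractions, function(e) {
    match_to_truth(e, sig, threshold = 0.9)$success
  }, logical(1))
  expect_equal(mean(successes), 0.75)
  expect_identical(successes, c(TRUE, TRUE, TRUE, FALSE))
})
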