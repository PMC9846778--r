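test_that("context schema has 96 unique labels over the six substitution classes", {
  ctx <- sbs96_contexts()
  expect_length(ctx, 96L)
  expect_false(anyDuplicated(ctx) > 0L)
  subs <- unique(substr(ctx, 3L, 5L))
  expect_setequal(subs, c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
})

test_that("signature tables read identically regardless of row order or scale", {
  set.seed(11)
  sig <- signature_matrix(matrix(runif(2 * 96), 2), names = c("toyA", "toyB"))
  canonical <- read_signature_table(write_toy_cosmic(sig))
  scrambled <- read_signature_table(write_toy_cosmic(sig, scramble = TRUE))
  percent <- read_signature_table(write_toy_cosmic(sig, scale = 100))
  expect_equal(unclass(scrambled), unclass(canonical), tolerance = 1e-12)
  expect_equal(unclass(percent), unclass(canonical), tolerance = 1e-12)
  expect_equal(unname(rowSums(canonical)), c(1, 1), tolerance = 1e-8)
  expect_identical(colnames(canonical), sbs96_contexts())
})

test_that("malformed signature tables are rejected", {
  set.seed(12)
  sig <- block_signatures(2)
  df <- data.frame(Type = sbs96_contexts(), t(unclass(sig)), check.names = FALSE)
  p1 <- tempfile(fileext = ".tsv")
  readr::write_tsv(df[-5L, ], p1, progress = FALSE)
  expect_error(read_signature_table(p1), "missing")
  df2 <- df
  df2$Type[2L] <- df2$Type[1L]
  p2 <- tempfile(fileext = ".tsv")
  readr::write_tsv(df2, p2, progress = FALSE)
  expect_error(read_signature_table(p2), "duplicate")
  df3 <- df
  df3[[2L]][1L] <- -0.1
  p3 <- tempfile(fileext = ".tsv")
  readr::write_tsv(df3, p3, progress = FALSE)
  expect_error(read_signature_table(p3), "negative")
})

test_that("artefact filtering drops named signatures and reports unknowns", {
  # synthetic stand-in for the 79-signature reference: real COSMIC names,
  # random profiles
  set.seed(13)
  names79 <- unique(c(
    paste0("SBS", c(1:9, "10a", "10b", "10c", "10d", 11:26, "17a", "17b",
                    28:42, 44, 84:94)),
    cosmic_artefact_signatures()
  ))
  names79 <- c(names79, paste0("SBSx", seq_len(max(0, 79 - length(names79)))))[1:79]
  sig79 <- signature_matrix(matrix(runif(79 * 96), 79), names = names79)
  expect_length(cosmic_artefact_signatures(), 19L)
  kept <- filter_artefact_signatures(sig79)
  expect_equal(nrow(kept), 60L)
  expect_length(intersect(rownames(kept), cosmic_artefact_signatures()), 0L)

  expect_identical(unclass(filter_artefact_signatures(sig79, character(0))),
                   unclass(sig79))
  expect_warning(filter_artefact_signatures(sig79, c("SBS27", "SBS999")),
                 "SBS999")
  expect_error(filter_artefact_signatures(sig79, names79), "every signature")
})

test_that("catalogue write/read round trip is bit exact", {
  set.seed(14)
  sig <- block_signatures(3)
  sim <- simulate_catalogue(sig, scenario_config(n_samples = 1000), seed = 14)
  p <- tempfile(fileext = ".tsv")
  write_catalogue(sim$catalogue, p)
  back <- read_catalogue(p)
  expect_identical(unclass(back), unclass(sim$catalogue))

  zeros <- mut_catalogue(matrix(0L, 96, 1))
  p0 <- tempfile(fileext = ".tsv")
  write_catalogue(zeros, p0)
  expect_identical(unclass(read_catalogue(p0)), unclass(zeros))
})

test_that("non-integer catalogue cells are rejected on read", {
  df <- data.frame(Type = sbs96_contexts(), s1 = runif(96))
  p <- tempfile(fileext = ".tsv")
  readr::write_tsv(df, p, progress = FALSE)
  expect_error(read_catalogue(p), "integer")
})

test_that("signature write/read round trip drifts at most 1e-12", {
  set.seed(15)
  sig <- signature_matrix(matrix(runif(4 * 96), 4),
                          names = paste0("synth_", 1:4))
  p <- tempfile(fileext = ".tsv")
  write_signature_table(sig, p)
  back <- read_signature_table(p)
  expect_lt(max(abs(unclass(back) - unclass(sig))), 1e-12)
})
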