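#' Construct a signature matrix
#'
#' A `signature_matrix` stores mutational-signature profiles as rows of a
#' signatures x 96 matrix: one probability distribution over the 96 SBS
#' contexts per signature. Rows are L1-normalised on construction, because
#' published signature files vary between probabilities and percentages.
#'
#' @param x Numeric matrix (signatures x 96, rows = signatures) or a data
#'   frame in the COSMIC dialect (a context column plus one numeric column
#'   per signature; contexts as rows).
#' @param names Optional signature identifiers; defaults to rownames of `x`.
#' @return A `signature_matrix`: a numeric matrix with class attribute,
#'   rownames = signature names, colnames = canonical SBS-96 contexts, every
#'   row summing to 1.
#' @examples
#' sm <- signature_matrix(matrix(1, 2, 96), names = c("S1", "S2"))
#' rowSums(sm)
#' @export
signature_matrix <- function(x, names = NULL) {
  if (is.data.frame(x)) {
    return(as_signature_matrix(x))
  }
  x <- as.matrix(x)
  if (ncol(x) != 96L) {
    stop("a signature matrix must have 96 columns (one per SBS context), got ", ncol(x))
  }
  if (any(!is.finite(x))) stop("non-finite entries in signature matrix")
  if (any(x < 0)) stop("negative entries in signature matrix")
  if (!is.null(names)) rownames(x) <- names
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x))) stop("signature names must be unique")
  rs <- rowSums(x)
  if (any(rs <= 0)) stop("signature profile(s) sum to zero: ",
                         paste(rownames(x)[rs <= 0], collapse = ", "))
  x <- x / rs
  if (is.null(colnames(x))) {
    colnames(x) <- sbs96_contexts()
  } else {
    perm <- match_sbs96(colnames(x))
    x <- x[, perm, drop = FALSE]
  }
  structure(x, class = c("signature_matrix", "matrix", "array"))
}

#' Coerce a COSMIC-dialect data frame to a signature matrix
#'
#' The first column holds the 96 context labels (any order); the remaining
#' columns hold one profile per signature. Contexts are reordered to the
#' canonical schema and the orientation transposed so signatures become rows.
#'
#' @param df Data frame or tibble in the COSMIC dialect.
#' @return A [signature_matrix()].
#' @export
as_signature_matrix <- function(df) {
  df <- as.data.frame(df)
  if (ncol(df) < 2L) stop("need a context column plus at least one signature column")
  labels <- as.character(df[[1L]])
  perm <- match_sbs96(labels)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("signature columns must be numeric")
  if (any(vals < 0)) stop("negative entries in signature table")
  vals <- vals[perm, , drop = FALSE]   # canonical context order
  m <- t(vals)
  colnames(m) <- sbs96_contexts()
  signature_matrix(m)
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat("<signature_matrix> ", nrow(x), " signatures x 96 contexts\n", sep = "")
  cat("signatures: ", paste(utils::head(rownames(x), 8L), collapse = ", "),
      if (nrow(x) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Tidy a signature matrix into long format
#'
#' @param x A `signature_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `signature`, `context`, `substitution`,
#'   `probability`.
#' @export
tidy.signature_matrix <- function(x, ...) {
  tibble::as_tibble(as.table(unclass(x)), .name_repair = "minimal") |>
    stats::setNames(c("signature", "context", "probability")) |>
    dplyr::mutate(substitution = substr(.data$context, 3L, 5L), .after = "context") |>
    dplyr::arrange(match(.data$signature, rownames(x)), match(.data$context, sbs96_contexts()))
}

#' Construct a mutational catalogue
#'
#' A `mut_catalogue` is a 96 x samples matrix of non-negative integer mutation
#' counts, rows in canonical SBS-96 context order.
#'
#' @param counts Numeric matrix, 96 rows (contexts) x samples; entries must be
#'   non-negative integers.
#' @param sample_ids Optional sample identifiers; defaults to colnames.
#' @return A `mut_catalogue` matrix with class attribute.
#' @export
mut_catalogue <- function(counts, sample_ids = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 96L) stop("a mutational catalogue must have 96 rows, got ", nrow(counts))
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("catalogue counts must be finite and non-negative")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("catalogue counts must be integers")
  }
  storage.mode(counts) <- "integer"
  if (!is.null(sample_ids)) colnames(counts) <- sample_ids
  if (is.null(colnames(counts))) colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  if (is.null(rownames(counts))) {
    rownames(counts) <- sbs96_contexts()
  } else {
    perm <- match_sbs96(rownames(counts))
    counts <- counts[perm, , drop = FALSE]
  }
  structure(counts, class = c("mut_catalogue", "matrix", "array"))
}

#' @export
print.mut_catalogue <- function(x, ...) {
  cat("<mut_catalogue> 96 contexts x ", ncol(x), " samples; total mutations ",
      sum(x), "\n", sep = "")
  invisible(x)
}

#' Tidy a mutational catalogue into long format
#'
#' @param x A `mut_catalogue`.
#' @param ... Unused.
#' @return A tibble with columns `context`, `sample`, `count`.
#' @export
tidy.mut_catalogue <- function(x, ...) {
  tibble::as_tibble(as.table(unclass(x)), .name_repair = "minimal") |>
    stats::setNames(c("context", "sample", "count")) |>
    dplyr::mutate(count = as.integer(.data$count))
}

# strip class for numeric work
as_plain <- function(x) {
  class(x) <- setdiff(class(x), c("signature_matrix", "mut_catalogue"))
  x
}
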