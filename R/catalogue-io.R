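#' Default list of COSMIC artefact signatures
#'
#' SBS signatures flagged "Possible sequencing artefact" in the COSMIC v3.3
#' catalogue. This list (19 names) is reconstructed from the COSMIC website
#' annotations, and is always overridable: pass your own `exclude` vector to
#' [filter_artefact_signatures()].
#'
#' @return Character vector of 19 signature names.
#' @export
cosmic_artefact_signatures <- function() {
  c("SBS27", "SBS43", paste0("SBS", 45:60), "SBS95")
}

#' Read a signature table in the COSMIC TSV dialect
#'
#' Expects a tab-separated file whose first column (conventionally named
#' `Type`) holds the 96 SBS context labels and whose remaining columns hold
#' one signature profile each. Rows may be in any order; they are reordered
#' to the canonical context schema. Profiles are renormalised to sum to 1,
#' so files expressed as percentages or counts read identically to
#' probability files.
#'
#' @param path Path to a TSV file.
#' @param dialect Only `"cosmic_v3"` is supported.
#' @return A [signature_matrix()] with one row per signature column of the file.
#' @export
read_signature_table <- function(path, dialect = "cosmic_v3") {
  dialect <- match.arg(dialect, "cosmic_v3")
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_signature_matrix(df)
}

#' Write a signature matrix in the COSMIC TSV dialect
#'
#' Inverse of [read_signature_table()]: contexts as rows (canonical order),
#' one column per signature.
#'
#' @param sig A [signature_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_table <- function(sig, path) {
  stopifnot(inherits(sig, "signature_matrix"))
  df <- tibble::as_tibble(t(as_plain(sig)))
  df <- dplyr::bind_cols(tibble::tibble(Type = sbs96_contexts()), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Remove artefact signatures from a signature matrix
#'
#' @param sig A [signature_matrix()].
#' @param exclude Character vector of signature names to drop; defaults to
#'   the COSMIC v3.3 artefact list ([cosmic_artefact_signatures()]). Names
#'   absent from `sig` trigger a warning (they are reported, not silently
#'   ignored) and the remaining filter is applied.
#' @return A [signature_matrix()] without the excluded rows, original row
#'   order preserved.
#' @export
filter_artefact_signatures <- function(sig, exclude = cosmic_artefact_signatures()) {
  stopifnot(inherits(sig, "signature_matrix"))
  unknown <- setdiff(exclude, rownames(sig))
  if (length(unknown) > 0L) {
    warning("exclude names not present in signature matrix: ",
            paste(unknown, collapse = ", "))
  }
  keep <- !(rownames(sig) %in% exclude)
  if (!any(keep)) stop("filtering removed every signature")
  signature_matrix(as_plain(sig)[keep, , drop = FALSE])
}

#' Read a mutational catalogue TSV
#'
#' First column holds the 96 context labels, remaining columns one sample
#' each, cells are integer mutation counts.
#'
#' @param path Path to a TSV file.
#' @return A [mut_catalogue()].
#' @export
read_catalogue <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  labels <- as.character(df[[1L]])
  perm <- match_sbs96(labels)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("catalogue cells must be numeric")
  if (any(abs(vals - round(vals)) > 1e-8)) stop("catalogue cells must be integers")
  vals <- vals[perm, , drop = FALSE]
  rownames(vals) <- sbs96_contexts()
  mut_catalogue(vals)
}

#' Write a mutational catalogue TSV
#'
#' @param cat A [mut_catalogue()].
#' @param path Output path.
#' @return `path`, invisibly. A write/read round trip reproduces the counts
#'   bit-exactly.
#' @export
write_catalogue <- function(cat, path) {
  stopifnot(inherits(cat, "mut_catalogue"))
  df <- tibble::as_tibble(as_plain(cat))
  df <- dplyr::bind_cols(tibble::tibble(Type = sbs96_contexts()), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
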