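#' Canonical SBS-96 mutation-context labels
#'
#' Single-base substitutions are classified by the pyrimidine-strand change
#' (C>A, C>G, C>T, T>A, T>C, T>G) together with the 5' and 3' flanking bases,
#' giving 6 x 16 = 96 categories. The canonical order used throughout this
#' package — and the single source of truth for it — is substitution class
#' first, then the 5' flank, then the 3' flank, each alphabetically, matching
#' the ordering used by the COSMIC reference files and SigProfiler tooling.
#'
#' @return Character vector of 96 labels such as `"A[C>A]A"`.
#' @examples
#' head(sbs96_contexts())
#' @export
sbs96_contexts <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(bases, bases, function(p5, p3) paste0(p5, "[", s, "]", p3))))
  }), use.names = FALSE)
}

#' Check a vector of context labels against the SBS-96 schema
#'
#' @param labels Character vector of context labels.
#' @return Invisibly, the integer permutation mapping `labels` to canonical
#'   order. Errors if labels are not exactly the 96 canonical contexts.
#' @keywords internal
match_sbs96 <- function(labels) {
  canon <- sbs96_contexts()
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    stop("duplicate mutation-context labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  idx <- match(canon, labels)
  if (anyNA(idx)) {
    stop("missing mutation-context labels (expected the 96 SBS contexts): ",
         paste(utils::head(canon[is.na(idx)], 5L), collapse = ", "),
         if (sum(is.na(idx)) > 5L) ", ...")
  }
  invisible(idx)
}
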