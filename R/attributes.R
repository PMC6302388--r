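# Binary protein x GO-slim attribute matrix O and the pairwise affinity S.

#' Build the binary attribute matrix
#'
#' Builds the n x m indicator matrix O over the network's proteins:
#' `O[i, j] = 1` iff protein i carries GO slim term j. The network defines
#' the protein universe: annotation rows for proteins absent from the
#' network are dropped, and network proteins without annotation get an
#' all-zero row. Term order is lexicographic.
#'
#' @param net a [ppi_network].
#' @param annotation data frame with columns `protein` and `term`
#'   (as from [read_go_slim()]), already aspect-filtered.
#' @return An object of class `attribute_data` with elements `proteins`,
#'   `terms` and `O`; the affinity matrix `S` is filled by
#'   [build_affinity()].
#' @export
build_attribute_matrix <- function(net, annotation) {
  stopifnot(inherits(net, "ppi_network"),
            all(c("protein", "term") %in% names(annotation)))
  ann <- annotation[annotation$protein %in% net$proteins, , drop = FALSE]
  terms <- sort_ids(ann$term)
  n <- length(net$proteins)
  O <- matrix(0, n, length(terms), dimnames = list(net$proteins, terms))
  if (nrow(ann) > 0L) {
    O[cbind(match(ann$protein, net$proteins), match(ann$term, terms))] <- 1
  }
  structure(list(proteins = net$proteins, terms = terms, O = O, S = NULL),
            class = "attribute_data")
}

#' @export
print.attribute_data <- function(x, ...) {
  cat(sprintf("Attribute data: %d proteins x %d GO slim terms (%d annotated)\n",
              nrow(x$O), ncol(x$O), sum(rowSums(x$O) > 0)))
  invisible(x)
}

#' Fill the attribute affinity matrix
#'
#' Computes the n x n affinity S as the cosine similarity between binary
#' annotation rows:
#' \deqn{s_{ij} = \frac{\sum_k o_{ik} o_{jk}}{\sqrt{\sum_k o_{ik}^2}\sqrt{\sum_k o_{jk}^2}}.}
#' A protein with no annotation has affinity 0 to everything (including
#' itself): a 0/0 cosine carries no evidence. Annotated proteins have
#' `s_ii = 1`, though diagonal terms never enter the embedding loss.
#'
#' @param attr an `attribute_data` from [build_attribute_matrix()].
#' @return The same object with `S` filled (symmetric, entries in `[0, 1]`).
#' @export
build_affinity <- function(attr) {
  stopifnot(inherits(attr, "attribute_data"))
  O <- attr$O
  norms <- sqrt(rowSums(O^2))
  S <- tcrossprod(O)
  denom <- outer(norms, norms)
  S <- ifelse(denom > 0, S / denom, 0)
  dimnames(S) <- list(attr$proteins, attr$proteins)
  attr$S <- S
  attr
}

#' Export the affinity matrix
#'
#' Writes S as a tab-separated table with protein IDs as the first column
#' and as the header, for inspection.
#'
#' @param attr an `attribute_data` with `S` filled.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_affinity <- function(attr, path) {
  stopifnot(inherits(attr, "attribute_data"), !is.null(attr$S))
  df <- data.frame(protein = attr$proteins, attr$S, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
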