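# Collection-level statistics feeding the weighting functions.

#' Corpus statistics for a fingerprint library
#'
#' Computes the collection-level quantities the fragment-weighting functions
#' depend on: the number of compounds m, the document frequency cf_i of each
#' fragment (number of compounds containing it), each compound's size |c_j|,
#' and the average size |c_avg|.  These mirror the document statistics of
#' Okapi/BM25 term weighting, with fragments in the role of terms.
#'
#' @param library An [fp_library()]; must be non-empty.
#' @param size_mode How |c_j| is measured: `"total"` (sum of fragment counts,
#'   the default; the analogue of document length) or `"distinct"` (number of
#'   distinct fragments).
#' @return A `corpus_stats` object with fields `n_compounds`, `doc_freq`
#'   (named integer vector keyed by fragment id), `sizes` (named numeric
#'   vector keyed by compound id), `avg_size`, and `size_mode`.
#' @examples
#' lib <- fp_library(list(A = c(`1` = 2, `2` = 1), B = c(`2` = 3)))
#' corpus_stats(lib)
#' @export
corpus_stats <- function(library, size_mode = c("total", "distinct")) {
  size_mode <- match.arg(size_mode)
  stopifnot(inherits(library, "fp_library"))
  if (length(library) == 0L) stop("library is empty")
  X <- fp_count_matrix(library)
  doc_freq <- Matrix::colSums(X > 0)
  sizes <- if (size_mode == "total") Matrix::rowSums(X) else Matrix::rowSums(X > 0)
  structure(
    list(
      n_compounds = length(library),
      doc_freq = stats::setNames(as.integer(doc_freq), colnames(X)),
      sizes = stats::setNames(as.numeric(sizes), rownames(X)),
      avg_size = mean(sizes),
      size_mode = size_mode
    ),
    class = "corpus_stats"
  )
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat("<corpus_stats | m =", x$n_compounds,
      "|", length(x$doc_freq), "fragments | avg |c| =",
      format(x$avg_size, digits = 4), paste0("(", x$size_mode, ")>"), "\n")
  invisible(x)
}

#' Mean pairwise similarity of a compound set
#'
#' The diversity statistic of an activity class: the arithmetic mean of the
#' continuous Tanimoto coefficient over all unordered pairs of members,
#' computed on raw fragment counts.  Values near 1 indicate a structurally
#' homogeneous class; heterogeneous (diverse) classes score low (on real
#' drug-discovery classes typically around 0.1).
#'
#' @param class_members An [fp_library()] or plain list of fingerprints with
#'   at least two members.
#' @return A number in \[0, 1\].
#' @seealso [tanimoto_continuous()]
#' @export
mean_pairwise_similarity <- function(class_members) {
  if (!inherits(class_members, "fp_library")) {
    class_members <- fp_library(class_members)
  }
  n <- length(class_members)
  if (n < 2L) stop("need at least 2 class members")
  X <- fp_count_matrix(class_members)
  G <- as.matrix(Matrix::tcrossprod(X))          # Gram matrix of raw counts
  sq <- diag(G)
  den <- outer(sq, sq, `+`) - G
  sim <- ifelse(den > 0, G / den, 0)             # both-empty pairs count as 0
  mean(sim[upper.tri(sim)])
}
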