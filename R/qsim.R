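# Quantum probability framework (distributions over an orthonormal fragment
# basis, density operators, projectors) and the two similarity coefficients:
# the SQB projection probability and the continuous Tanimoto benchmark.
#
# The screening path uses only the sparse closed forms; the dense-matrix
# operators exist as the framework definition and as brute-force test
# oracles.

#' Probability distribution over fragments
#'
#' A classical probability distribution over the orthonormal fragment basis
#' of the chemical-information space.  Probabilities must be non-negative
#' and sum to 1 (tolerance 1e-9).
#'
#' @param probs Named numeric vector, names = fragment ids.
#' @return A `fragment_distribution` object.
#' @export
fragment_distribution <- function(probs) {
  if (is.null(names(probs)) || any(names(probs) == "")) {
    stop("probabilities must be named by fragment id")
  }
  if (any(probs < 0)) stop("probabilities must be non-negative")
  if (abs(sum(probs) - 1) > 1e-9) {
    stop("probabilities must sum to 1 (got ", format(sum(probs)), ")")
  }
  structure(as.numeric(probs), names = names(probs), class = "fragment_distribution")
}

#' Probability of a subspace
#'
#' The probability assigned to the subspace spanned by a set of basis
#' fragments: the sum of their individual probabilities.  Fragments outside
#' the distribution's support carry zero mass.
#'
#' @param dist A [fragment_distribution()].
#' @param subspace_fragments Character vector of fragment ids.
#' @return A number in \[0, 1\].
#' @export
subspace_probability <- function(dist, subspace_fragments) {
  stopifnot(inherits(dist, "fragment_distribution"))
  idx <- match(as.character(subspace_fragments), names(dist))
  sum(dist[idx[!is.na(idx)]])
}

#' Density operator of a fragment distribution
#'
#' The mixed-state density operator `D = sum_f pr(f) |f><f|`: in the
#' orthonormal fragment basis, a diagonal matrix with the probabilities on
#' the diagonal.  Always Hermitian, positive semidefinite, and of trace 1.
#'
#' @param dist A [fragment_distribution()].
#' @param basis_order Character vector enumerating the basis; must contain
#'   the distribution's support.
#' @return A complex matrix with `dimnames = list(basis, basis)`.
#' @export
density_from_distribution <- function(dist, basis_order) {
  stopifnot(inherits(dist, "fragment_distribution"))
  basis_order <- as.character(basis_order)
  if (!all(names(dist)[dist > 0] %in% basis_order)) {
    stop("basis_order must contain the distribution's support")
  }
  p <- stats::setNames(numeric(length(basis_order)), basis_order)
  p[names(dist)[names(dist) %in% basis_order]] <-
    dist[names(dist) %in% basis_order]
  D <- diag(as.complex(p), nrow = length(basis_order))
  dimnames(D) <- list(basis_order, basis_order)
  D
}

# Expand a sparse named (complex or numeric) vector into a dense complex
# vector over an explicit basis.
.dense_state <- function(phi, basis_order) {
  basis_order <- as.character(basis_order)
  if (!all(names(phi) %in% basis_order)) {
    stop("basis_order must contain every fragment of the vector")
  }
  v <- stats::setNames(complex(length(basis_order)), basis_order)
  v[names(phi)] <- as.complex(phi)
  v
}

#' Pure-state density operator of a vector
#'
#' The rank-1 density operator `d = |phi><phi|` of the unit-normalised state
#' vector: the outer product of the vector with its conjugate transpose.
#' Hermitian, idempotent, trace 1.
#'
#' @param phi Named complex (or numeric) vector over fragments; must have
#'   non-zero norm.
#' @param basis_order Basis enumeration (contains all fragments of `phi`).
#' @return A complex matrix.
#' @export
pure_density <- function(phi, basis_order) {
  v <- .dense_state(phi, basis_order)
  nrm2 <- sum(Mod(v)^2)
  if (nrm2 == 0) stop("cannot form a pure state from a zero vector")
  v <- v / sqrt(nrm2)
  outer(v, Conj(v))
}

#' Rank-1 projector onto a vector's subspace
#'
#' The projector `P = |phi><phi| / <phi|phi>` onto the one-dimensional
#' subspace spanned by `phi`.  Numerically identical to [pure_density()];
#' both names are kept because the SQB probability uses one object in each
#' role (reference as density, compound as projector).
#'
#' @inheritParams pure_density
#' @return A complex matrix, Hermitian and idempotent.
#' @export
projector_onto <- function(phi, basis_order) {
  pure_density(phi, basis_order)
}

#' Validate a density operator
#'
#' Checks Hermiticity, unit trace, and positive semidefiniteness (all
#' eigenvalues >= -tol).
#'
#' @param D Square complex matrix.
#' @param tol Numerical tolerance (default 1e-9).
#' @return `TRUE` or `FALSE`.
#' @export
is_density_operator <- function(D, tol = 1e-9) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) return(FALSE)
  if (max(Mod(D - Conj(t(D)))) > tol) return(FALSE)
  if (abs(Re(sum(diag(D))) - 1) > tol || abs(Im(sum(diag(D)))) > tol) return(FALSE)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  all(ev >= -tol)
}

#' Validate a projector
#'
#' Checks Hermiticity and idempotence (`P %*% P == P` within tolerance).
#'
#' @param P Square complex matrix.
#' @param tol Numerical tolerance (default 1e-9).
#' @return `TRUE` or `FALSE`.
#' @export
is_projector <- function(P, tol = 1e-9) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) return(FALSE)
  if (max(Mod(P - Conj(t(P)))) > tol) return(FALSE)
  max(Mod(P %*% P - P)) <= tol
}

#' SQB projection probability between two embedded structures
#'
#' The Standard Quantum-Based similarity: the probability obtained by
#' projecting the reference's pure state onto the compound's one-dimensional
#' subspace, `tr(d S)` with `d = |r><r| / <r|r>` and `S = |c><c| / <c|c>`.
#' On sparse vectors this reduces to the closed form
#' `|<r|c>|^2 / (<r|r> <c|c>)`, a value in \[0, 1\] by Cauchy-Schwarz; the
#' dense trace computation is retained only as a test oracle (see
#' [pure_density()] and [projector_onto()]).  The Hermitian inner product
#' conjugates the reference argument; the choice of side does not affect the
#' modulus.
#'
#' If either vector has zero norm the similarity is defined as 0 and a
#' warning is raised, so screening never aborts on empty fingerprints.
#'
#' @param reference,compound Named complex (or numeric) vectors, typically
#'   from [embed_compound()].  Fragments are aligned by name; missing
#'   entries are zero.
#' @return A number in \[0, 1\].
#' @examples
#' r <- c(`1` = 1 + 2i, `2` = 0.5 + 0i)
#' sqb_probability(r, r)  # self-similarity is exactly 1
#' @export
sqb_probability <- function(reference, compound) {
  r <- as.complex(reference)
  cc <- as.complex(compound)
  names(r) <- names(reference)
  names(cc) <- names(compound)
  nr <- sum(Mod(r)^2)
  nc <- sum(Mod(cc)^2)
  if (nr == 0 || nc == 0) {
    warning("zero-norm embedding; SQB probability defined as 0")
    return(0)
  }
  if (is.null(names(r)) || is.null(names(cc))) {
    if (length(r) != length(cc)) stop("unnamed vectors must have equal length")
    inner <- sum(Conj(r) * cc)
  } else {
    shared <- intersect(names(r), names(cc))
    inner <- if (length(shared)) sum(Conj(r[shared]) * cc[shared]) else 0 + 0i
  }
  Mod(inner)^2 / (nr * nc)
}

#' Continuous Tanimoto coefficient
#'
#' The count/continuous generalisation of the Tanimoto (Jaccard) similarity
#' between two non-negative vectors:
#' `sum(x * y) / (sum(x^2) + sum(y^2) - sum(x * y))`.  Equals 1 exactly for
#' identical non-zero vectors, 0 for disjoint supports, and reduces to the
#' binary Tanimoto `|A & B| / |A | B|` on 0/1 vectors.  Two zero vectors
#' yield 0 by convention (with a warning).
#'
#' @param w_k,w_l Non-negative numeric vectors; if named, entries are
#'   aligned by fragment id, otherwise they must have equal length.
#' @return A number in \[0, 1\].
#' @export
tanimoto_continuous <- function(w_k, w_l) {
  x <- as.numeric(w_k)
  y <- as.numeric(w_l)
  if (any(x < 0) || any(y < 0)) stop("inputs must be non-negative")
  if (!is.null(names(w_k)) && !is.null(names(w_l))) {
    shared <- intersect(names(w_k), names(w_l))
    num <- if (length(shared)) sum(x[match(shared, names(w_k))] * y[match(shared, names(w_l))]) else 0
  } else {
    if (length(x) != length(y)) stop("unnamed vectors must have equal length")
    num <- sum(x * y)
  }
  den <- sum(x^2) + sum(y^2) - num
  if (den == 0) {
    warning("both vectors are zero; Tanimoto defined as 0")
    return(0)
  }
  num / den
}
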