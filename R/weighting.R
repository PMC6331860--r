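# Fragment weighting: the Okapi-style global weight carried in the real
# component of the embedding, and the three local/composite weights carried
# in the imaginary component.

#' Global (inverse-frequency) fragment weight
#'
#' The collection-level weight of a fragment,
#' `log((m + 0.5) / cf) / log(m + 1)`, the Okapi-style inverse document
#' frequency normalised to the collection size.  Rare fragments score close
#' to 1, ubiquitous fragments (cf = m) close to 0.  This weight forms the
#' real component of every SQB embedding.
#'
#' @param cf Number of compounds containing the fragment; integer in
#'   \[1, m\].  Vectorised.
#' @param m Total number of compounds in the collection.
#' @return Numeric vector of weights, each in (0, 1\] for valid inputs.
#' @examples
#' global_weight(10, 1000)    # rare-ish fragment, ~0.667
#' global_weight(1000, 1000)  # ubiquitous fragment, ~7e-5
#' @export
global_weight <- function(cf, m) {
  if (any(m < 1)) stop("m must be >= 1")
  if (any(cf < 1) || any(cf > m)) stop("cf must satisfy 1 <= cf <= m")
  log((m + 0.5) / cf) / log(m + 1)
}

#' Local fragment weight (technique 1)
#'
#' The Okapi-style saturating term-frequency weight
#' `ff / (ff + 0.5 + 1.5 * c_j / c_avg)`: increasing in the fragment count
#' `ff`, damped for compounds larger than average.  Always in \[0, 1).
#'
#' @param ff Fragment count in the compound (>= 0).  Vectorised.
#' @param c_j Size of the compound (see [fp_size()]).
#' @param c_avg Average compound size over the collection; must be positive.
#' @return Numeric vector of weights.
#' @export
tech1_weight <- function(ff, c_j, c_avg) {
  if (any(c_avg <= 0)) stop("c_avg must be positive")
  if (any(ff < 0) || any(c_j < 0)) stop("ff and c_j must be non-negative")
  ff / (ff + 0.5 + 1.5 * c_j / c_avg)
}

#' Combined local-global fragment weight (technique 2)
#'
#' The product of the local saturating weight ([tech1_weight()]) and the
#' global inverse-frequency weight ([global_weight()]).
#'
#' @inheritParams tech1_weight
#' @inheritParams global_weight
#' @return Numeric vector of weights.
#' @export
tech2_weight <- function(ff, c_j, c_avg, cf, m) {
  tech1_weight(ff, c_j, c_avg) * global_weight(cf, m)
}

#' Okapi fragment weight relative to a reference (technique 3)
#'
#' Extends [tech2_weight()] with a reference-matching factor
#' `min(ff, ff_ref) / max(ff, ff_ref)`: the weight is largest when the
#' compound carries the fragment with the same multiplicity as the reference
#' structure, and zero for fragments absent from either.  By convention the
#' 0/0 case (fragment absent from both) contributes 0.
#'
#' @inheritParams tech2_weight
#' @param ff_ref Count of the fragment in the reference structure (>= 0).
#' @return Numeric vector of weights.
#' @export
tech3_okapi_weight <- function(ff, ff_ref, c_j, c_avg, cf, m) {
  if (any(ff_ref < 0)) stop("ff_ref must be non-negative")
  hi <- pmax(ff, ff_ref)
  factor <- ifelse(hi > 0, pmin(ff, ff_ref) / hi, 0)
  tech2_weight(ff, c_j, c_avg, cf, m) * factor
}

#' Weighting scheme for SQB embeddings
#'
#' Selects which of the four compound representations the embedding uses.
#' All four place the global weight in the real component; they differ in the
#' imaginary component: `"tech1"` uses the local weight alone, `"tech2"` the
#' local x global product, `"okapi"` additionally the reference-matching
#' min/max factor, and `"real"` sets the imaginary part to zero (the
#' real-Hilbert-space special case).
#'
#' @param technique One of `"tech1"`, `"tech2"`, `"okapi"`, `"real"`.
#' @return A `weight_scheme` object.
#' @export
weight_scheme <- function(technique = c("tech1", "tech2", "okapi", "real")) {
  structure(list(technique = match.arg(technique)), class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("<weight_scheme:", x$technique, ">\n")
  invisible(x)
}

#' Embed a compound as a complex vector
#'
#' Builds the sparse complex-valued representation of a compound used by the
#' SQB similarity: one entry per fragment present in the fingerprint, with
#' real part [global_weight()] and imaginary part given by the scheme's
#' technique.  Under the `"okapi"` scheme the imaginary part depends on the
#' reference structure; embedding the reference against itself yields a
#' min/max factor of 1, so the reference's own entries reduce to the
#' technique-2 weights.
#'
#' @param fp The compound's [count_fingerprint()].
#' @param stats [corpus_stats()] computed over the library containing `fp`
#'   (compound sizes are taken from the fingerprint itself using the stats'
#'   `size_mode`).
#' @param scheme A [weight_scheme()].
#' @param reference Reference [count_fingerprint()]; required for the
#'   `"okapi"` technique, ignored otherwise.
#' @return A named complex vector (names = fragment ids) with attribute
#'   `compound_id`; empty for an empty fingerprint.
#' @export
embed_compound <- function(fp, stats, scheme, reference = NULL) {
  stopifnot(inherits(stats, "corpus_stats"), inherits(scheme, "weight_scheme"))
  if (!inherits(fp, "count_fp")) fp <- count_fingerprint(fp)
  if (length(fp) == 0L) {
    return(structure(complex(0), names = character(0),
                     compound_id = attr(fp, "compound_id")))
  }
  frags <- names(fp)
  cf <- stats$doc_freq[frags]
  if (anyNA(cf)) {
    stop("fragment(s) not covered by corpus statistics: ",
         paste(utils::head(frags[is.na(cf)], 5), collapse = ", "))
  }
  m <- stats$n_compounds
  ff <- as.numeric(fp)
  c_j <- fp_size(fp, stats$size_mode)
  re <- global_weight(cf, m)
  im <- switch(scheme$technique,
    real  = rep(0, length(ff)),
    tech1 = tech1_weight(ff, c_j, stats$avg_size),
    tech2 = tech2_weight(ff, c_j, stats$avg_size, cf, m),
    okapi = {
      if (is.null(reference)) stop("the 'okapi' technique requires a reference fingerprint")
      if (!inherits(reference, "count_fp")) reference <- count_fingerprint(reference)
      ff_ref <- as.numeric(reference)[match(frags, names(reference))]
      ff_ref[is.na(ff_ref)] <- 0
      tech3_okapi_weight(ff, ff_ref, c_j, stats$avg_size, cf, m)
    }
  )
  structure(complex(real = re, imaginary = im), names = frags,
            compound_id = attr(fp, "compound_id"))
}
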