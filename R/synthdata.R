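# Synthetic benchmark generator: fingerprint libraries with activity
# classes of controllable size and intra-class diversity, emulating the
# statistical shape (class sizes, homogeneous vs heterogeneous classes,
# active:decoy ratio) of the public screening benchmarks.

#' Specify a synthetic screening benchmark
#'
#' Each activity class is built around a set of core fragments private to
#' that class (cores of different classes are disjoint): an active draws
#' each core fragment independently with probability `core_prob`, plus
#' background fragments from the whole universe at rate `background_rate`;
#' decoys draw background fragments only.  Every drawn fragment receives a
#' count of `1 + Poisson(count_dispersion)`, so fingerprints are genuinely
#' count-valued.  `core_prob` controls intra-class diversity (mean pairwise
#' Tanimoto): see [calibrate_diversity()].
#'
#' @param classes Data frame with columns `class_id`, `n_actives`,
#'   `core_size`, `core_prob` (one row per activity class).
#' @param n_decoys Number of decoy compounds.
#' @param fragment_universe Number of distinct fragment ids (0-based);
#'   must be at least the sum of core sizes.
#' @param background_rate Per-fragment inclusion probability for the
#'   background draw, in \[0, 1).
#' @param count_dispersion Mean of the Poisson count noise (0 = all counts
#'   are 1).
#' @param seed Integer seed; mandatory, so every benchmark is reproducible.
#' @return A `benchmark_spec` object.
#' @export
benchmark_spec <- function(classes, n_decoys,
                           fragment_universe = 512L,
                           background_rate = 0.02,
                           count_dispersion = 0.5,
                           seed) {
  if (missing(seed)) stop("a seed is mandatory")
  classes <- as.data.frame(classes)
  needed <- c("class_id", "n_actives", "core_size", "core_prob")
  if (!all(needed %in% names(classes))) {
    stop("classes needs columns: ", paste(needed, collapse = ", "))
  }
  if (any(classes$n_actives < 1) || any(classes$core_size < 1)) {
    stop("class sizes must be >= 1")
  }
  if (any(classes$core_prob <= 0 | classes$core_prob > 1)) {
    stop("core_prob must lie in (0, 1]")
  }
  if (anyDuplicated(classes$class_id)) stop("duplicate class_id")
  if (sum(classes$core_size) > fragment_universe) {
    stop("fragment universe too small for requested core sizes (need ",
         sum(classes$core_size), ", have ", fragment_universe, ")")
  }
  if (background_rate < 0 || background_rate >= 1) {
    stop("background_rate must lie in [0, 1)")
  }
  if (count_dispersion < 0) stop("count_dispersion must be >= 0")
  structure(
    list(classes = classes, n_decoys = as.integer(n_decoys),
         fragment_universe = as.integer(fragment_universe),
         background_rate = background_rate,
         count_dispersion = count_dispersion,
         seed = as.integer(seed)),
    class = "benchmark_spec"
  )
}

#' @export
print.benchmark_spec <- function(x, ...) {
  cat("<benchmark_spec |", nrow(x$classes), "classes,",
      sum(x$classes$n_actives), "actives,", x$n_decoys, "decoys,",
      x$fragment_universe, "fragments, seed", x$seed, ">\n")
  invisible(x)
}

# One compound: core picks (prob p over `core` fragments) plus background
# picks (prob rate over the whole universe), counts 1 + Poisson(disp).
.draw_compound <- function(core, p, universe, rate, disp) {
  hit <- core[stats::runif(length(core)) < p]
  bg <- if (rate > 0) which(stats::runif(universe) < rate) - 1L else integer(0)
  frags <- sort(unique(c(hit, setdiff(bg, hit))))
  if (length(frags) == 0L) return(count_fingerprint())
  counts <- 1 + stats::rpois(length(frags), disp)
  count_fingerprint(stats::setNames(counts, frags))
}

#' Generate a synthetic benchmark library
#'
#' Draws the library described by a [benchmark_spec()]: class cores are
#' carved disjointly out of a seeded permutation of the fragment universe,
#' then actives and decoys are sampled compound by compound in a fixed
#' order, so the same spec (including seed) always yields the identical
#' library.
#'
#' @param spec A [benchmark_spec()].
#' @return A list with elements `library` (an [fp_library()]), `labels`
#'   (an [activity_labels()]), and `cores` (the per-class core fragment
#'   ids, for inspection).
#' @export
generate_benchmark <- function(spec) {
  stopifnot(inherits(spec, "benchmark_spec"))
  with_seed(spec$seed, {
    perm <- sample.int(spec$fragment_universe) - 1L
    cores <- list()
    offset <- 0L
    for (k in seq_len(nrow(spec$classes))) {
      cs <- spec$classes$core_size[[k]]
      cores[[spec$classes$class_id[[k]]]] <- sort(perm[(offset + 1L):(offset + cs)])
      offset <- offset + cs
    }
    fps <- list()
    labels <- list()
    for (k in seq_len(nrow(spec$classes))) {
      cid <- spec$classes$class_id[[k]]
      ids <- sprintf("%s_a%03d", cid, seq_len(spec$classes$n_actives[[k]]))
      for (a in seq_along(ids)) {
        fps[[ids[[a]]]] <- .draw_compound(
          cores[[cid]], spec$classes$core_prob[[k]],
          spec$fragment_universe, spec$background_rate, spec$count_dispersion
        )
      }
      labels[[cid]] <- ids
    }
    if (spec$n_decoys > 0) {
      dids <- sprintf("DEC_%05d", seq_len(spec$n_decoys))
      for (d in seq_along(dids)) {
        fps[[dids[[d]]]] <- .draw_compound(
          integer(0), 0, spec$fragment_universe,
          spec$background_rate, spec$count_dispersion
        )
      }
    }
    list(library = fp_library(fps), labels = activity_labels(labels),
         cores = cores)
  })
}

#' Calibrate class diversity to a target mean pairwise Tanimoto
#'
#' Searches `core_prob` by monotone bisection (at most `max_iter`
#' iterations, fixed seed throughout) until the generated class's mean
#' pairwise Tanimoto similarity is within `tol` of the target.  Values
#' around 0.3 emulate a structurally homogeneous activity class, values
#' around 0.1 a heterogeneous one.
#'
#' @param target_mean_tanimoto Target diversity in (0, 1).
#' @param class_shape List with `n_actives` and `core_size`, plus
#'   optionally `class_id`, `fragment_universe`, `background_rate`,
#'   `count_dispersion` (defaults as in [benchmark_spec()]).
#' @param seed Integer seed used for every trial generation.
#' @param tol Acceptable deviation from the target (default 0.02).
#' @param max_iter Bisection iteration cap (default 30).
#' @return A one-row data frame `class_id, n_actives, core_size, core_prob`
#'   ready for [benchmark_spec()], with the achieved diversity in the
#'   `achieved` column.
#' @export
calibrate_diversity <- function(target_mean_tanimoto, class_shape, seed,
                                tol = 0.02, max_iter = 30L) {
  if (!(target_mean_tanimoto > 0 && target_mean_tanimoto < 1)) {
    stop("target must lie in (0, 1)")
  }
  shape <- class_shape
  cid <- shape$class_id %||% "CAL"
  universe <- shape$fragment_universe %||% 512L
  bg <- shape$background_rate %||% 0.02
  disp <- shape$count_dispersion %||% 0.5
  measure <- function(p) {
    spec <- benchmark_spec(
      data.frame(class_id = cid, n_actives = shape$n_actives,
                 core_size = shape$core_size, core_prob = p),
      n_decoys = 0L, fragment_universe = universe,
      background_rate = bg, count_dispersion = disp, seed = seed
    )
    bench <- generate_benchmark(spec)
    mean_pairwise_similarity(fp_library(bench$library[bench$labels[[cid]]]))
  }
  lo <- 1e-3
  hi <- 1
  f_lo <- measure(lo)
  f_hi <- measure(hi)
  if (target_mean_tanimoto > f_hi + tol || target_mean_tanimoto < f_lo - tol) {
    stop("target ", target_mean_tanimoto, " unreachable for this shape; ",
         "achievable range approximately [", format(f_lo, digits = 3), ", ",
         format(f_hi, digits = 3), "]")
  }
  p <- NA_real_
  achieved <- NA_real_
  for (it in seq_len(max_iter)) {
    p <- (lo + hi) / 2
    achieved <- measure(p)
    if (abs(achieved - target_mean_tanimoto) <= tol) break
    if (achieved < target_mean_tanimoto) lo <- p else hi <- p
  }
  if (abs(achieved - target_mean_tanimoto) > tol) {
    stop("bisection did not reach target ", target_mean_tanimoto,
         " within ", max_iter, " iterations (achieved ",
         format(achieved, digits = 3), ")")
  }
  data.frame(class_id = cid, n_actives = shape$n_actives,
             core_size = shape$core_size, core_prob = p, achieved = achieved)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default calibrated benchmark specification
#'
#' The package's reference synthetic benchmark: four activity classes of 40
#' actives each — two homogeneous (diversity calibrated to ~0.30) and two
#' heterogeneous (~0.10) — against 1600 decoys (a 1:40 per-class
#' active:decoy ratio), over a 512-fragment universe with background rate
#' 0.02 and count dispersion 0.5.  Class diversities are calibrated with
#' [calibrate_diversity()] at construction.
#'
#' @param seed Integer seed for both calibration and generation.
#' @param n_actives Actives per class (default 40).
#' @param n_decoys Decoys (default 1600).
#' @return A [benchmark_spec()].
#' @export
default_benchmark_spec <- function(seed, n_actives = 40L, n_decoys = 1600L) {
  shapes <- list(
    list(class_id = "HOM1", core_size = 30L, target = 0.30),
    list(class_id = "HOM2", core_size = 40L, target = 0.30),
    list(class_id = "HET1", core_size = 60L, target = 0.10),
    list(class_id = "HET2", core_size = 80L, target = 0.10)
  )
  rows <- lapply(seq_along(shapes), function(k) {
    s <- shapes[[k]]
    calibrate_diversity(
      s$target,
      list(class_id = s$class_id, n_actives = n_actives,
           core_size = s$core_size),
      seed = seed + k
    )[, c("class_id", "n_actives", "core_size", "core_prob")]
  })
  benchmark_spec(do.call(rbind, rows), n_decoys = n_decoys, seed = seed)
}
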