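# Similarity searching and the evaluation protocol: rank the library against
# a reference, compute recall at percentage cutoffs, aggregate per-class
# recall into tables with mean and best-cell (shaded) summaries.

SCREEN_METHODS <- c("tan", "sqb-real", "sqb-tech1", "sqb-tech2", "sqb-okapi")

# Evaluate with a private RNG stream, leaving the caller's untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Precomputed sparse structures shared by all rankings over one library.
.screen_index <- function(library, stats) {
  X <- fp_count_matrix(library)
  frags <- colnames(X)
  cf <- stats$doc_freq[frags]
  if (anyNA(cf)) stop("corpus statistics do not cover the library's fragments")
  m <- stats$n_compounds
  gw <- global_weight(cf, m)
  sizes <- stats$sizes[rownames(X)]
  if (anyNA(sizes)) stop("corpus statistics do not cover the library's compounds")
  Tx <- methods::as(X, "TsparseMatrix")
  i <- Tx@i + 1L
  j <- Tx@j + 1L
  x <- Tx@x
  tech1x <- x / (x + 0.5 + 1.5 * sizes[i] / stats$avg_size)
  tech2x <- tech1x * gw[j]
  rex <- gw[j]
  sp <- function(vals) {
    Matrix::sparseMatrix(i = i, j = j, x = vals, dims = dim(X),
                         dimnames = dimnames(X))
  }
  ReX <- sp(rex)
  list(
    X = X, ids = rownames(X), frags = frags, m = m, gw = gw,
    sizes = sizes, avg = stats$avg_size,
    i = i, j = j, x = x, sp = sp,
    tech1x = tech1x, tech2x = tech2x,
    ReX = ReX,
    re_norm2 = Matrix::rowSums(ReX^2),
    tan_norm2 = Matrix::rowSums(X^2),
    Im_tech1 = sp(tech1x), Im_tech2 = sp(tech2x),
    im_norm2_tech1 = NULL, im_norm2_tech2 = NULL
  )
}

# Dense per-fragment-column vector for one fingerprint (0 where absent).
.dense_counts <- function(fp, frags) {
  v <- numeric(length(frags))
  idx <- match(names(fp), frags)
  known <- !is.na(idx)
  v[idx[known]] <- as.numeric(fp)[known]
  v
}

# Score every library row against one reference with one method.
.score_all <- function(idx, ref_fp, method, stats) {
  if (method == "tan") {
    xr <- .dense_counts(ref_fp, idx$frags)
    extra <- sum(as.numeric(ref_fp)^2) - sum(xr^2)  # fragments unseen in library
    num <- as.numeric(idx$X %*% xr)
    den <- idx$tan_norm2 + sum(xr^2) + extra - num
    ifelse(den > 0, num / den, 0)
  } else {
    technique <- sub("^sqb-", "", method)
    technique <- if (technique == "okapi") "okapi" else technique
    er <- embed_compound(ref_fp, stats, weight_scheme(technique), reference = ref_fp)
    re_r <- .dense_counts(stats::setNames(Re(er), names(er)), idx$frags)
    im_r <- .dense_counts(stats::setNames(Im(er), names(er)), idx$frags)
    rnorm2 <- sum(re_r^2) + sum(im_r^2)
    ImM <- switch(technique,
      real = NULL,
      tech1 = idx$Im_tech1,
      tech2 = idx$Im_tech2,
      okapi = {
        ffr <- .dense_counts(ref_fp, idx$frags)[idx$j]
        hi <- pmax(idx$x, ffr)
        idx$sp(idx$tech2x * ifelse(hi > 0, pmin(idx$x, ffr) / hi, 0))
      }
    )
    if (is.null(ImM)) {
      inner_re <- as.numeric(idx$ReX %*% re_r)
      inner_im <- as.numeric(-(idx$ReX %*% im_r))
      cnorm2 <- idx$re_norm2
    } else {
      inner_re <- as.numeric(idx$ReX %*% re_r + ImM %*% im_r)
      inner_im <- as.numeric(ImM %*% re_r - idx$ReX %*% im_r)
      cnorm2 <- idx$re_norm2 + Matrix::rowSums(ImM^2)
    }
    den <- cnorm2 * rnorm2
    ifelse(den > 0, (inner_re^2 + inner_im^2) / den, 0)
  }
}

#' Rank a library against a reference structure
#'
#' Scores every library compound against the reference with the chosen
#' similarity method and returns them sorted by descending score.  The
#' reference itself, when it is a library member, is removed from the
#' candidates.  Ties are broken by ascending compound id so rankings are
#' machine-independent.
#'
#' Methods: `"tan"` (continuous Tanimoto on raw counts) or the four SQB
#' variants `"sqb-real"`, `"sqb-tech1"`, `"sqb-tech2"`, `"sqb-okapi"`
#' (complex embedding + projection probability; the okapi variant re-embeds
#' every candidate against the reference).
#'
#' @param reference A compound id present in `library`, or an external
#'   [count_fingerprint()] whose fragments are covered by `stats`.
#' @param library An [fp_library()].
#' @param stats [corpus_stats()] for `library`; computed on the fly when
#'   omitted.
#' @param method One of `"tan"`, `"sqb-real"`, `"sqb-tech1"`, `"sqb-tech2"`,
#'   `"sqb-okapi"`.
#' @return A `ranked_list`: a data frame with columns `compound_id`, `score`
#'   (non-increasing), and attributes `reference_id` and `method`.
#' @export
rank_library <- function(reference, library, stats = NULL,
                         method = SCREEN_METHODS) {
  method <- match.arg(method)
  stopifnot(inherits(library, "fp_library"))
  if (is.null(stats)) stats <- corpus_stats(library)
  idx <- .screen_index(library, stats)
  .rank_with_index(reference, library, stats, idx, method)
}

.rank_with_index <- function(reference, library, stats, idx, method,
                             warn_empty = TRUE) {
  if (is.character(reference) && length(reference) == 1L) {
    if (!reference %in% names(library)) {
      stop("reference '", reference, "' is not in the library")
    }
    ref_id <- reference
    ref_fp <- library[[reference]]
  } else {
    if (!inherits(reference, "count_fp")) reference <- count_fingerprint(reference)
    ref_fp <- reference
    ref_id <- attr(reference, "compound_id")
  }
  scores <- .score_all(idx, ref_fp, method, stats)
  n_empty <- sum(idx$tan_norm2 == 0)
  if (warn_empty && n_empty > 0) {
    warning(n_empty, " empty fingerprint(s) scored 0 by convention")
  }
  keep <- if (!is.null(ref_id) && ref_id %in% idx$ids) idx$ids != ref_id else rep(TRUE, length(idx$ids))
  ids <- idx$ids[keep]
  scores <- scores[keep]
  ord <- order(-scores, ids, method = "radix")
  structure(
    data.frame(compound_id = ids[ord], score = scores[ord],
               row.names = NULL, stringsAsFactors = FALSE),
    reference_id = ref_id, method = method,
    class = c("ranked_list", "data.frame")
  )
}

#' Recall within the top fraction of a ranking
#'
#' The percentage of a class's active compounds retrieved in the top
#' `fraction` of the ranked library.  The cutoff is
#' `round(fraction * N)` positions (half away from zero), with a floor of
#' one position.  The reference structure must not be counted among the
#' actives; if present it is removed from the recall denominator.
#'
#' @param ranked A `ranked_list` from [rank_library()].
#' @param actives Character vector of active compound ids.
#' @param fraction Cutoff fraction in (0, 1), e.g. `0.01` for top 1%.
#' @return Recall as a percentage in \[0, 100\].
#' @export
recall_at <- function(ranked, actives, fraction) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  actives <- setdiff(as.character(actives), attr(ranked, "reference_id"))
  if (length(actives) == 0L) stop("no actives to retrieve (empty after removing the reference)")
  n_top <- max(1L, as.integer(floor(fraction * nrow(ranked) + 0.5)))
  hits <- sum(ranked$compound_id[seq_len(min(n_top, nrow(ranked)))] %in% actives)
  100 * hits / length(actives)
}

#' Run the full screening evaluation protocol
#'
#' For every activity class, draws `references_per_class` reference
#' structures at random (seeded; the *same* references are used for every
#' method), ranks the library against each reference with each method, and
#' records the mean recall over references at each cutoff fraction.  Results
#' are aggregated per cutoff into a class-by-method recall table with its
#' mean row and shaded-cell (row-best) counts.
#'
#' @param library An [fp_library()].
#' @param labels [activity_labels()]; every class must have more than
#'   `references_per_class` members.
#' @param references_per_class Number of query structures per class
#'   (default 10).
#' @param methods Similarity methods to compare (default: all five).
#' @param fractions Cutoff fractions (default top 1% and top 5%).
#' @param seed Integer seed for the reference draw; runs with the same seed
#'   are bit-reproducible.
#' @param size_mode Compound-size convention for the corpus statistics.
#' @return A named list of `screening_result` objects, one per fraction
#'   (names like `"top1pct"`), each with fields `cutoff_fraction`, `table`
#'   (class x method matrix of recall percentages), `mean_row`,
#'   `shaded_cells`, and `references`.
#' @export
evaluate_screening <- function(library, labels,
                               references_per_class = 10L,
                               methods = SCREEN_METHODS,
                               fractions = c(0.01, 0.05),
                               seed,
                               size_mode = c("total", "distinct")) {
  size_mode <- match.arg(size_mode)
  stopifnot(inherits(library, "fp_library"))
  if (!inherits(labels, "activity_labels")) labels <- activity_labels(labels)
  methods <- match.arg(methods, SCREEN_METHODS, several.ok = TRUE)
  if (missing(seed)) stop("a seed is required for the reference draw")
  too_small <- names(labels)[lengths(labels) <= references_per_class]
  if (length(too_small)) {
    stop("class too small for ", references_per_class, " references: ",
         paste(too_small, collapse = ", "))
  }
  missing_ids <- setdiff(unlist(labels, use.names = FALSE), names(library))
  if (length(missing_ids)) {
    stop("class members absent from library: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }

  stats <- corpus_stats(library, size_mode)
  idx <- .screen_index(library, stats)
  n_empty <- sum(idx$tan_norm2 == 0)
  if (n_empty > 0) {
    message(n_empty, " empty fingerprint(s) in the library will score 0 by convention")
  }

  refs <- with_seed(seed, lapply(labels, function(members) {
    sort(sample(members, references_per_class))
  }))

  tabs <- lapply(fractions, function(f) {
    matrix(NA_real_, nrow = length(labels), ncol = length(methods),
           dimnames = list(names(labels), methods))
  })
  names(tabs) <- .fraction_label(fractions)

  for (cls in names(labels)) {
    actives <- labels[[cls]]
    for (meth in methods) {
      rec <- matrix(NA_real_, nrow = length(refs[[cls]]), ncol = length(fractions))
      for (r in seq_along(refs[[cls]])) {
        ranked <- .rank_with_index(refs[[cls]][[r]], library, stats, idx, meth,
                                   warn_empty = FALSE)
        rec[r, ] <- vapply(fractions, function(f) recall_at(ranked, actives, f),
                           numeric(1))
      }
      for (k in seq_along(fractions)) tabs[[k]][cls, meth] <- mean(rec[, k])
    }
  }

  out <- lapply(seq_along(fractions), function(k) {
    s <- summarize_table(tabs[[k]])
    structure(
      list(cutoff_fraction = fractions[[k]], table = tabs[[k]],
           mean_row = s$mean_row, shaded_cells = s$shaded_cells,
           references = refs),
      class = "screening_result"
    )
  })
  names(out) <- .fraction_label(fractions)
  out
}

.fraction_label <- function(fractions) {
  paste0("top", sub("\\.?0+$", "", formatC(100 * fractions, format = "fg")), "pct")
}

#' Summarise a recall table
#'
#' Given a complete class-by-method recall matrix (percentages), computes
#' the per-method mean over classes (the table's Mean row) and the
#' shaded-cell counts: for each class row, every method attaining the row
#' maximum (ties included) receives one shaded cell.
#'
#' @param recall_table Numeric matrix, rows = activity classes, columns =
#'   methods, values in \[0, 100\]; no missing cells.
#' @return A list with `mean_row` (named numeric) and `shaded_cells` (named
#'   integer).
#' @export
summarize_table <- function(recall_table) {
  if (!is.matrix(recall_table) || !is.numeric(recall_table)) {
    stop("recall_table must be a numeric matrix")
  }
  if (anyNA(recall_table)) stop("recall_table has missing cells")
  if (any(recall_table < 0 | recall_table > 100)) {
    stop("recall values must lie in [0, 100]")
  }
  if (is.null(colnames(recall_table))) {
    colnames(recall_table) <- paste0("method", seq_len(ncol(recall_table)))
  }
  row_max <- apply(recall_table, 1, max)
  shaded <- colSums(recall_table >= row_max - 1e-9)
  list(
    mean_row = colMeans(recall_table),
    shaded_cells = stats::setNames(as.integer(shaded), colnames(recall_table))
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat("Screening evaluation, top ", 100 * x$cutoff_fraction, "% cutoff\n\n", sep = "")
  tab <- rbind(x$table, Mean = x$mean_row, `Shaded cells` = x$shaded_cells)
  print(round(tab, 2))
  invisible(x)
}

#' Convert a screening result to the tabular CSV layout
#'
#' Rows are activity classes followed by `Mean` and `Shaded cells` summary
#' rows; columns are the methods.
#'
#' @param x A `screening_result`.
#' @param ... Unused.
#' @return A data frame with a leading `class_id` column.
#' @export
as.data.frame.screening_result <- function(x, ...) {
  tab <- rbind(x$table, Mean = x$mean_row, `Shaded cells` = x$shaded_cells)
  data.frame(class_id = rownames(tab), tab, row.names = NULL, check.names = FALSE)
}
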