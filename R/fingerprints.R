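# Sparse count fingerprints and their file formats.
#
# A fingerprint is a named numeric vector: names are fragment identifiers
# (non-negative integers, stored as character), values are occurrence counts
# (>= 1).  Zero counts are never stored.  A library is a named list of such
# vectors keyed by compound id.

#' Construct a count fingerprint
#'
#' A count fingerprint is the sparse fragment-to-count map of one compound:
#' each key is a non-negative integer fragment identifier (for example a
#' folded ECFC_4 bit position) and each value is the number of times that
#' fragment occurs in the compound.  Zero counts are absent by construction;
#' an empty fingerprint (no fragments at all) is legal and represents a
#' compound with no perceived features.
#'
#' @param counts Named numeric vector of positive integer counts; names are
#'   non-negative integer fragment ids.  May be empty.
#' @param compound_id Optional compound identifier attached as an attribute.
#' @return A `count_fp` object: the counts sorted by fragment id.
#' @examples
#' count_fingerprint(c(`7` = 2, `19` = 1), compound_id = "C1")
#' @export
count_fingerprint <- function(counts = numeric(0), compound_id = NULL) {
  if (length(counts) == 0L) {
    counts <- numeric(0)
    names(counts) <- character(0)
  } else {
    if (is.null(names(counts)) || anyNA(names(counts)) || any(names(counts) == "")) {
      stop("fingerprint counts must be named by fragment id")
    }
    frag <- suppressWarnings(as.numeric(names(counts)))
    if (anyNA(frag) || any(frag < 0) || any(frag != trunc(frag))) {
      stop("fragment ids must be non-negative integers")
    }
    if (anyDuplicated(names(counts))) {
      stop("duplicate fragment id in fingerprint")
    }
    if (anyNA(counts) || any(counts < 1) || any(counts != trunc(counts))) {
      stop("stored counts must be positive integers (zero counts are absent, not stored)")
    }
    counts <- as.numeric(counts)[order(frag)]
    names(counts) <- as.character(sort(frag))
  }
  structure(counts, class = "count_fp", compound_id = compound_id)
}

#' @export
print.count_fp <- function(x, ...) {
  id <- attr(x, "compound_id")
  cat("<count_fp", if (!is.null(id)) paste0("'", id, "'"), "|",
      length(x), "fragments, size", fp_size(x), ">\n")
  if (length(x)) print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Fingerprint size
#'
#' The size |c| of a compound used by the Okapi-style length normalisation:
#' either the total number of fragment occurrences (sum of counts, the
#' default, matching document length in text retrieval) or the number of
#' distinct fragments.
#'
#' @param fp A [count_fingerprint()].
#' @param mode `"total"` (sum of counts) or `"distinct"` (number of keys).
#' @return A single number.
#' @export
fp_size <- function(fp, mode = c("total", "distinct")) {
  mode <- match.arg(mode)
  if (mode == "total") sum(fp) else length(fp)
}

#' Construct a fingerprint library
#'
#' @param fps Named list of fingerprints (anything [count_fingerprint()]
#'   accepts); names are compound ids.  Alternatively an unnamed list of
#'   `count_fp` objects carrying `compound_id` attributes.
#' @return An `fp_library`: a named list of `count_fp` objects.
#' @export
fp_library <- function(fps) {
  if (!is.list(fps)) stop("fps must be a list")
  ids <- names(fps)
  if (is.null(ids)) {
    ids <- vapply(fps, function(f) {
      id <- attr(f, "compound_id")
      if (is.null(id)) NA_character_ else as.character(id)
    }, character(1))
  }
  if (anyNA(ids) || any(ids == "")) stop("every fingerprint needs a compound id")
  if (anyDuplicated(ids)) {
    stop("duplicate compound_id: ", ids[anyDuplicated(ids)])
  }
  out <- lapply(seq_along(fps), function(i) {
    f <- fps[[i]]
    if (inherits(f, "count_fp")) {
      attr(f, "compound_id") <- ids[[i]]
      f
    } else {
      count_fingerprint(f, compound_id = ids[[i]])
    }
  })
  names(out) <- ids
  structure(out, class = "fp_library")
}

#' @export
print.fp_library <- function(x, ...) {
  nf <- length(unique(unlist(lapply(x, names), use.names = FALSE)))
  cat("<fp_library |", length(x), "compounds,", nf, "distinct fragments>\n")
  invisible(x)
}

#' Read a fingerprint library from disk
#'
#' Two plain-text dialects are supported.  The primary `"tsv"` format has one
#' compound per line, `compound_id<TAB>frag:count<TAB>frag:count...`; blank
#' lines and lines starting with `#` are ignored.  The secondary `"csv"`
#' format is a dense table with header `compound_id,f0,f1,...` whose zero
#' entries are dropped on load.
#'
#' Malformed lines are reported with their line number.  Duplicate compound
#' ids, duplicate fragment keys within one record, and non-positive stored
#' counts are all rejected rather than silently repaired.
#'
#' @param path File to read.
#' @param format `"tsv"` or `"csv"`.
#' @return An [fp_library()].
#' @seealso [write_fingerprints()]
#' @export
read_fingerprints <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") .read_fp_tsv(path) else .read_fp_csv(path)
}

.read_fp_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  fps <- vector("list", length(keep))
  ids <- character(length(keep))
  for (k in seq_along(keep)) {
    ln <- keep[[k]]
    fields <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 1L || fields[[1]] == "") {
      stop("line ", ln, ": missing compound_id")
    }
    ids[[k]] <- fields[[1]]
    pairs <- fields[-1]
    pairs <- pairs[pairs != ""]
    if (length(pairs)) {
      ok <- grepl("^[0-9]+:-?[0-9]+$", pairs)
      if (!all(ok)) {
        stop("line ", ln, ": malformed frag:count token '", pairs[!ok][1], "'")
      }
      mat <- do.call(rbind, strsplit(pairs, ":", fixed = TRUE))
      frag <- mat[, 1]
      cnt <- as.numeric(mat[, 2])
      if (anyDuplicated(as.numeric(frag))) {
        stop("line ", ln, ": duplicate fragment key")
      }
      if (any(cnt <= 0)) {
        stop("line ", ln, ": count must be >= 1 (got ", min(cnt), ")")
      }
      fps[[k]] <- tryCatch(count_fingerprint(stats::setNames(cnt, frag)),
                           error = function(e) stop("line ", ln, ": ", conditionMessage(e)))
    } else {
      fps[[k]] <- count_fingerprint()
    }
  }
  if (anyDuplicated(ids)) stop("duplicate compound_id: ", ids[anyDuplicated(ids)])
  names(fps) <- ids
  fp_library(fps)
}

.read_fp_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 1L || names(df)[[1]] != "compound_id") {
    stop("dense CSV must start with a 'compound_id' column")
  }
  fragcols <- names(df)[-1]
  frag <- sub("^f", "", fragcols)
  if (!all(grepl("^[0-9]+$", frag))) {
    stop("dense CSV fragment columns must be named f<integer>")
  }
  fps <- lapply(seq_len(nrow(df)), function(i) {
    v <- suppressWarnings(as.numeric(df[i, -1]))
    if (anyNA(v)) stop("row ", i, ": non-numeric count")
    keep <- v != 0
    count_fingerprint(stats::setNames(v[keep], frag[keep]))
  })
  names(fps) <- df$compound_id
  if (anyDuplicated(names(fps))) {
    stop("duplicate compound_id: ", names(fps)[anyDuplicated(names(fps))])
  }
  fp_library(fps)
}

#' Write a fingerprint library to disk
#'
#' Inverse of [read_fingerprints()]; a library round-trips losslessly through
#' either dialect.
#'
#' @param library An [fp_library()].
#' @param path Output file.
#' @param format `"tsv"` (sparse, the default) or `"csv"` (dense).
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(library, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(library, "fp_library"))
  if (format == "tsv") {
    lines <- vapply(names(library), function(id) {
      fp <- library[[id]]
      pairs <- if (length(fp)) paste0(names(fp), ":", as.numeric(fp)) else character(0)
      paste(c(id, pairs), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
  } else {
    frags <- sort(unique(as.numeric(unlist(lapply(library, names), use.names = FALSE))))
    mat <- matrix(0, nrow = length(library), ncol = length(frags),
                  dimnames = list(NULL, paste0("f", frags)))
    for (i in seq_along(library)) {
      fp <- library[[i]]
      if (length(fp)) mat[i, paste0("f", names(fp))] <- as.numeric(fp)
    }
    df <- data.frame(compound_id = names(library), mat, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read activity-class labels
#'
#' Expects a CSV with columns `class_id,compound_id`, one active per row.
#' Compounds not listed under any class are treated as decoys/inactives by
#' the screening evaluation.
#'
#' @param path CSV file.
#' @return An `activity_labels` object: a named list mapping class id to a
#'   character vector of member compound ids.
#' @export
read_activity_labels <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("class_id", "compound_id") %in% names(df))) {
    stop("labels CSV needs 'class_id' and 'compound_id' columns")
  }
  activity_labels(split(df$compound_id, df$class_id))
}

#' Construct activity-class labels
#'
#' @param classes Named list: class id to character vector of active
#'   compound ids.
#' @param library Optional [fp_library()]; if given, membership is checked
#'   against it.
#' @return An `activity_labels` object.
#' @export
activity_labels <- function(classes, library = NULL) {
  if (!is.list(classes) || is.null(names(classes)) || any(names(classes) == "")) {
    stop("classes must be a named list of compound id vectors")
  }
  classes <- lapply(classes, function(m) {
    m <- as.character(m)
    if (anyDuplicated(m)) stop("duplicate compound_id within a class")
    m
  })
  if (!is.null(library)) {
    missing <- setdiff(unlist(classes, use.names = FALSE), names(library))
    if (length(missing)) {
      stop("class members absent from library: ", paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  structure(classes, class = "activity_labels")
}

#' Write activity labels as CSV
#'
#' @param labels An [activity_labels()] object.
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_activity_labels <- function(labels, path) {
  df <- data.frame(
    class_id = rep(names(labels), lengths(labels)),
    compound_id = unlist(labels, use.names = FALSE)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Compounds x fragments sparse count matrix for a library; fragment columns
# sorted numerically.  The workhorse behind corpus statistics and screening.
fp_count_matrix <- function(library) {
  stopifnot(inherits(library, "fp_library"))
  frags <- sort(unique(as.numeric(unlist(lapply(library, names), use.names = FALSE))))
  fragkey <- as.character(frags)
  nnz <- lengths(library)
  i <- rep.int(seq_along(library), nnz)
  j <- match(unlist(lapply(library, names), use.names = FALSE), fragkey)
  x <- as.numeric(unlist(library, use.names = FALSE))
  Matrix::sparseMatrix(
    i = i, j = j, x = x,
    dims = c(length(library), length(frags)),
    dimnames = list(names(library), fragkey)
  )
}
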