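# Published benchmark recall tables shipped with the package.

#' Published benchmark recall tables
#'
#' Per-class recall tables (percentages) from published screening
#' evaluations of the five similarity methods (SQB complex techniques 1-3,
#' SQB real, and continuous Tanimoto) on the MDDR DS1-DS3, MUV, and DUD
#' reference collections, at the top-1% and top-5% cutoffs.  They are
#' distributed as ready-made inputs for the aggregation
#' ([summarize_table()]) and concordance ([kendall_w()]) tools, so the
#' package's summary statistics can be checked against an external
#' evaluation without access to the (partly commercial) compound
#' collections themselves.
#'
#' @param dataset One of `"mddr_ds1"`, `"mddr_ds2"`, `"mddr_ds3"`, `"muv"`,
#'   `"dud"`.
#' @param cutoff `0.01` or `0.05`.
#' @return A numeric matrix, rows = activity classes, columns = the method
#'   tokens `sqb_tech1`, `sqb_tech2`, `sqb_tech3`, `sqb_real`, `tan`.
#' @examples
#' tab <- published_recall_table("mddr_ds2", 0.01)
#' kendall_w(tab)
#' @export
published_recall_table <- function(dataset = c("mddr_ds1", "mddr_ds2",
                                               "mddr_ds3", "muv", "dud"),
                                   cutoff = 0.01) {
  dataset <- match.arg(dataset)
  if (!cutoff %in% c(0.01, 0.05)) stop("cutoff must be 0.01 or 0.05")
  file <- sprintf("recall_%s_top%d.csv", dataset, as.integer(100 * cutoff))
  path <- system.file("extdata", file, package = "sqbvs", mustWork = TRUE)
  df <- utils::read.csv(path, colClasses = c(class_id = "character"))
  m <- as.matrix(df[, -1])
  rownames(m) <- df$class_id
  m
}

#' Display labels for the similarity method tokens
#'
#' Maps the package's method tokens to the conventional display names used
#' in the published evaluation tables (e.g. `sqb_tech3` to `"SQB(C./T3)"`).
#'
#' @return A named character vector.
#' @export
method_display_labels <- function() {
  c(sqb_tech1 = "SQB(C./T1)", sqb_tech2 = "SQB(C./T2)",
    sqb_tech3 = "SQB(C./T3)", sqb_real = "SQB(R.)", tan = "TAN",
    `sqb-tech1` = "SQB(C./T1)", `sqb-tech2` = "SQB(C./T2)",
    `sqb-okapi` = "SQB(C./T3)", `sqb-real` = "SQB(R.)")
}
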