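# Kendall coefficient of concordance over recall tables: each activity
# class acts as a judge ranking the similarity methods.

#' Kendall coefficient of concordance (W) with tie correction
#'
#' Treats each row of the score matrix as a rater ranking the columns
#' (objects); higher scores receive better (smaller) ranks, with midranks
#' for ties.  The tie-corrected coefficient is
#' \deqn{W = \frac{12 \sum_j R_j^2 - 3 m^2 n (n+1)^2}
#'            {m^2 (n^3 - n) - m \sum_i T_i}}
#' where \eqn{R_j} are the column rank sums and
#' \eqn{T_i = \sum (t^3 - t)} over the tie groups of rater \eqn{i}.
#' Significance uses the chi-square approximation
#' \eqn{\chi^2 = m (n - 1) W} on \eqn{n - 1} degrees of freedom.  With no
#' ties the formula reduces to the classical \eqn{12 S / (m^2 (n^3 - n))}
#' form.
#'
#' An overall ranking string of the objects (best first, ascending rank
#' sum, exact ties joined with `"="`) accompanies the statistics.
#'
#' @param score_matrix Numeric matrix, rows = raters (m >= 2), columns =
#'   objects (n >= 2), no missing cells.  Column names label the objects.
#' @return A `concordance_result` with fields `W`, `chi2`, `df`, `p`,
#'   `rank_sums`, and `ranking`.
#' @examples
#' # three judges in perfect agreement
#' m <- matrix(c(3, 2, 1, 30, 20, 10, 9, 5, 1), nrow = 3, byrow = TRUE,
#'             dimnames = list(NULL, c("A", "B", "C")))
#' kendall_w(m)$W  # 1
#' @export
kendall_w <- function(score_matrix) {
  if (!is.matrix(score_matrix) || !is.numeric(score_matrix)) {
    stop("score_matrix must be a numeric matrix")
  }
  if (anyNA(score_matrix)) stop("score_matrix has missing cells")
  m <- nrow(score_matrix)
  n <- ncol(score_matrix)
  if (m < 2L || n < 2L) stop("need at least 2 raters and 2 objects")
  if (is.null(colnames(score_matrix))) {
    colnames(score_matrix) <- paste0("obj", seq_len(n))
  }
  R <- t(apply(score_matrix, 1L, function(row) rank(-row)))  # 1 = best, midranks
  rank_sums <- colSums(R)
  tie_sum <- sum(apply(R, 1L, function(r) {
    t <- table(r)
    sum(t^3 - t)
  }))
  denom <- m^2 * (n^3 - n) - m * tie_sum
  if (denom <= 0) stop("all raters are fully tied; W is undefined")
  W <- (12 * sum(rank_sums^2) - 3 * m^2 * n * (n + 1)^2) / denom
  chi2 <- m * (n - 1) * W
  structure(
    list(
      W = W,
      chi2 = chi2,
      df = n - 1L,
      p = stats::pchisq(chi2, df = n - 1, lower.tail = FALSE),
      rank_sums = stats::setNames(rank_sums, colnames(score_matrix)),
      ranking = ranking_string(stats::setNames(rank_sums, colnames(score_matrix)))
    ),
    class = "concordance_result"
  )
}

#' Overall ranking string from rank sums
#'
#' Orders objects by ascending rank sum (best first) and joins them with
#' `" > "`, using `" = "` between objects whose rank sums are exactly equal.
#' Objects with tied sums keep their input order.
#'
#' @param rank_sums Named numeric vector of rank sums.
#' @return A single string, e.g. `"A = B > C"`.
#' @export
ranking_string <- function(rank_sums) {
  if (length(rank_sums) == 0L) stop("rank_sums is empty")
  if (is.null(names(rank_sums))) stop("rank_sums must be named")
  ord <- order(rank_sums)  # stable: ties keep input order
  s <- rank_sums[ord]
  nm <- names(s)
  if (length(s) == 1L) return(nm)
  sep <- ifelse(s[-1] == s[-length(s)], " = ", " > ")
  paste0(nm[1], paste0(sep, nm[-1], collapse = ""))
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("Kendall W = ", format(x$W, digits = 3),
      ", chi-square = ", format(x$chi2, digits = 4),
      " (df = ", x$df, "), p = ", format.pval(x$p, digits = 2), "\n",
      "Ranking: ", x$ranking, "\n", sep = "")
  invisible(x)
}
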