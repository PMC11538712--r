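#' Convert counts to relative abundance
#'
#' Divides every sample column by its total so columns sum to 1. Guards
#' against double normalisation: proportions-scale input is rejected.
#'
#' @param table A counts-scale [cohort_table()] with positive column sums.
#' @return A proportions-scale [cohort_table()].
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  if (table$scale == "proportions")
    abort("input is already proportions scale (double normalization guard)")
  cs <- colSums(table$counts)
  if (any(cs == 0))
    abort(sprintf("zero-sum sample column(s): %s",
                  paste(colnames(table$counts)[cs == 0], collapse = ", ")))
  out <- table
  out$counts <- sweep(table$counts, 2, cs, "/")
  out$scale <- "proportions"
  out
}

#' Centered log-ratio transform
#'
#' Per sample column: `log(x + pseudocount) - mean(log(x + pseudocount))`, so
#' every transformed column sums to zero. The pseudocount (default 1 count)
#' handles zeros and is recorded on the result.
#'
#' @param table A counts-scale [cohort_table()].
#' @param pseudocount Non-negative value added to every entry before logging;
#'   must be positive if any count is zero.
#' @return A `clr_matrix`: the transformed species x samples matrix with a
#'   `pseudocount` attribute.
#' @export
clr_transform <- function(table, pseudocount = 1) {
  stopifnot(inherits(table, "cohort_table"))
  if (table$scale != "counts") abort("clr_transform expects counts-scale input")
  if (pseudocount <= 0 && any(table$counts == 0))
    abort("pseudocount <= 0 with zero counts present")
  lx <- log(table$counts + pseudocount)
  vals <- sweep(lx, 2, colMeans(lx), "-")
  structure(vals, pseudocount = pseudocount, class = c("clr_matrix", class(vals)))
}
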