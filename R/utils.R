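#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn
#' @importFrom stats p.adjust var sd cor cor.test wilcox.test fisher.test lm
#'   pnorm pt rnorm runif rgamma rmultinom quantile hclust cutree dist as.dist
#'   coef predict complete.cases setNames as.formula vcov rbinom median
#' @importFrom utils head modifyList
NULL

# log to stderr with a level prefix; level gates nothing (filtering is the
# caller's concern, the contract is just the prefixed line on stderr)
ibs_log <- function(level = c("INFO", "WARN", "ERROR"), ...) {
  level <- match.arg(level)
  message(sprintf("[%s] %s", level, paste0(...)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment for one family of tests. Thin,
#' argument-checked wrapper around [stats::p.adjust()] so every multiple-testing
#' family in the pipeline (meta-analysis, network edges, diet grid, per-cohort
#' functional tests) goes through one audited entry point.
#'
#' @param p Numeric vector of p-values, all in `[0, 1]` (`NA` allowed and
#'   returned as `NA`).
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric")
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    abort(sprintf("p-values outside [0, 1]: %s",
                  paste(signif(p[bad], 4), collapse = ", ")))
  }
  p.adjust(p, method = "BH")
}

# deterministic child seeds below 2^31 derived from one master seed
# (double arithmetic: index * multiplier exceeds 32-bit range)
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 101393 * as.numeric(index)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
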