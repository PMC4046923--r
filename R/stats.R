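#' @include AllClasses.R
NULL

#' One-sided enrichment test for a count against a background rate
#'
#' Upper-tail probability \eqn{P(X \ge k)} for
#' \eqn{X \sim Binomial(n, p_0)} -- the large-background limit of the
#' one-sided exact test for enrichment of a category (e.g. coiled-coil
#' proteins among scaffold proteins, against the proteome-wide
#' coiled-coil rate).
#'
#' @param k observed count in the category.
#' @param n sample size.
#' @param p0 background proportion in (0, 1).
#' @return one-sided p-value.
#' @examples
#' enrichmentTest(12, 44, 0.12)  # ~0.005
#' @export
enrichmentTest <- function(k, n, p0) {
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}
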