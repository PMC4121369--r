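#' @keywords internal
"_PACKAGE"

#' @importFrom stats kmeans pnorm pt rbeta rbinom rnorm rpois runif sd var setNames
#' @importFrom utils packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize chromosome labels
#'
#' Strips any `chr` prefix and upper-cases sex chromosomes so that `chr1`,
#' `1`, `chrx` and `X` all map onto the internal convention
#' `{1..22, X, Y}`.
#'
#' @param x character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @export
norm_chrom <- function(x) {
  out <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  out[toupper(out) %in% c("X", "Y")] <- toupper(out[toupper(out) %in% c("X", "Y")])
  out
}

is_autosome <- function(chrom) norm_chrom(chrom) %in% as.character(1:22)

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# row-wise mean / sample sd (n-1) without looping in R
row_means <- function(m) rowMeans(m)
row_sds <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(pmax(rowSums((m - mu)^2), 0) / (n - 1))
}
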