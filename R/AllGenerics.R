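#' @importFrom methods setGeneric setMethod setClass setValidity new validObject is slot
#' @importFrom stats runif rpois
#' @importFrom utils read.table write.table head tail
NULL

#' Chromosome name of an object
#'
#' @param x an object with a chromosome slot (e.g. a
#'   [CoverageHistogram-class]).
#' @return A character scalar.
#' @export
setGeneric("chrom", function(x) standardGeneric("chrom"))

#' Genomic coordinate of the first histogram bin
#'
#' @param x a [CoverageHistogram-class].
#' @return A 1-based integer genomic coordinate.
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' Coverage height at genomic positions
#'
#' Heights at positions outside the histogram extent are zero.
#'
#' @param x a [CoverageHistogram-class].
#' @param positions integer genomic positions (1-based).
#' @return Integer vector of coverage heights.
#' @export
setGeneric("heightAt", function(x, positions) standardGeneric("heightAt"))
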