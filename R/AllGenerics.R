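#' @rdname TestResult-class
#' @param object a TestResult, ContrastSet, RandomizationResult or
#'   CodonPairAlignment.
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname TestResult-class
#' @export
setGeneric("testStatistic", function(object) standardGeneric("testStatistic"))

#' @rdname ContrastSet-class
#' @export
setGeneric("contrastValues", function(object) standardGeneric("contrastValues"))

#' @rdname RandomizationResult-class
#' @export
setGeneric("observedR", function(object) standardGeneric("observedR"))

#' @rdname RandomizationResult-class
#' @export
setGeneric("exceedances", function(object) standardGeneric("exceedances"))

#' @rdname CodonPairAlignment-class
#' @export
setGeneric("codonsA", function(object) standardGeneric("codonsA"))

#' @rdname CodonPairAlignment-class
#' @export
setGeneric("codonsB", function(object) standardGeneric("codonsB"))

#' @rdname CodonPairAlignment-class
#' @export
setGeneric("gcCounts", function(object) standardGeneric("gcCounts"))

#' @rdname CodonPairAlignment-class
#' @export
setGeneric("purineCounts", function(object) standardGeneric("purineCounts"))

setMethod("pValue", "TestResult", function(object) object@pValue)
setMethod("pValue", "RandomizationResult", function(object) object@pValue)
setMethod("testStatistic", "TestResult", function(object) object@statistic)
setMethod("contrastValues", "ContrastSet", function(object)
  setNames(object@contrasts, object@nodes))
setMethod("observedR", "RandomizationResult", function(object) object@observedR)
setMethod("exceedances", "RandomizationResult", function(object) object@exceedances)
setMethod("codonsA", "CodonPairAlignment", function(object) object@codonsA)
setMethod("codonsB", "CodonPairAlignment", function(object) object@codonsB)

#' @rdname CodonPairAlignment-class
#' @export
setMethod("length", "CodonPairAlignment", function(x) length(x@codonsA))

## per-codon G+C counts, columns A and B
setMethod("gcCounts", "CodonPairAlignment", function(object) {
  cbind(A = countBases(object@codonsA, c("G", "C")),
        B = countBases(object@codonsB, c("G", "C")))
})

## per-codon A+G (purine) counts
setMethod("purineCounts", "CodonPairAlignment", function(object) {
  cbind(A = countBases(object@codonsA, c("A", "G")),
        B = countBases(object@codonsB, c("A", "G")))
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("TestResult [%s, %s-sided]\n", object@method, object@alternative))
  cat(sprintf("  statistic: %s = %.6g\n",
              if (length(names(object@statistic))) names(object@statistic)[1] else "stat",
              object@statistic[1]))
  cat(sprintf("  p-value:   %.6g\n", object@pValue))
  cat(sprintf("  n:         %s\n", paste(object@sampleSizes, collapse = ", ")))
})

setMethod("show", "ContrastSet", function(object) {
  cat(sprintf("ContrastSet of %d standardized contrasts for trait '%s'\n",
              length(object@contrasts), object@trait))
  if (length(object@contrasts)) {
    shown <- head(setNames(round(object@contrasts, 5), object@nodes), 6L)
    print(shown)
    if (length(object@contrasts) > 6L) cat("  ...\n")
  }
})

setMethod("show", "RandomizationResult", function(object) {
  cat("Randomization test of through-origin contrast correlation\n")
  cat(sprintf("  observed R: %.5f\n", object@observedR))
  cat(sprintf("  exceedances: %d of %d permutations\n",
              object@exceedances, object@nPerm))
  cat(sprintf("  p = (k+1)/(N+1) = %.6g", object@pValue))
  if (!is.na(object@seed)) cat(sprintf("  [seed %d]", object@seed))
  cat("\n")
})

setMethod("show", "CodonPairAlignment", function(object) {
  cat(sprintf("CodonPairAlignment '%s': %d aligned codon pairs (%d dropped)\n",
              object@id, length(object@codonsA), object@nDropped))
})
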