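#' @import methods
#' @importFrom stats cor.test pt sd setNames wilcox.test
#' @importFrom utils read.delim head
NULL

#' TestResult: outcome of a two-sample or correlation test
#'
#' Light container for the hypothesis tests used throughout the package
#' (Wilcoxon rank-sum, Pearson, Spearman). Records the statistic, the
#' p-value, how the p-value was obtained (exact enumeration vs normal
#' approximation vs t distribution) and the sample sizes, so that every
#' reported p is traceable to its method.
#'
#' @slot statistic named numeric, the test statistic.
#' @slot pValue numeric in (0, 1].
#' @slot method character tag, e.g. \code{"normal_approx"} or \code{"exact"}.
#' @slot alternative one of \code{"two"}, \code{"greater"}, \code{"less"}.
#' @slot sampleSizes integer vector of per-sample sizes.
#' @exportClass TestResult
setClass("TestResult",
  representation(
    statistic   = "numeric",
    pValue      = "numeric",
    method      = "character",
    alternative = "character",
    sampleSizes = "integer"
  )
)

setValidity("TestResult", function(object) {
  if (length(object@pValue) != 1L || !is.finite(object@pValue))
    return("pValue must be a single finite number")
  if (object@pValue <= 0 || object@pValue > 1)
    return("pValue must lie in (0, 1]")
  TRUE
})

#' ContrastSet: standardized independent contrasts for one trait
#'
#' Holds the Felsenstein contrasts computed by
#' \code{\link{independentContrasts}}: one standardized contrast per internal
#' node of a fully bifurcating rooted tree (n_leaves - 1 values), indexed by
#' the internal node number of the source tree so that two ContrastSets from
#' the same tree can be paired node-by-node.
#'
#' @slot contrasts numeric vector of standardized contrasts.
#' @slot nodes character vector of internal node identifiers, parallel to
#'   \code{contrasts}.
#' @slot trait single character, the trait name.
#' @exportClass ContrastSet
setClass("ContrastSet",
  representation(
    contrasts = "numeric",
    nodes     = "character",
    trait     = "character"
  )
)

setValidity("ContrastSet", function(object) {
  if (length(object@contrasts) != length(object@nodes))
    return("contrasts and nodes must have equal length")
  if (any(!is.finite(object@contrasts)))
    return("contrasts must all be finite")
  if (length(object@trait) != 1L)
    return("trait must be a single name")
  TRUE
})

#' RandomizationResult: permutation null for a contrast correlation
#'
#' Result of the seeded randomization test on the through-origin correlation
#' of two contrast sets. The p-value follows the plus-one estimator
#' p = (k + 1) / (N + 1), where k counts permuted correlations at least as
#' extreme (in the direction of the observed correlation) as the observed one;
#' the observed data set is treated as one additional permutation, so p is
#' bounded below by 1 / (N + 1) and can never be zero.
#'
#' @slot observedR numeric, the observed through-origin correlation.
#' @slot nPerm integer, number of permutations N.
#' @slot exceedances integer, the exceedance count k.
#' @slot pValue numeric, (k + 1) / (N + 1).
#' @slot seed integer seed used for the permutation stream (NA when the
#'   result was assembled from a pre-tabulated exceedance count).
#' @exportClass RandomizationResult
setClass("RandomizationResult",
  representation(
    observedR   = "numeric",
    nPerm       = "integer",
    exceedances = "integer",
    pValue      = "numeric",
    seed        = "integer"
  )
)

setValidity("RandomizationResult", function(object) {
  N <- object@nPerm
  k <- object@exceedances
  if (N < 1L) return("nPerm must be >= 1")
  if (k < 0L || k > N) return("exceedances must lie in [0, nPerm]")
  p <- (k + 1) / (N + 1)
  if (abs(object@pValue - p) > 1e-12)
    return("pValue must equal (exceedances + 1) / (nPerm + 1)")
  TRUE
})

#' Construct a RandomizationResult from its components
#'
#' Applies the plus-one permutation estimator p = (k + 1)/(N + 1). Used both
#' by \code{\link{randomizationPvalue}} and directly when the exceedance
#' count comes from an external randomization run.
#'
#' @param observedR observed through-origin correlation.
#' @param nPerm number of permutations N.
#' @param exceedances exceedance count k, i.e. the number of permutations
#'   whose correlation was at least as extreme as \code{observedR}.
#' @param seed integer seed that generated the permutation stream, or NA.
#' @return A \linkS4class{RandomizationResult}.
#' @examples
#' ## N = 9999 permutations with 498 exceedances -> p = 499/10000
#' pValue(RandomizationResult(0.9, 9999, 498))
#' @export
RandomizationResult <- function(observedR, nPerm, exceedances, seed = NA_integer_) {
  new("RandomizationResult",
      observedR   = as.numeric(observedR),
      nPerm       = as.integer(nPerm),
      exceedances = as.integer(exceedances),
      pValue      = (as.integer(exceedances) + 1) / (as.integer(nPerm) + 1),
      seed        = as.integer(seed))
}

#' CodonPairAlignment: aligned, gap-free codon columns of an ortholog pair
#'
#' One codon pair per protein-alignment column where neither side is a gap
#' and neither codon contains an ambiguous base. Both sides must translate
#' without internal stops (enforced upstream by \code{\link{backmapCodons}}).
#'
#' @slot id character, ortholog/gene identifier.
#' @slot codonsA character vector of 3-letter codons (first species).
#' @slot codonsB character vector, parallel to \code{codonsA}.
#' @slot nDropped integer, columns discarded because of gaps or ambiguous
#'   bases (kept for auditability).
#' @exportClass CodonPairAlignment
setClass("CodonPairAlignment",
  representation(
    id       = "character",
    codonsA  = "character",
    codonsB  = "character",
    nDropped = "integer"
  )
)

setValidity("CodonPairAlignment", function(object) {
  if (length(object@codonsA) != length(object@codonsB))
    return("codonsA and codonsB must have equal length")
  all_codons <- c(object@codonsA, object@codonsB)
  if (length(all_codons) && !all(grepl("^[ACGT]{3}$", all_codons)))
    return("codons must be 3 letters over {A,C,G,T}")
  TRUE
})
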