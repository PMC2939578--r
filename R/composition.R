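#' Amino-acid frequencies of a protein sequence
#'
#' Counts the 20 standard amino acids and returns their fractions among all
#' counted residues. Ambiguity letters (X, B, Z, U) and stops (*) are excluded
#' from both numerator and denominator, so assembly artifacts do not dilute
#' the composition estimate.
#'
#' @param sequence a protein sequence (character scalar or \code{AAString}).
#' @return Named numeric vector of 20 fractions summing to 1, with attribute
#'   \code{"nResidues"} giving the counted length.
#' @examples
#' aminoAcidFrequencies("ERK")   # E, R, K each 1/3
#' aminoAcidFrequencies("AAXA")  # A = 1, 3 residues counted
#' @export
aminoAcidFrequencies <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop("sequence must be a single non-empty protein string")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% c(AA20, AA_SKIP))
  if (any(bad))
    stop("illegal character '", chars[which(bad)[1]], "' at position ",
         which(bad)[1])
  counts <- table(factor(chars[chars %in% AA20], levels = AA20))
  n <- sum(counts)
  if (n == 0L)
    stop("no countable residues: sequence contains only ambiguity letters/stops")
  freqs <- as.numeric(counts) / n
  names(freqs) <- AA20
  attr(freqs, "nResidues") <- as.integer(n)
  freqs
}

## shared kernel: percentage-point difference between two residue sets
scoreFromSets <- function(freqs, plus, minus) {
  100 * (sum(freqs[plus]) - sum(freqs[minus]))
}

#' ERK amino-acid usage bias
#'
#' ERK = E + R + K - D - N - Q - T - S - H - A, each letter the fraction of
#' that amino acid among all residues, reported in percentage points
#' (fractions x 100). Higher ERK proxies greater protein thermostability:
#' the three enriched residues strengthen surface electrostatics at high
#' temperature while the seven subtracted ones are depleted in thermophiles.
#'
#' @param x amino-acid frequencies from \code{\link{aminoAcidFrequencies}},
#'   or a raw protein sequence (converted internally).
#' @return ERK in percentage points, in [-100, 100].
#' @examples
#' erkScore("ERK")      # +100
#' erkScore("DNQTSHA")  # -100
#' @seealso \code{\link{cvpScore}}, \code{\link{proteomeBias}}
#' @export
erkScore <- function(x) {
  if (is.character(x) && is.null(names(x))) x <- aminoAcidFrequencies(x)
  scoreFromSets(x, ERK_PLUS, ERK_MINUS)
}

#' CvP-bias: charged versus polar-uncharged residues
#'
#' CvP-bias = D + E + R + K - N - Q - T - S in percentage points. A
#' thermostability proxy closely related to ERK; the two differ only in the
#' treatment of D, H and A.
#'
#' @inheritParams erkScore
#' @return CvP-bias in percentage points.
#' @examples
#' cvpScore("DERK")  # +100
#' cvpScore("AHG")   # 0: A, H, G are unscored by CvP
#' @export
cvpScore <- function(x) {
  if (is.character(x) && is.null(names(x))) x <- aminoAcidFrequencies(x)
  scoreFromSets(x, CVP_PLUS, CVP_MINUS)
}

#' Per-protein and concatenated-proteome composition bias
#'
#' Computes ERK and CvP-bias for every protein and for the whole proteome.
#' The proteome-level value is obtained from the pooled residue counts of all
#' proteins (equivalently, the length-weighted mean of per-protein values) —
#' not the unweighted mean — mirroring how a species-level value is derived
#' from the concatenated sequence of all its proteins.
#'
#' @param proteome an \code{AAStringSet} or named character vector of protein
#'   sequences.
#' @param measure which statistics to report: \code{"both"} (default),
#'   \code{"ERK"} or \code{"CvP"}.
#' @return List with \code{perProtein} (data.frame: id, length, ERK and/or
#'   CvP) and \code{concatenated} (named numeric of proteome-level values).
#' @examples
#' pb <- proteomeBias(c(a = "ERK", b = "DNQTSHA"))
#' pb$concatenated["ERK"]  # -40: pooled counts, not mean of +100 and -100
#' @export
proteomeBias <- function(proteome, measure = c("both", "ERK", "CvP")) {
  measure <- match.arg(measure)
  seqs <- asSequenceVector(proteome)
  if (!length(seqs)) stop("empty proteome")
  if (is.null(names(seqs))) names(seqs) <- paste0("p", seq_along(seqs))

  freqList <- lapply(seqs, aminoAcidFrequencies)
  lengths <- vapply(freqList, function(f) attr(f, "nResidues"), integer(1))
  per <- data.frame(id = names(seqs), length = lengths,
                    row.names = NULL, stringsAsFactors = FALSE)

  ## pooled counts across proteins = composition of the concatenated sequence
  countMat <- vapply(freqList, function(f) as.numeric(f) * attr(f, "nResidues"),
                     numeric(length(AA20)))
  pooled <- rowSums(countMat)
  pooledFreqs <- setNames(pooled / sum(pooled), AA20)

  conc <- numeric(0)
  if (measure %in% c("both", "ERK")) {
    per$ERK <- vapply(freqList, erkScore, numeric(1), USE.NAMES = FALSE)
    conc["ERK"] <- erkScore(pooledFreqs)
  }
  if (measure %in% c("both", "CvP")) {
    per$CvP <- vapply(freqList, cvpScore, numeric(1), USE.NAMES = FALSE)
    conc["CvP"] <- cvpScore(pooledFreqs)
  }
  list(perProtein = per, concatenated = conc, pooledFrequencies = pooledFreqs)
}

#' Pooled amino-acid frequencies of a proteome
#'
#' @param proteome an \code{AAStringSet} or character vector.
#' @return Named numeric vector of 20 fractions (pooled over all proteins),
#'   with attribute \code{"nResidues"}.
#' @export
proteomeFrequencies <- function(proteome) {
  pb <- proteomeBias(proteome, measure = "ERK")
  f <- pb$pooledFrequencies
  attr(f, "nResidues") <- sum(pb$perProtein$length)
  f
}

#' AT-rich and GC-rich codon usage of a coding sequence
#'
#' Classifies each sense codon by the nucleotide character of the amino acid
#' it encodes and reports the two class percentages. Under the default
#' FYMINK/GARP scheme a codon is AT-rich iff it encodes F, Y, M, I, N or K
#' and GC-rich iff it encodes G, A, R or P; other codons are unclassified but
#' still count in the denominator. The alternative \code{allAT_allGC} scheme
#' classifies by the codon's own bases (all three A/T vs all three G/C).
#'
#' @param cds in-frame coding sequence (character scalar, \code{DNAString},
#'   or a \code{CdsRecord}-style named element). A single terminal stop codon
#'   is allowed and excluded from the denominator.
#' @param scheme \code{"FYMINK_GARP"} (default) or \code{"allAT_allGC"}.
#' @return List: \code{pctATrich}, \code{pctGCrich}, \code{nCodons} (sense
#'   codons counted), \code{scheme}.
#' @examples
#' codonClassFractions("AAAAAATTT")  # K,K,F: 100% AT-rich
#' codonClassFractions("AAAGGCGAA")  # K,G,E: 33.3% / 33.3%, E unclassified
#' @export
codonClassFractions <- function(cds, scheme = c("FYMINK_GARP", "allAT_allGC")) {
  scheme <- match.arg(scheme)
  cds <- toupper(as.character(cds))
  codons <- splitCodons(cds)
  if (!length(codons)) stop("empty coding sequence")
  aa <- translateCodons(codons)

  ## terminal stop tolerated; internal stop is a frame/annotation error
  if (length(aa) && aa[length(aa)] == "*") {
    codons <- codons[-length(codons)]
    aa <- aa[-length(aa)]
  }
  if (any(aa == "*"))
    stop("internal stop codon at codon index ", which(aa == "*")[1])
  if (!length(codons)) stop("no sense codons")

  if (scheme == "FYMINK_GARP") {
    at <- aa %in% FYMINK
    gc <- aa %in% GARP
  } else {
    nGC <- countBases(codons, c("G", "C"))
    at <- nGC == 0L
    gc <- nGC == 3L
  }
  list(pctATrich = 100 * mean(at),
       pctGCrich = 100 * mean(gc),
       nCodons = length(codons),
       scheme = scheme)
}

#' Codon-class usage pooled over a CDS set
#'
#' Applies \code{\link{codonClassFractions}} to every sequence and pools the
#' counts, giving the species-level percentages used in group comparisons.
#'
#' @param cdsSet \code{DNAStringSet} or character vector of in-frame CDS.
#' @inheritParams codonClassFractions
#' @return As \code{\link{codonClassFractions}}, for the pooled codons.
#' @export
codonClassUsage <- function(cdsSet, scheme = c("FYMINK_GARP", "allAT_allGC")) {
  scheme <- match.arg(scheme)
  seqs <- asSequenceVector(cdsSet)
  if (!length(seqs)) stop("empty CDS set")
  parts <- lapply(seqs, codonClassFractions, scheme = scheme)
  n <- vapply(parts, `[[`, numeric(1), "nCodons")
  list(pctATrich = sum(vapply(parts, `[[`, numeric(1), "pctATrich") * n) / sum(n),
       pctGCrich = sum(vapply(parts, `[[`, numeric(1), "pctGCrich") * n) / sum(n),
       nCodons = as.integer(sum(n)),
       scheme = scheme)
}
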