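#' Back-map a protein alignment onto codons
#'
#' Replaces each aligned amino acid with its encoding codon, producing the
#' codon-level alignment on which the GC-neutral and purine-neutral controls
#' operate. The ungapped protein sequences must equal the translations of
#' their coding sequences (a single terminal stop codon is ignored); any
#' discrepancy is reported with the first mismatching residue index.
#' Alignment columns where either side is a gap, and codon pairs containing
#' ambiguous bases, are dropped and counted.
#'
#' @param alignedA,alignedB equal-length aligned protein strings (gaps
#'   as \code{-}).
#' @param cdsA,cdsB the corresponding in-frame coding sequences.
#' @param id identifier stored in the result.
#' @return A \linkS4class{CodonPairAlignment}.
#' @examples
#' cpa <- backmapCodons("ME", "ME", "ATGGAA", "ATGGAG")
#' codonsA(cpa)  # ATG GAA
#' @export
backmapCodons <- function(alignedA, alignedB, cdsA, cdsB, id = "pair") {
  alignedA <- toupper(as.character(alignedA))
  alignedB <- toupper(as.character(alignedB))
  if (nchar(alignedA) != nchar(alignedB))
    stop("aligned sequences differ in length")
  codA <- cdsToCodons(cdsA, gsub("-", "", alignedA, fixed = TRUE), "A")
  codB <- cdsToCodons(cdsB, gsub("-", "", alignedB, fixed = TRUE), "B")

  colsA <- strsplit(alignedA, "", fixed = TRUE)[[1]]
  colsB <- strsplit(alignedB, "", fixed = TRUE)[[1]]
  ia <- cumsum(colsA != "-")
  ib <- cumsum(colsB != "-")
  keep <- colsA != "-" & colsB != "-"
  pa <- codA[ia[keep]]
  pb <- codB[ib[keep]]
  clean <- grepl("^[ACGT]{3}$", pa) & grepl("^[ACGT]{3}$", pb)
  new("CodonPairAlignment", id = as.character(id),
      codonsA = pa[clean], codonsB = pb[clean],
      nDropped = as.integer(sum(!keep) + sum(!clean)))
}

## validate a CDS against its (ungapped) protein and return its codons
cdsToCodons <- function(cds, protein, label) {
  cds <- toupper(as.character(cds))
  codons <- splitCodons(cds)
  aa <- translateCodons(codons)
  if (length(aa) && aa[length(aa)] == "*") {
    codons <- codons[-length(codons)]
    aa <- aa[-length(aa)]
  }
  np <- nchar(protein)
  if (length(codons) != np)
    stop("CDS ", label, " encodes ", length(codons),
         " residues but the protein has ", np)
  prot <- strsplit(protein, "", fixed = TRUE)[[1]]
  ## ambiguous codons translate to X and are only accepted against X
  mism <- which(aa != prot)
  if (length(mism))
    stop("translation mismatch on side ", label, " at residue index ",
         mism[1], " (", aa[mism[1]], " vs ", prot[mism[1]], ")")
  codons
}

#' Keep codon pairs matched for GC or purine content
#'
#' \code{gc_neutral} retains pairs whose two codons carry the same integer
#' G+C count (0-3); \code{purine_neutral} retains pairs with equal A+G
#' counts. Recomputing a composition statistic on the retained codons
#' decouples it from genome-wide nucleotide-composition differences between
#' the two species: any residual difference cannot be explained by GC (or
#' purine) content alone. Order is preserved and the filter is idempotent.
#'
#' @param pairs a \linkS4class{CodonPairAlignment}.
#' @param mode \code{"gc_neutral"} or \code{"purine_neutral"}.
#' @return The filtered \linkS4class{CodonPairAlignment}.
#' @export
matchedCodonFilter <- function(pairs, mode = c("gc_neutral", "purine_neutral")) {
  mode <- match.arg(mode)
  counts <- if (mode == "gc_neutral") gcCounts(pairs) else purineCounts(pairs)
  keep <- counts[, "A"] == counts[, "B"]
  new("CodonPairAlignment", id = pairs@id,
      codonsA = pairs@codonsA[keep], codonsB = pairs@codonsB[keep],
      nDropped = pairs@nDropped + as.integer(sum(!keep)))
}

#' ERK on the two sides of a matched codon alignment
#'
#' Translates each side's retained codons and applies the ERK statistic to
#' the resulting amino-acid multisets. Typically called after
#' \code{\link{matchedCodonFilter}}; an empty retained set is an error so
#' that callers can skip over-filtered genes explicitly.
#'
#' @param pairs a \linkS4class{CodonPairAlignment} with at least one pair.
#' @return List: \code{erkA}, \code{erkB} (percentage points),
#'   \code{nCodons}.
#' @export
matchedErk <- function(pairs) {
  if (!length(pairs))
    stop("no codon pairs retained; gene should be skipped")
  aaA <- translateCodons(pairs@codonsA)
  aaB <- translateCodons(pairs@codonsB)
  list(erkA = erkScore(aminoAcidFrequencies(paste(aaA, collapse = ""))),
       erkB = erkScore(aminoAcidFrequencies(paste(aaB, collapse = ""))),
       nCodons = length(pairs))
}
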