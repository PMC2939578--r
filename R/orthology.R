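## pick the best subject for every query: max bitscore, then min evalue,
## then lexicographically smallest subject id (deterministic ladder)
bestHits <- function(tab) {
  if (!nrow(tab))
    return(data.frame(query = character(0), subject = character(0),
                      bitscore = numeric(0), stringsAsFactors = FALSE))
  ord <- order(tab$query, -tab$bitscore, tab$evalue, tab$subject)
  tab <- tab[ord, , drop = FALSE]
  tab[!duplicated(tab$query), c("query", "subject", "bitscore"), drop = FALSE]
}

#' Reciprocal-best-hit ortholog pairs
#'
#' A pair (a, b) is an ortholog call iff b is the best hit of a in the
#' A-to-B table and a is the best hit of b in the B-to-A table. Best hits
#' are chosen by maximum bit score, ties broken by minimum e-value, then by
#' lexicographically smallest subject id, so results are identical across
#' platforms. Queries without hits are skipped.
#'
#' @param hitsAB,hitsBA hit tables as returned by \code{\link{readHitTable}}
#'   (already reduced to the best HSP per pair).
#' @param speciesA,speciesB labels recorded in the output.
#' @return data.frame: speciesA, proteinA, speciesB, proteinB, bitscore (of
#'   the A-to-B best hit).
#' @export
reciprocalBestHits <- function(hitsAB, hitsBA, speciesA = "A", speciesB = "B") {
  ba <- bestHits(hitsAB)
  ab <- bestHits(hitsBA)
  backMap <- setNames(ab$subject, ab$query)
  keep <- !is.na(backMap[ba$subject]) & backMap[ba$subject] == ba$query
  keep[is.na(keep)] <- FALSE
  out <- data.frame(speciesA = rep(speciesA, sum(keep)),
                    proteinA = ba$query[keep],
                    speciesB = rep(speciesB, sum(keep)),
                    proteinB = ba$subject[keep],
                    bitscore = ba$bitscore[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Retain proteins with at least one ortholog outside their life-style group
#'
#' Given reciprocal-best-hit pairs across a species panel labeled by
#' life-style group (hyperthermophile / thermophile / mesophile), a protein
#' is retained iff it participates in at least one ortholog pair whose
#' partner species carries a different group label. This removes proteins
#' whose presence is confined to one life style, controlling for gene
#' repertoire differences between groups.
#'
#' @param pairs data.frame of ortholog pairs (speciesA, proteinA, speciesB,
#'   proteinB), typically row-bound output of
#'   \code{\link{reciprocalBestHits}} over all species pairs.
#' @param groups named character vector: species -> group label.
#' @return Named list, species -> character vector of retained protein ids.
#' @export
lifestyleFilteredSet <- function(pairs, groups) {
  spp <- unique(c(pairs$speciesA, pairs$speciesB))
  missing <- setdiff(spp, names(groups))
  if (length(missing))
    stop("species without a group label: ", paste(missing, collapse = ", "))
  cross <- groups[pairs$speciesA] != groups[pairs$speciesB]
  keepA <- unique(pairs[cross, c("speciesA", "proteinA")])
  keepB <- unique(pairs[cross, c("speciesB", "proteinB")])
  names(keepA) <- names(keepB) <- c("species", "protein")
  kept <- unique(rbind(keepA, keepB))
  split(kept$protein, factor(kept$species, levels = sort(unique(kept$species))))
}

#' Reference-anchored ubiquitous co-ortholog groups
#'
#' A reference protein founds a co-ortholog group iff it has a
#' reciprocal-best-hit partner in every non-reference species of the panel.
#'
#' @param reference name of the reference (anchor) species.
#' @param pairsList list of ortholog-pair data.frames, each from
#'   \code{\link{reciprocalBestHits}} between the reference and one other
#'   species (either orientation).
#' @return data.frame with one row per group: column \code{reference} (the
#'   anchor protein id) plus one column per other species.
#' @export
coOrthologGroups <- function(reference, pairsList) {
  if (!length(pairsList))
    return(data.frame(reference = character(0), stringsAsFactors = FALSE))
  maps <- lapply(pairsList, function(p) {
    if (!nrow(p)) return(NULL)
    if (all(p$speciesA == reference)) {
      data.frame(ref = p$proteinA, other = p$proteinB,
                 species = p$speciesB[1], stringsAsFactors = FALSE)
    } else if (all(p$speciesB == reference)) {
      data.frame(ref = p$proteinB, other = p$proteinA,
                 species = p$speciesA[1], stringsAsFactors = FALSE)
    } else {
      stop("each pair table must involve the reference species '",
           reference, "'")
    }
  })
  maps <- Filter(Negate(is.null), maps)
  if (!length(maps))
    return(data.frame(reference = character(0), stringsAsFactors = FALSE))
  others <- vapply(maps, function(m) m$species[1], character(1))
  if (anyDuplicated(others))
    stop("multiple pair tables for species '", others[duplicated(others)][1], "'")
  anchors <- Reduce(intersect, lapply(maps, function(m) m$ref))
  out <- data.frame(reference = sort(anchors), stringsAsFactors = FALSE)
  for (m in maps) {
    idx <- match(out$reference, m$ref)
    out[[m$species[1]]] <- m$other[idx]
  }
  out
}

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment via Biostrings, with BLAST-like
#' defaults (BLOSUM62, gap open 11, gap extend 1). Intended for desk-scale
#' segment comparisons; externally produced alignments are accepted as
#' aligned FASTA wherever this package consumes alignments.
#'
#' @param a,b protein sequences (character scalars).
#' @param substitutionMatrix name of a Biostrings substitution matrix or a
#'   matrix.
#' @param gapOpening,gapExtension positive gap penalties.
#' @return List: \code{alignedA}, \code{alignedB} (equal-length strings with
#'   \code{-} gaps), \code{score}.
#' @examples
#' alignPair("ERK", "EK")  # one gap column
#' @export
alignPair <- function(a, b, substitutionMatrix = "BLOSUM62",
                      gapOpening = 11, gapExtension = 1) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = substitutionMatrix,
                                      gapOpening = gapOpening,
                                      gapExtension = gapExtension)
  list(alignedA = as.character(Biostrings::pattern(pa)),
       alignedB = as.character(Biostrings::subject(pa)),
       score = Biostrings::score(pa))
}
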