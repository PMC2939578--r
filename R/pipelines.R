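## check that proteome names and trait species coincide
checkSpeciesMatch <- function(proteomes, traits) {
  spp <- names(proteomes)
  ts <- traits$species
  extra <- setdiff(spp, ts); lacking <- setdiff(ts, spp)
  if (length(extra) || length(lacking))
    stop("species mismatch; proteomes without traits: [",
         paste(extra, collapse = ", "), "]; traits without proteomes: [",
         paste(lacking, collapse = ", "), "]")
  invisible(TRUE)
}

#' Proteome-wide thermal-composition analysis of a species panel
#'
#' Reproduces the prokaryote workflow end to end: species-level ERK and
#' CvP-bias from pooled (concatenated) proteome counts; naive Pearson and
#' Spearman correlations of ERK with temperature; pairwise Wilcoxon
#' rank-sum tests between life-style groups (hyperthermophile /
#' thermophile / mesophile) on the species values; a per-amino-acid profile
#' contrasting the naive and phylogenetically corrected correlations; and,
#' when a tree is supplied, the independent-contrast correlation of ERK with
#' temperature together with its seeded randomization p-value.
#'
#' @param proteomes named list, species -> \code{AAStringSet} or character
#'   vector of proteins.
#' @param traits trait table (data.frame with species, temperature, group).
#' @param tree optional rooted bifurcating \code{phylo} covering the panel.
#' @param nPerm,seed randomization parameters.
#' @return List: \code{speciesStats}, \code{naive} (pearson, spearman
#'   TestResults), \code{groupTests}, \code{perAminoAcid},
#'   \code{comparative} (R + \linkS4class{RandomizationResult}, or NULL),
#'   \code{notes}.
#' @export
runProkaryoteAnalysis <- function(proteomes, traits, tree = NULL,
                                  nPerm = 9999, seed = 1L) {
  if (length(proteomes) < 3) stop("need at least 3 species")
  checkSpeciesMatch(proteomes, traits)
  spp <- names(proteomes)
  traits <- traits[match(spp, traits$species), , drop = FALSE]
  notes <- character(0)

  biases <- lapply(proteomes, proteomeBias)
  speciesStats <- data.frame(
    species = spp,
    temperature = traits$temperature,
    group = traits$group,
    ERK = vapply(biases, function(b) unname(b$concatenated["ERK"]), numeric(1)),
    CvP = vapply(biases, function(b) unname(b$concatenated["CvP"]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(speciesStats) <- NULL

  naive <- list(pearson = pearsonTest(speciesStats$ERK, speciesStats$temperature),
                spearman = spearmanTest(speciesStats$ERK, speciesStats$temperature))

  groups <- unique(speciesStats$group[!is.na(speciesStats$group)])
  groupTests <- list()
  if (length(groups) < 2) {
    notes <- c(notes, "only one life-style group present; group tests skipped")
  } else {
    for (pair in utils::combn(sort(groups), 2, simplify = FALSE)) {
      a <- speciesStats$ERK[speciesStats$group == pair[1]]
      b <- speciesStats$ERK[speciesStats$group == pair[2]]
      if (length(a) < 2 || length(b) < 2) {
        notes <- c(notes, paste0("group pair ", pair[1], "/", pair[2],
                                 " too small; skipped"))
        next
      }
      groupTests[[paste(pair, collapse = "_vs_")]] <-
        wilcoxonRankSum(a, b, method = "normal_approx")
    }
  }

  comparative <- NULL
  if (is.null(tree)) {
    notes <- c(notes, "no tree supplied; comparative columns omitted")
    perAA <- perAaTemperatureProfile(proteomes, traits, tree = NULL)
  } else {
    perAA <- perAaTemperatureProfile(proteomes, traits, tree = tree)
    erkVec <- setNames(speciesStats$ERK, spp)
    tVec <- setNames(speciesStats$temperature, spp)
    cErk <- independentContrasts(tree, erkVec, name = "ERK")
    cT <- independentContrasts(tree, tVec, name = "temperature")
    comparative <- list(
      R = contrastCorrelation(cErk, cT),
      randomization = randomizationPvalue(cErk, cT, nPerm = nPerm, seed = seed))
  }

  list(speciesStats = speciesStats, naive = naive, groupTests = groupTests,
       perAminoAcid = perAA, comparative = comparative, notes = notes)
}

#' Vertebrate endotherm-vs-ectotherm composition analysis
#'
#' Runs the vertebrate workflow: per-species concatenated ERK (computed from
#' proteomes, or taken from a precomputed species-level table such as a
#' published summary); the endotherm-vs-ectotherm Wilcoxon rank-sum test on
#' genomic averages (normal approximation with tie and continuity
#' correction), applied to ERK, to temperature, and to any codon-class
#' usage columns present; reference-anchored co-ortholog groups and
#' per-species one-sided ortholog tests when hit tables are supplied; the
#' independent-contrast correlation with its randomization p when a tree is
#' supplied; and GC-neutral / purine-neutral matched-ERK tests for a
#' designated species pair when coding sequences are supplied.
#'
#' @param traits trait table with species, temperature and group labels
#'   (\code{"endotherm"} / \code{"ectotherm"}); extra numeric columns of a
#'   \code{speciesTable} (e.g. \code{ERK}, \code{pct_at_rich}) are tested
#'   too.
#' @param proteomes optional named list of per-species protein sets.
#' @param speciesTable optional precomputed data.frame (species,
#'   temperature, group, ERK, ...); used when proteomes are not given.
#' @param tree optional \code{phylo} covering the panel.
#' @param cds optional named list of per-species \code{DNAStringSet}.
#' @param hitTables optional nested list of hit tables [[A]][[B]].
#' @param reference reference species for co-orthology (must be in the
#'   panel).
#' @param matchedPair optional length-2 character: the species pair for the
#'   codon-matched controls (requires \code{cds} and \code{hitTables}).
#' @param nPerm,seed randomization parameters.
#' @return List of result blocks; see Details in the vignette.
#' @export
runVertebrateAnalysis <- function(traits, proteomes = NULL,
                                  speciesTable = NULL, tree = NULL,
                                  cds = NULL, hitTables = NULL,
                                  reference = NULL, matchedPair = NULL,
                                  nPerm = 9999, seed = 1L) {
  notes <- character(0)
  if (is.null(proteomes) && is.null(speciesTable) && !("ERK" %in% names(traits)))
    stop("supply proteomes, or a speciesTable / trait table with an ERK column")
  if (is.null(speciesTable) && !is.null(traits) && "ERK" %in% names(traits))
    speciesTable <- traits

  if (!is.null(proteomes)) {
    checkSpeciesMatch(proteomes, traits)
    spp <- names(proteomes)
    tr <- traits[match(spp, traits$species), , drop = FALSE]
    biases <- lapply(proteomes, proteomeBias)
    speciesTable <- data.frame(
      species = spp, temperature = tr$temperature, group = tr$group,
      ERK = vapply(biases, function(b) unname(b$concatenated["ERK"]), numeric(1)),
      CvP = vapply(biases, function(b) unname(b$concatenated["CvP"]), numeric(1)),
      stringsAsFactors = FALSE)
    if (!is.null(cds)) {
      usage <- lapply(spp, function(s) codonClassUsage(cds[[s]]))
      speciesTable$pct_at_rich <- vapply(usage, `[[`, numeric(1), "pctATrich")
      speciesTable$pct_gc_rich <- vapply(usage, `[[`, numeric(1), "pctGCrich")
    }
  }
  rownames(speciesTable) <- NULL

  grp <- speciesTable$group
  if (length(unique(grp[!is.na(grp)])) < 2)
    stop("group test needs both endotherm and ectotherm species")
  endo <- speciesTable[grp == "endotherm", , drop = FALSE]
  ecto <- speciesTable[grp == "ectotherm", , drop = FALSE]

  testCols <- intersect(c("ERK", "temperature", "CvP",
                          "pct_at_rich", "pct_gc_rich"),
                        names(speciesTable))
  groupTests <- lapply(setNames(testCols, testCols), function(col)
    wilcoxonRankSum(endo[[col]], ecto[[col]], method = "normal_approx"))

  orthology <- NULL
  if (!is.null(hitTables) && !is.null(reference)) {
    if (!reference %in% speciesTable$species)
      stop("reference species '", reference, "' not in the panel")
    others <- setdiff(speciesTable$species, reference)
    pairsList <- lapply(others, function(s)
      reciprocalBestHits(hitTables[[reference]][[s]],
                         hitTables[[s]][[reference]],
                         speciesA = reference, speciesB = s))
    names(pairsList) <- others
    groups <- coOrthologGroups(reference, pairsList)

    perSpecies <- NULL
    if (!is.null(proteomes) && nrow(groups)) {
      refSeqs <- asSequenceVector(proteomes[[reference]])
      refErk <- vapply(refSeqs[groups$reference], erkScore, numeric(1))
      perSpecies <- do.call(rbind, lapply(others, function(s) {
        seqs <- asSequenceVector(proteomes[[s]])
        erks <- vapply(seqs[groups[[s]]], erkScore, numeric(1))
        tt <- wilcoxonRankSum(erks, refErk, method = "normal_approx",
                              sides = "greater")
        data.frame(species = s, n = length(erks),
                   meanErk = mean(erks), meanRefErk = mean(refErk),
                   pGreaterThanReference = pValue(tt),
                   stringsAsFactors = FALSE)
      }))
    }
    orthology <- list(pairs = pairsList, groups = groups,
                      nGroups = nrow(groups), perSpeciesTests = perSpecies)
  }

  comparative <- NULL
  if (!is.null(tree)) {
    erkVec <- setNames(speciesTable$ERK, speciesTable$species)
    tVec <- setNames(speciesTable$temperature, speciesTable$species)
    cErk <- independentContrasts(tree, erkVec, name = "ERK")
    cT <- independentContrasts(tree, tVec, name = "temperature")
    comparative <- list(
      R = contrastCorrelation(cErk, cT),
      randomization = randomizationPvalue(cErk, cT, nPerm = nPerm, seed = seed))
  } else {
    notes <- c(notes, "no tree supplied; comparative block omitted")
  }

  matched <- NULL
  if (!is.null(matchedPair)) {
    if (is.null(cds) || is.null(proteomes) || is.null(orthology))
      stop("matchedPair controls need proteomes, cds and hitTables")
    matched <- matchedErkControls(matchedPair, proteomes, cds, hitTables)
  }

  list(speciesTable = speciesTable, groupTests = groupTests,
       orthology = orthology, comparative = comparative,
       matchedControls = matched, notes = notes)
}

## align ortholog pairs of two species, back-map codons, and test the
## per-gene ERK difference on GC-neutral and purine-neutral codons
matchedErkControls <- function(pair, proteomes, cds, hitTables) {
  a <- pair[1]; b <- pair[2]
  rbh <- reciprocalBestHits(hitTables[[a]][[b]], hitTables[[b]][[a]],
                            speciesA = a, speciesB = b)
  if (!nrow(rbh)) stop("no ortholog pairs between ", a, " and ", b)
  seqA <- asSequenceVector(proteomes[[a]])
  seqB <- asSequenceVector(proteomes[[b]])
  cdsA <- asSequenceVector(cds[[a]])
  cdsB <- asSequenceVector(cds[[b]])

  perGene <- lapply(seq_len(nrow(rbh)), function(i) {
    pa <- rbh$proteinA[i]; pb <- rbh$proteinB[i]
    aln <- alignPair(seqA[[pa]], seqB[[pb]])
    cpa <- backmapCodons(aln$alignedA, aln$alignedB,
                         cdsA[[pa]], cdsB[[pb]], id = pa)
    out <- list(gene = pa)
    for (mode in c("gc_neutral", "purine_neutral")) {
      filt <- matchedCodonFilter(cpa, mode)
      out[[mode]] <- if (length(filt)) matchedErk(filt) else NULL
    }
    out
  })

  summarise <- function(mode) {
    vals <- Filter(Negate(is.null), lapply(perGene, `[[`, mode))
    if (length(vals) < 2) return(NULL)
    dA <- vapply(vals, `[[`, numeric(1), "erkA")
    dB <- vapply(vals, `[[`, numeric(1), "erkB")
    p <- wilcox.test(dA, dB, paired = TRUE, exact = FALSE)$p.value
    list(nGenes = length(vals), meanErkA = mean(dA), meanErkB = mean(dB),
         pairedWilcoxonP = p)
  }
  list(pair = pair, nOrthologs = nrow(rbh),
       gc_neutral = summarise("gc_neutral"),
       purine_neutral = summarise("purine_neutral"))
}

#' Compare composition bias across aligned segment pairs
#'
#' For each aligned segment pair, ERK is computed on both gap-stripped
#' sides; each labeled comparison then gets a Wilcoxon rank-sum test of the
#' side-A values against the side-B values across its segment pairs
#' (mirroring genome-vs-genome segment comparisons such as chicken against
#' individual reptiles).
#'
#' @param segments data.frame with columns \code{label}, \code{segA},
#'   \code{segB} (aligned segment strings; gaps allowed).
#' @param sides test sidedness, default two-sided.
#' @return data.frame: label, nPairs, meanErkA, meanErkB, p.
#' @export
runSegmentComparison <- function(segments, sides = "two") {
  need <- c("label", "segA", "segB")
  if (!all(need %in% names(segments)))
    stop("segments must have columns label, segA, segB")
  if (!nrow(segments)) stop("empty comparison")
  erkOf <- function(s) erkScore(aminoAcidFrequencies(gsub("-", "", s)))
  segments$erkA <- vapply(segments$segA, erkOf, numeric(1), USE.NAMES = FALSE)
  segments$erkB <- vapply(segments$segB, erkOf, numeric(1), USE.NAMES = FALSE)
  out <- do.call(rbind, lapply(split(segments, segments$label), function(d) {
    tt <- wilcoxonRankSum(d$erkA, d$erkB, method = "normal_approx",
                          sides = sides)
    data.frame(label = d$label[1], nPairs = nrow(d),
               meanErkA = mean(d$erkA), meanErkB = mean(d$erkB),
               p = pValue(tt), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
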