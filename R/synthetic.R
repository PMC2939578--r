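#' Baseline amino-acid frequencies
#'
#' A typical proteome composition (Swiss-Prot-like relative abundances),
#' normalized to sum to 1. Its ERK of about -17.9 pp sits in the range
#' observed for real vertebrate proteomes, so tilted simulations stay on a
#' realistic scale.
#'
#' @return Named numeric vector over the 20 standard amino acids.
#' @export
baselineAminoAcidFrequencies <- function() {
  f <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38, Q = 3.93,
         E = 6.72, G = 7.07, H = 2.27, I = 5.91, L = 9.65, K = 5.80,
         M = 2.41, F = 3.86, P = 4.74, S = 6.66, T = 5.35, W = 1.10,
         Y = 2.92, V = 6.85)
  f <- f / sum(f)
  f[AA20]
}

#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the simulation: panel size, Yule tree birth rate,
#' the Brownian-motion temperature trait (root value, rate, biological
#' clamp), the linear amino-acid tilt linking composition to temperature,
#' proteome shape, codon GC3, ortholog divergence, and the master seed that
#' makes all outputs reproducible.
#'
#' Defaults describe a prokaryote-like panel: 50 species, root temperature
#' 50 degrees C with BM rate 100 degC^2 per unit branch clamped to 0-103
#' degrees C (amino-acid composition responds approximately linearly to
#' temperature over roughly 7-103 degrees C), and an ERK-vs-temperature
#' slope of 0.05 percentage points per degree. The default 300 proteins of
#' 100-300 residues per species are a desk-scale stand-in for a complete
#' proteome: they keep the ERK counting noise (about 0.3 pp per species)
#' well below the imposed temperature signal, as it is for real proteomes,
#' while remaining fast to simulate.
#'
#' @param nSpecies number of species (>= 2).
#' @param birthRate Yule (pure-birth) speciation rate.
#' @param rootTemperature BM root value, degrees C.
#' @param sigma2 BM rate, degC^2 per unit branch length.
#' @param clamp length-2 numeric, temperatures clipped to this interval.
#' @param beta ERK slope, percentage points per degree C.
#' @param baselineFrequencies amino-acid frequency vector summing to 1.
#' @param proteinsPerSpecies proteins simulated per species.
#' @param lengthRange length-2 integer, protein length bounds.
#' @param gc3 third-position G/C probability for synonymous codon choice.
#' @param substitutionRate per-site substitution probability per unit branch
#'   for ortholog divergence.
#' @param seed master integer seed, recorded in all outputs.
#' @return An object of class \code{GeneratorConfig} (a validated list).
#' @export
generatorConfig <- function(nSpecies = 50, birthRate = 1,
                            rootTemperature = 50, sigma2 = 100,
                            clamp = c(0, 103), beta = 0.05,
                            baselineFrequencies = baselineAminoAcidFrequencies(),
                            proteinsPerSpecies = 300,
                            lengthRange = c(100, 300), gc3 = 0.5,
                            substitutionRate = 0.1, seed = 1L) {
  stopifnot(nSpecies >= 2, birthRate > 0, sigma2 >= 0,
            length(clamp) == 2, clamp[1] < clamp[2],
            is.finite(beta), proteinsPerSpecies >= 1,
            length(lengthRange) == 2, lengthRange[1] <= lengthRange[2],
            gc3 > 0, gc3 < 1, substitutionRate >= 0)
  f <- baselineFrequencies[AA20]
  if (anyNA(f) || abs(sum(f) - 1) > 1e-8)
    stop("baselineFrequencies must cover the 20 standard amino acids and sum to 1")
  structure(list(nSpecies = as.integer(nSpecies), birthRate = birthRate,
                 rootTemperature = rootTemperature, sigma2 = sigma2,
                 clamp = clamp, beta = beta, baselineFrequencies = f,
                 proteinsPerSpecies = as.integer(proteinsPerSpecies),
                 lengthRange = as.integer(lengthRange), gc3 = gc3,
                 substitutionRate = substitutionRate,
                 seed = as.integer(seed)),
            class = "GeneratorConfig")
}

#' Simulate a pure-birth (Yule) species tree
#'
#' Ultrametric, fully bifurcating, tips labeled s1..sn. Same seed, same
#' newick string.
#'
#' @param nSpecies number of tips.
#' @param birthRate speciation rate.
#' @param seed integer seed.
#' @return A \code{phylo} object.
#' @export
simulateTree <- function(nSpecies, birthRate = 1, seed = 1L) {
  set.seed(as.integer(seed))
  tree <- ape::rphylo(nSpecies, birth = birthRate, death = 0)
  tree$tip.label <- paste0("s", seq_len(nSpecies))
  tree
}

#' Simulate a Brownian-motion trait on a tree
#'
#' Temperature (or any continuous trait) evolved by Brownian motion along
#' branches, optionally clamped to a biological interval.
#'
#' @param tree a \code{phylo} with positive branch lengths.
#' @param rootValue trait value at the root.
#' @param sigma2 BM rate (trait-units^2 per unit branch).
#' @param seed integer seed.
#' @param clamp optional length-2 interval.
#' @return Named numeric vector, species -> trait value.
#' @export
simulateBmTrait <- function(tree, rootValue = 50, sigma2 = 100, seed = 1L,
                            clamp = NULL) {
  set.seed(as.integer(seed))
  x <- phytools::fastBM(tree, a = rootValue, sig2 = sigma2)
  if (!is.null(clamp)) x <- pmin(pmax(x, clamp[1]), clamp[2])
  x[tree$tip.label]
}

## tilt the baseline so expected ERK = baseline ERK + beta * (T - Troot):
## mass m = beta*dT/200 moves from the depleted to the enriched set,
## spread proportionally to the baseline frequencies within each set
tiltedFrequencies <- function(config, temperature) {
  f <- config$baselineFrequencies
  m <- config$beta * (temperature - config$rootTemperature) / 200
  f[ERK_PLUS] <- f[ERK_PLUS] + m * f[ERK_PLUS] / sum(f[ERK_PLUS])
  f[ERK_MINUS] <- f[ERK_MINUS] - m * f[ERK_MINUS] / sum(f[ERK_MINUS])
  if (any(f < 0))
    stop("tilt drives a frequency negative; beta too large for this ",
         "temperature span")
  f
}

#' Simulate one species' proteome at a given temperature
#'
#' Residues are drawn i.i.d. from the baseline frequency vector tilted so
#' that the expected ERK equals baseline ERK + beta * (T - rootTemperature):
#' probability mass moves from the ERK-depleted set {D,N,Q,T,S,H,A} to the
#' enriched set {E,R,K}, proportionally to the baseline frequencies within
#' each set. ERK is a pure composition statistic, so i.i.d. sampling (no
#' site heterogeneity, no ordering structure) is sufficient.
#'
#' @param temperature species temperature, degrees C.
#' @param config a \code{\link{generatorConfig}}.
#' @param seed integer seed (defaults to the config seed).
#' @param prefix protein id prefix.
#' @return List: \code{proteome} (\code{AAStringSet}), \code{expectedErk}
#'   (pp), \code{frequencies} (the tilted vector).
#' @export
simulateProteome <- function(temperature, config, seed = config$seed,
                             prefix = "p") {
  f <- tiltedFrequencies(config, temperature)
  set.seed(as.integer(seed))
  n <- config$proteinsPerSpecies
  lens <- sample(seq(config$lengthRange[1], config$lengthRange[2]), n,
                 replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(AA20, L, replace = TRUE, prob = f), collapse = ""),
    character(1))
  names(seqs) <- paste0(prefix, seq_len(n))
  list(proteome = Biostrings::AAStringSet(seqs),
       expectedErk = erkScore(f),
       frequencies = f)
}

## synonymous codons for each amino acid, split by third-position base class
codonChoices <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    code <- Biostrings::GENETIC_CODE
    sense <- code[code != "*"]
    byAA <- split(names(sense), unname(sense))
    cache <<- lapply(byAA, function(codons) {
      third <- substr(codons, 3, 3)
      list(gc = codons[third %in% c("G", "C")],
           at = codons[third %in% c("A", "T")])
    })
    cache
  }
})

#' Simulate coding sequences with controlled GC3
#'
#' For each residue, a synonymous codon is chosen: with probability
#' \code{gc3} from the codons ending in G/C, otherwise from those ending in
#' A/T (uniformly within the chosen set; residues whose codons offer only
#' one class use that class). Translation round-trips exactly.
#'
#' @param proteome \code{AAStringSet} or named character vector of proteins
#'   (standard 20 letters only).
#' @param gc3 third-position G/C probability, in (0, 1); 1 and 0 are
#'   accepted as degenerate limits.
#' @param seed integer seed.
#' @return \code{DNAStringSet} with the same names.
#' @export
simulateCds <- function(proteome, gc3 = 0.5, seed = 1L) {
  seqs <- asSequenceVector(proteome)
  choices <- codonChoices()
  set.seed(as.integer(seed))
  cds <- vapply(seqs, function(s) {
    aa <- strsplit(s, "", fixed = TRUE)[[1]]
    if (any(!aa %in% AA20))
      stop("proteome contains non-standard letters; cannot back-translate")
    picks <- vapply(aa, function(a) {
      ch <- choices[[a]]
      pool <- if (!length(ch$gc)) ch$at
              else if (!length(ch$at)) ch$gc
              else if (stats::runif(1) < gc3) ch$gc else ch$at
      if (length(pool) == 1L) pool else sample(pool, 1L)
    }, character(1))
    paste(picks, collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(cds)
}

#' Simulate a diverged ortholog panel with known truth
#'
#' Each gene family descends from a single ancestral protein evolved along
#' the species tree: on every branch each site substitutes with probability
#' 1 - exp(-rate * length), the replacement drawn from the baseline
#' frequencies. Tip sequences form the per-species proteomes; the true
#' ortholog map and all-against-all hit tables (ungapped identity scores,
#' bit score proportional to matches, e-value a deterministic decreasing
#' function of score) are returned so recovery can be checked against
#' construction.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param nGenes gene families to simulate.
#' @param hitPairs either \code{"all"} (every unordered species pair; the
#'   default for panels of up to 8 species) or \code{"reference"} (species
#'   s1 against every other species).
#' @return List: \code{tree}, \code{temperatures}, \code{proteomes} (named
#'   list of \code{AAStringSet}), \code{cds} (named list of
#'   \code{DNAStringSet}), \code{orthologMap} (data.frame gene, species,
#'   proteinId), \code{hitTables} (nested list, [[A]][[B]]), \code{config}.
#' @export
simulateOrthologPanel <- function(config = generatorConfig(), nGenes = 50,
                                  hitPairs = NULL) {
  seed <- config$seed
  tree <- simulateTree(config$nSpecies, config$birthRate, seed = seed)
  temps <- simulateBmTrait(tree, config$rootTemperature, config$sigma2,
                           seed = seed + 1L, clamp = config$clamp)
  spp <- tree$tip.label
  if (is.null(hitPairs))
    hitPairs <- if (length(spp) <= 8) "all" else "reference"

  set.seed(seed + 2L)
  lens <- sample(seq(config$lengthRange[1], config$lengthRange[2]), nGenes,
                 replace = TRUE)
  f <- config$baselineFrequencies
  rate <- config$substitutionRate

  tree2 <- stats::reorder(tree, "cladewise")
  nTip <- length(spp)
  root <- nTip + 1L
  tipSeqs <- vector("list", nGenes)
  for (g in seq_len(nGenes)) {
    L <- lens[g]
    nodeSeq <- vector("list", nTip + tree2$Nnode)
    nodeSeq[[root]] <- sample(AA20, L, replace = TRUE, prob = f)
    for (e in seq_len(nrow(tree2$edge))) {
      parent <- tree2$edge[e, 1]; child <- tree2$edge[e, 2]
      s <- nodeSeq[[parent]]
      pSub <- 1 - exp(-rate * tree2$edge.length[e])
      hit <- stats::runif(L) < pSub
      if (any(hit)) s[hit] <- sample(AA20, sum(hit), replace = TRUE, prob = f)
      nodeSeq[[child]] <- s
    }
    tipSeqs[[g]] <- nodeSeq[seq_len(nTip)]
  }

  proteomes <- lapply(seq_len(nTip), function(i) {
    seqs <- vapply(seq_len(nGenes),
                   function(g) paste(tipSeqs[[g]][[i]], collapse = ""),
                   character(1))
    names(seqs) <- paste0(spp[i], "_g", seq_len(nGenes))
    Biostrings::AAStringSet(seqs)
  })
  names(proteomes) <- spp

  cds <- lapply(seq_len(nTip), function(i)
    simulateCds(proteomes[[i]], gc3 = config$gc3, seed = seed + 10L + i))
  names(cds) <- spp

  orthologMap <- data.frame(
    gene = rep(paste0("g", seq_len(nGenes)), each = nTip),
    species = rep(spp, nGenes),
    proteinId = paste0(rep(spp, nGenes), "_g",
                       rep(seq_len(nGenes), each = nTip)),
    stringsAsFactors = FALSE)

  pairIdx <- if (identical(hitPairs, "all")) {
    utils::combn(seq_len(nTip), 2, simplify = FALSE)
  } else {
    lapply(seq.int(2L, nTip), function(i) c(1L, i))
  }
  hitTables <- list()
  for (pr in pairIdx) {
    a <- spp[pr[1]]; b <- spp[pr[2]]
    tabAB <- tabBA <- vector("list", nGenes * nGenes)
    r <- 0L
    for (ga in seq_len(nGenes)) {
      sa <- tipSeqs[[ga]][[pr[1]]]
      for (gb in seq_len(nGenes)) {
        sb <- tipSeqs[[gb]][[pr[2]]]
        L <- min(length(sa), length(sb))
        matches <- sum(sa[seq_len(L)] == sb[seq_len(L)])
        bits <- 2 * matches
        ev <- max(10^(-matches / 2), 1e-180)
        r <- r + 1L
        tabAB[[r]] <- data.frame(
          query = paste0(a, "_g", ga), subject = paste0(b, "_g", gb),
          pident = 100 * matches / L, length = L, evalue = ev,
          bitscore = bits, stringsAsFactors = FALSE)
        tabBA[[r]] <- data.frame(
          query = paste0(b, "_g", gb), subject = paste0(a, "_g", ga),
          pident = 100 * matches / L, length = L, evalue = ev,
          bitscore = bits, stringsAsFactors = FALSE)
      }
    }
    if (is.null(hitTables[[a]])) hitTables[[a]] <- list()
    if (is.null(hitTables[[b]])) hitTables[[b]] <- list()
    hitTables[[a]][[b]] <- do.call(rbind, tabAB)
    hitTables[[b]][[a]] <- do.call(rbind, tabBA)
  }

  list(tree = tree, temperatures = temps, proteomes = proteomes, cds = cds,
       orthologMap = orthologMap, hitTables = hitTables, config = config)
}

#' Simulate a species panel for the composition pipeline
#'
#' Convenience wrapper producing exactly what
#' \code{\link{runProkaryoteAnalysis}} consumes: a Yule tree, BM
#' temperatures, one i.i.d. tilted proteome per species, and a trait table
#' with OGT group labels.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @return List: \code{tree}, \code{traits} (data.frame species,
#'   temperature, group), \code{proteomes} (named list), \code{expectedErk}
#'   (named numeric), \code{config}.
#' @export
simulateSpeciesPanel <- function(config = generatorConfig()) {
  seed <- config$seed
  tree <- simulateTree(config$nSpecies, config$birthRate, seed = seed)
  temps <- simulateBmTrait(tree, config$rootTemperature, config$sigma2,
                           seed = seed + 1L, clamp = config$clamp)
  spp <- tree$tip.label
  sims <- lapply(seq_along(spp), function(i)
    simulateProteome(temps[i], config, seed = seed + 100L + i,
                     prefix = paste0(spp[i], "_p")))
  proteomes <- lapply(sims, `[[`, "proteome")
  names(proteomes) <- spp
  list(tree = tree,
       traits = data.frame(species = spp, temperature = unname(temps),
                           group = ogtGroup(temps), stringsAsFactors = FALSE),
       proteomes = proteomes,
       expectedErk = setNames(vapply(sims, `[[`, numeric(1), "expectedErk"), spp),
       config = config)
}
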