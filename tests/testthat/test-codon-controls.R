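test_that("codon back-mapping follows alignment columns and drops gaps", {
  cpa <- backmapCodons("ME", "ME", "ATGGAA", "ATGGAG")
  expect_equal(codonsA(cpa), c("ATG", "GAA"))
  expect_equal(codonsB(cpa), c("ATG", "GAG"))

  gapped <- backmapCodons("M-E", "MKE", "ATGGAA", "ATGAAAGAG")
  expect_equal(length(gapped), 2)
  expect_equal(codonsB(gapped), c("ATG", "GAG"))
  expect_equal(gapped@nDropped, 1L)

  ## terminal stop in the CDS is tolerated
  stop1 <- backmapCodons("ME", "ME", "ATGGAATAA", "ATGGAG")
  expect_equal(length(stop1), 2)

  expect_error(backmapCodons("ME", "ME", "ATGGAT", "ATGGAG"),
               "mismatch on side A at residue index 2")
  expect_error(backmapCodons("MEK", "MEK", "ATGGAA", "ATGGAGAAA"),
               "encodes 2 residues")
})

test_that("ambiguous-base columns are dropped and counted", {
  ## a codon with N translates to X; it must be annotated X in the protein,
  ## and the N-containing column is then excluded from the codon pairs
  cpa <- backmapCodons("MX", "ME", "ATGGAN", "ATGGAG")
  expect_equal(length(cpa), 1)
  expect_equal(cpa@nDropped, 1L)
  ## a CDS that truly encodes a different residue is a hard error
  expect_error(backmapCodons("ME", "ME", "ATGGAN", "ATGGAG"), "mismatch")
})

test_that("matched filters keep exactly the equal-count pairs", {
  cpa <- new("CodonPairAlignment", id = "g",
             codonsA = c("GAA", "GAA", "AAA"),
             codonsB = c("GAT", "GAG", "AAA"),
             nDropped = 0L)
  gc <- matchedCodonFilter(cpa, "gc_neutral")
  ## (GAA,GAT): GC 1 vs 1 kept; (GAA,GAG): 1 vs 2 dropped; identical kept
  expect_equal(codonsA(gc), c("GAA", "AAA"))
  pur <- matchedCodonFilter(cpa, "purine_neutral")
  ## purines: (GAA,GAT) 3 vs 2 dropped; (GAA,GAG) 3 vs 3 kept
  expect_equal(codonsB(pur), c("GAG", "AAA"))
})

test_that("filters satisfy their invariants exhaustively and under concat", {
  set.seed(29)
  sense <- allSenseCodons()
  cpa <- new("CodonPairAlignment", id = "r",
             codonsA = sample(sense, 300, replace = TRUE),
             codonsB = sample(sense, 300, replace = TRUE), nDropped = 0L)
  for (mode in c("gc_neutral", "purine_neutral")) {
    filt <- matchedCodonFilter(cpa, mode)
    counts <- if (mode == "gc_neutral") gcCounts(filt) else purineCounts(filt)
    expect_true(all(counts[, "A"] == counts[, "B"]))
    ## idempotent
    expect_equal(codonsA(matchedCodonFilter(filt, mode)), codonsA(filt))
  }
  ## commutes with concatenation
  half1 <- new("CodonPairAlignment", id = "r", codonsA = codonsA(cpa)[1:150],
               codonsB = codonsB(cpa)[1:150], nDropped = 0L)
  half2 <- new("CodonPairAlignment", id = "r", codonsA = codonsA(cpa)[151:300],
               codonsB = codonsB(cpa)[151:300], nDropped = 0L)
  f1 <- matchedCodonFilter(half1, "gc_neutral")
  f2 <- matchedCodonFilter(half2, "gc_neutral")
  fAll <- matchedCodonFilter(cpa, "gc_neutral")
  expect_equal(c(codonsA(f1), codonsA(f2)), codonsA(fAll))
})

test_that("matched ERK translates the retained codons on both sides", {
  same <- backmapCodons("MEK", "MEK", "ATGGAAAAA", "ATGGAGAAG")
  r <- matchedErk(same)
  expect_equal(r$erkA, r$erkB)

  ed <- new("CodonPairAlignment", id = "x", codonsA = "GAA", codonsB = "GAT",
            nDropped = 0L)
  r2 <- matchedErk(ed)
  expect_equal(r2$erkA, 100)   # E
  expect_equal(r2$erkB, -100)  # D

  empty <- new("CodonPairAlignment", id = "e", codonsA = character(0),
               codonsB = character(0), nDropped = 0L)
  expect_error(matchedErk(empty), "skipped")
})

test_that("GC-borne ERK differences vanish on GC-neutral codons", {
  ## construct orthologs whose only systematic difference is E (GAG) in A vs
  ## D (GAT) in B -- a GC-changing move, so the gc_neutral filter removes it;
  ## remaining columns are balanced noise with equal GC
  set.seed(37)
  sense <- allSenseCodons()
  gcOf <- function(cod) vapply(strsplit(cod, ""), function(ch)
    sum(ch %in% c("G", "C")), integer(1))
  diffs <- vapply(1:60, function(g) {
    shared <- sample(sense, 40, replace = TRUE)
    ## balanced GC-matched noise: random equal-GC codon pairs
    noiseA <- sample(sense, 10, replace = TRUE)
    noiseB <- vapply(noiseA, function(cA) {
      pool <- sense[gcOf(sense) == gcOf(cA)]
      sample(pool, 1)
    }, character(1))
    cpa <- new("CodonPairAlignment", id = paste0("g", g),
               codonsA = c(shared, rep("GAG", 8), noiseA),
               codonsB = c(shared, rep("GAT", 8), noiseB),
               nDropped = 0L)
    filt <- matchedCodonFilter(cpa, "gc_neutral")
    ## the systematic E/D columns must all be gone
    stopifnot(!any(codonsA(filt) == "GAG" & codonsB(filt) == "GAT"))
    r <- matchedErk(filt)
    r$erkA - r$erkB
  }, numeric(1))
  nz <- diffs[abs(diffs) > 1e-9]
  p <- if (length(nz)) binom.test(sum(nz > 0), length(nz))$p.value else 1
  expect_gt(p, 0.05)
})

test_that("an amino-acid-level ERK gap survives GC-neutral filtering", {
  ## here the E/D difference is encoded GC-neutrally (GAA vs GAT), so the
  ## filter keeps it and the per-gene paired test stays strongly significant
  set.seed(41)
  sense <- allSenseCodons()
  n <- 500
  erks <- t(vapply(seq_len(n), function(g) {
    shared <- sample(sense, 30, replace = TRUE)
    nE <- 3 + sample(0:3, 1)
    cpa <- new("CodonPairAlignment", id = paste0("g", g),
               codonsA = c(shared, rep("GAA", nE)),
               codonsB = c(shared, rep("GAT", nE)),
               nDropped = 0L)
    filt <- matchedCodonFilter(cpa, "gc_neutral")
    r <- matchedErk(filt)
    c(r$erkA, r$erkB)
  }, numeric(2)))
  p <- wilcox.test(erks[, 1], erks[, 2], paired = TRUE, exact = FALSE)$p.value
  expect_lt(p, 0.01)
  expect_gt(mean(erks[, 1] - erks[, 2]), 0)
})
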