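## Independent oracles, deliberately naive: enumeration and closed forms
## that the implementation under test never calls.

## Exact two-sided rank-sum p by full enumeration of group assignments.
## Only valid for tie-free samples; exact by construction.
enumWilcoxonP <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  ranks <- rank(c(x, y))
  obs <- sum(ranks[seq_len(n1)])
  all1 <- combn(n, n1)
  sums <- colSums(matrix(rank(seq_len(n))[all1], nrow = n1))
  ## two-sided: distance of the rank sum from its mean
  mu <- n1 * (n + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

## Optimal global alignment score by exhaustive enumeration of all gapped
## alignments (affine penalties), for very short sequences only.
bruteForceAlignScore <- function(a, b, mat, gapOpen = 11, gapExtend = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  best <- -Inf
  ## state: (i, j, score, prevMove); moves: M(atch), I(nsert in a), D
  recur <- function(i, j, score, prev) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(a) && j <= length(b))
      recur(i + 1, j + 1, score + mat[a[i], b[j]], "M")
    if (i <= length(a)) {
      pen <- if (prev == "D") gapExtend else gapOpen + gapExtend
      recur(i + 1, j, score - pen, "D")
    }
    if (j <= length(b)) {
      pen <- if (prev == "I") gapExtend else gapOpen + gapExtend
      recur(i, j + 1, score - pen, "I")
    }
  }
  recur(1L, 1L, 0, "start")
  best
}

## Score an aligned pair under the same affine scheme (to check optimality
## of a returned alignment, not just its score).
scoreAlignment <- function(alnA, alnB, mat, gapOpen = 11, gapExtend = 1) {
  a <- strsplit(alnA, "")[[1]]; b <- strsplit(alnB, "")[[1]]
  stopifnot(length(a) == length(b))
  score <- 0; prev <- "none"
  for (k in seq_along(a)) {
    if (a[k] == "-" || b[k] == "-") {
      cur <- if (a[k] == "-") "I" else "D"
      score <- score - gapExtend - if (prev == cur) 0 else gapOpen
      prev <- cur
    } else {
      score <- score + mat[a[k], b[k]]
      prev <- "M"
    }
  }
  score
}

## Hand-executed Felsenstein recursion for the fixed 3-leaf tree
## ((A:1,B:1):1,C:2); traits A=3, B=1, C=0:
##   inner node: contrast (3-1)/sqrt(2), value 2, branch 1 + 1/2
##   root:       contrast (2-0)/sqrt(1.5 + 2)
THREE_LEAF_CONTRASTS <- c(inner = 2 / sqrt(2), root = 2 / sqrt(3.5))

## random tie-free sample pair generator
randomTieFreePair <- function(n1, n2) {
  repeat {
    v <- round(rnorm(n1 + n2), 3)
    if (!anyDuplicated(v)) break
  }
  list(x = v[seq_len(n1)], y = v[-seq_len(n1)])
}

## random protein string over the 20 standard letters
randomProtein <- function(n) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"), n, replace = TRUE),
        collapse = "")
}

## all 61 sense codons (for exhaustive codon-filter checks)
allSenseCodons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}
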