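## Residue sets behind the two composition statistics.
## ERK: enriched at high temperature (E,R,K) minus depleted (D,N,Q,T,S,H,A).
## CvP: charged (D,E,R,K) minus polar-uncharged (N,Q,T,S).
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
ERK_PLUS  <- c("E", "R", "K")
ERK_MINUS <- c("D", "N", "Q", "T", "S", "H", "A")
CVP_PLUS  <- c("D", "E", "R", "K")
CVP_MINUS <- c("N", "Q", "T", "S")

## amino acids whose codons are AT-rich vs GC-rich (FYMINK/GARP dichotomy)
FYMINK <- c("F", "Y", "M", "I", "N", "K")
GARP   <- c("G", "A", "R", "P")

## ambiguity letters tolerated in protein input but excluded from counting
AA_SKIP <- c("X", "B", "Z", "U", "*")

## count occurrences of `bases` in each element of a codon vector
countBases <- function(codons, bases) {
  if (!length(codons)) return(integer(0))
  chars <- strsplit(codons, "", fixed = TRUE)
  vapply(chars, function(ch) sum(ch %in% bases), integer(1))
}

## standard-code translation; codons containing non-ACGT bases give "X"
translateCodons <- function(codons) {
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  aa
}

## split an in-frame CDS string into codons
splitCodons <- function(sequence) {
  n <- nchar(sequence)
  if (n %% 3L != 0L)
    stop("CDS length (", n, ") is not divisible by 3")
  if (n == 0L) return(character(0))
  substring(sequence, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

## coerce AAStringSet / DNAStringSet / character to a named character vector
asSequenceVector <- function(x) {
  if (methods::is(x, "XStringSet")) {
    setNames(as.character(x), names(x))
  } else if (is.character(x)) {
    x
  } else {
    stop("expected a character vector or an XStringSet")
  }
}
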