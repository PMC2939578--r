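#' Read a FASTA file with sequence hygiene checks
#'
#' Wraps Biostrings FASTA parsing and enforces the conventions used
#' throughout the package: record ids are the first whitespace-delimited
#' token of the header, sequences are upper-cased, duplicate ids and empty
#' sequences are errors, and any letter outside the declared alphabet is
#' reported with its record and position.
#'
#' Protein sequences may contain the 20 standard letters plus the ambiguity
#' letters X, B, Z, U and the stop character *; nucleotide sequences are over
#' A, C, G, T, N.
#'
#' @param path path to a FASTA file.
#' @param alphabet \code{"protein"} or \code{"dna"}.
#' @return An \code{AAStringSet} (protein) or \code{DNAStringSet} (dna),
#'   named by record id, in file order.
#' @export
readFasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (any(!nzchar(ids))) stop("record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate id '", dup[1], "' in ", path)
  seqs <- toupper(as.character(raw))
  if (any(!nzchar(seqs)))
    stop("empty sequence for id '", ids[which(!nzchar(seqs))[1]], "'")
  allowed <- if (alphabet == "protein") c(AA20, AA_SKIP) else c("A", "C", "G", "T", "N")
  pattern <- paste0("[^", gsub("\\*", "\\\\*", paste(allowed, collapse = "")), "]")
  hit <- regexpr(pattern, seqs)
  if (any(hit > 0)) {
    i <- which(hit > 0)[1]
    stop("illegal character '", substr(seqs[i], hit[i], hit[i]),
         "' at position ", hit[i], " in record '", ids[i], "'")
  }
  names(seqs) <- ids
  if (alphabet == "protein") Biostrings::AAStringSet(seqs)
  else Biostrings::DNAStringSet(seqs)
}

#' Write sequences to FASTA
#'
#' @param x \code{XStringSet} or named character vector.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named")
    x <- Biostrings::BStringSet(x)
  }
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Parse a temperature cell of the trait table
#'
#' Cells may carry a representative value followed by a range, e.g.
#' "26 (24- 28)" or "21(18-22)"; the leading value is authoritative. A bare
#' range "24-28" falls back to the midpoint.
#' @noRd
parseTemperature <- function(cell) {
  cell <- trimws(as.character(cell))
  num <- "[-+]?[0-9]*\\.?[0-9]+"
  ## leading value, optionally followed by a parenthesised range
  m <- regmatches(cell, regexec(paste0("^(", num, ")\\s*(\\(|$)"), cell))[[1]]
  if (length(m) >= 2 && nzchar(m[2])) return(as.numeric(m[2]))
  ## bare range "a-b" -> midpoint
  m <- regmatches(cell, regexec(paste0("^(", num, ")\\s*-\\s*(", num, ")$"), cell))[[1]]
  if (length(m) == 3) return((as.numeric(m[2]) + as.numeric(m[3])) / 2)
  suppressWarnings(as.numeric(cell))
}

#' Classify a prokaryote by optimal growth temperature
#'
#' Hyperthermophile: OGT >= 80 C; thermophile: 50-80 C; mesophile: <= 50 C.
#'
#' @param temperature numeric vector of OGT in degrees Celsius.
#' @return Character vector of group labels.
#' @examples
#' ogtGroup(c(85, 60, 30))
#' @export
ogtGroup <- function(temperature) {
  ifelse(temperature >= 80, "hyperthermophile",
         ifelse(temperature > 50, "thermophile", "mesophile"))
}

#' Read a species trait table
#'
#' Tab-separated with a header containing at least \code{species} and
#' \code{temperature}; an optional \code{group} column carries life-style
#' labels (e.g. endotherm/ectotherm). Temperature cells may include a range
#' ("26 (24- 28)"); the leading representative value is used. When no group
#' column is present, prokaryotic OGT classes are derived from the
#' temperature thresholds.
#'
#' Extra columns (e.g. precomputed composition statistics) are carried
#' through unchanged.
#'
#' @param path path to the TSV file.
#' @param groupScheme \code{"auto"} (use the group column if present, else
#'   derive OGT classes), \code{"ogt"} (always derive), or \code{"asis"}
#'   (never derive; group NA when absent).
#' @return data.frame with columns species (character), temperature
#'   (numeric), group (character), plus any extra input columns.
#' @export
readTraitTable <- function(path, groupScheme = c("auto", "ogt", "asis")) {
  groupScheme <- match.arg(groupScheme)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ## standardize the three core columns case-insensitively; keep the rest
  core <- match(c("species", "temperature", "group"), tolower(names(tab)))
  names(tab)[core[!is.na(core)]] <-
    c("species", "temperature", "group")[!is.na(core)]
  if (!all(c("species", "temperature") %in% names(tab)))
    stop("trait table must have 'species' and 'temperature' columns")
  temps <- vapply(seq_len(nrow(tab)), function(i) {
    t <- parseTemperature(tab$temperature[i])
    if (is.na(t))
      stop("non-numeric temperature '", tab$temperature[i], "' at row ", i)
    t
  }, numeric(1))
  if (anyDuplicated(tab$species))
    stop("duplicate species '", tab$species[duplicated(tab$species)][1], "'")
  out <- tab
  out$species <- as.character(tab$species)
  out$temperature <- temps
  if (groupScheme == "ogt" || (groupScheme == "auto" && is.null(tab$group))) {
    out$group <- ogtGroup(temps)
  } else if (is.null(tab$group)) {
    out$group <- NA_character_
  }
  out
}

#' Read a tabular similarity (BLAST outfmt-6 style) hit table
#'
#' Accepts the full 12-column tabular dialect (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore) or a reduced
#' 6-column dialect (qseqid sseqid pident length evalue bitscore). Multiple
#' HSPs for the same (query, subject) pair are reduced to the single best
#' row: highest bit score, ties broken by lowest e-value, then first
#' occurrence. Bit score is the standard reciprocal-best-hit criterion
#' because it is independent of database size.
#'
#' @param path path to the tab-separated file; an empty file yields an empty
#'   table.
#' @return data.frame with columns query, subject, pident, length, evalue,
#'   bitscore — at most one row per (query, subject) pair.
#' @export
readHitTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  empty <- data.frame(query = character(0), subject = character(0),
                      pident = numeric(0), length = integer(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (!all(nf == nf[1]) || !(nf[1] %in% c(6L, 12L))) {
    bad <- which(nf != nf[1] | !(nf %in% c(6L, 12L)))[1]
    stop("malformed hit-table row at line ", bad,
         " (expected 6 or 12 tab-separated columns, found ", nf[bad], ")")
  }
  cols <- if (nf[1] == 12L) c(1L, 2L, 3L, 4L, 11L, 12L) else 1:6
  mat <- do.call(rbind, fields)[, cols, drop = FALSE]
  tab <- data.frame(query = mat[, 1], subject = mat[, 2],
                    pident = as.numeric(mat[, 3]),
                    length = as.integer(mat[, 4]),
                    evalue = as.numeric(mat[, 5]),
                    bitscore = as.numeric(mat[, 6]),
                    stringsAsFactors = FALSE)
  if (anyNA(tab$evalue) || anyNA(tab$bitscore)) {
    bad <- which(is.na(tab$evalue) | is.na(tab$bitscore))[1]
    stop("malformed hit-table row at line ", bad, ": non-numeric score field")
  }
  if (any(tab$evalue < 0)) stop("negative e-value in hit table")
  reduceHitTable(tab)
}

## best HSP per (query, subject): max bitscore, then min evalue, then first
reduceHitTable <- function(tab) {
  if (!nrow(tab)) return(tab)
  ord <- order(tab$query, tab$subject, -tab$bitscore, tab$evalue,
               seq_len(nrow(tab)))
  tab <- tab[ord, , drop = FALSE]
  keep <- !duplicated(paste(tab$query, tab$subject, sep = "\r"))
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
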