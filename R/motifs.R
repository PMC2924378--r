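AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Parse a minimotif consensus pattern
#'
#' Grammar, case-insensitive: each position is a single amino-acid letter,
#' `x` for a wildcard (any of the 20 canonical residues), or a bracketed
#' alternative set such as `[ST]`. Non-canonical residue codes (B, J, O, U,
#' Z) are rejected in patterns and never matched in sequences.
#'
#' @param text Pattern string, e.g. `"yytm"` or `"[ST]P"`.
#' @return A `motif_pattern`: list with `classes` (one character vector of
#'   admissible residues per position), `text` (canonical uppercase form)
#'   and `length`.
#' @examples
#' parse_pattern("[ST]Pxx")
#' @export
parse_pattern <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text)) {
    stop("empty or invalid motif pattern")
  }
  chars <- strsplit(toupper(text), "")[[1]]
  classes <- list()
  canon <- character()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)
      if (!length(close)) stop("unbalanced bracket in motif pattern: ", text)
      close <- close[1]
      members <- chars[(i + 1L):(close - 1L)]
      if (!length(members) || close == i + 1L) {
        stop("empty bracket class in motif pattern: ", text)
      }
      if (!all(members %in% AA20)) {
        stop("non-amino-acid letter in motif pattern: ", text)
      }
      members <- unique(members)
      classes[[length(classes) + 1L]] <- members
      canon <- c(canon, paste0("[", paste(sort(members), collapse = ""), "]"))
      i <- close + 1L
    } else if (ch == "]") {
      stop("unbalanced bracket in motif pattern: ", text)
    } else if (ch == "X") {
      classes[[length(classes) + 1L]] <- AA20
      canon <- c(canon, "x")
      i <- i + 1L
    } else if (ch %in% AA20) {
      classes[[length(classes) + 1L]] <- ch
      canon <- c(canon, ch)
      i <- i + 1L
    } else {
      stop("non-amino-acid letter '", ch, "' in motif pattern: ", text)
    }
  }
  structure(list(classes = classes, text = paste(canon, collapse = ""),
                 length = length(classes)),
            class = "motif_pattern")
}

.as_pattern <- function(pattern) {
  if (inherits(pattern, "motif_pattern")) pattern else parse_pattern(pattern)
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("motif_pattern:", x$text, "(", x$length, "positions )\n")
  invisible(x)
}

#' Scan a protein sequence for pattern matches
#'
#' Reports every (possibly overlapping) match of the consensus pattern, in
#' ascending 1-based start order. Residues outside the 20 canonical letters
#' never match any position class.
#'
#' @param sequence Amino-acid sequence string.
#' @param pattern A `motif_pattern` or pattern string.
#' @return Data frame with columns `start` (1-based inclusive) and
#'   `matched` (the matching substring).
#' @examples
#' scan_motif("ACACA", "ACA")
#' @export
scan_motif <- function(sequence, pattern) {
  pattern <- .as_pattern(pattern)
  sequence <- toupper(sequence)
  rx <- paste0("(?=", paste(vapply(pattern$classes, function(cl) {
    if (length(cl) == 1L) cl else paste0("[", paste(cl, collapse = ""), "]")
  }, ""), collapse = ""), ")")
  starts <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  starts <- as.integer(starts[starts > 0L])
  data.frame(start = starts,
             matched = if (length(starts))
               substring(sequence, starts, starts + pattern$length - 1L)
             else character(),
             stringsAsFactors = FALSE)
}

#' Uniform amino-acid background
#'
#' @return Named numeric vector: probability 1/20 for each canonical
#'   residue.
#' @export
uniform_background <- function() {
  stats::setNames(rep(1 / 20, 20), AA20)
}

.check_background <- function(bg) {
  if (!is.numeric(bg) || is.null(names(bg)) || !setequal(names(bg), AA20)) {
    stop("background must be a numeric vector named by the 20 canonical amino acids")
  }
  if (any(bg < 0) || any(bg > 1) || abs(sum(bg) - 1) > 1e-9) {
    stop("background frequencies must lie in [0,1] and sum to 1")
  }
  bg
}

#' Probability that one random window matches the pattern
#'
#' Product over positions of the summed background frequencies of the
#' position's residue class; in (0, 1].
#'
#' @param pattern A `motif_pattern` or pattern string.
#' @param background Named background frequencies (default uniform 1/20).
#' @return Match probability.
#' @export
match_probability <- function(pattern, background = uniform_background()) {
  pattern <- .as_pattern(pattern)
  background <- .check_background(background)
  prod(vapply(pattern$classes, function(cl) sum(background[cl]), 0))
}

#' Frequency score of a pattern in a protein
#'
#' The expected number of chance occurrences of the pattern in a random
#' sequence of the protein's length under the background composition:
#' `max(L - k + 1, 0) * match_probability`. Low scores mark complex,
#' information-rich motifs; the frequency-score filter retains a motif when
#' its score is at or below a threshold (published thresholds 0.02, 0.03,
#' 0.04).
#'
#' @param pattern A `motif_pattern` or pattern string.
#' @param protein_length Residue count L of the (source) protein.
#' @param background Named background frequencies (default uniform 1/20).
#' @return Expected occurrence count (non-negative).
#' @examples
#' frequency_score("AC", 11)  # 10 windows x (1/20)^2 = 0.025
#' @export
frequency_score <- function(pattern, protein_length,
                            background = uniform_background()) {
  pattern <- .as_pattern(pattern)
  stopifnot(protein_length >= 0)
  max(protein_length - pattern$length + 1, 0) *
    match_probability(pattern, background)
}

#' Read a minimotif table
#'
#' TSV with header columns `source_accession`, `motif`, `activity`,
#' `target_accession`. A pairs-only TSV (`source_accession`,
#' `target_accession`) is also accepted for function-filter-only runs; the
#' missing columns are filled with `NA`.
#'
#' @param file Path to the TSV.
#' @return Data frame with the four minimotif columns.
#' @export
read_minimotifs <- function(file) {
  df <- utils::read.delim(file, header = TRUE, colClasses = "character")
  need <- c("source_accession", "target_accession")
  if (!all(need %in% names(df))) {
    stop("minimotif table must have columns source_accession and target_accession")
  }
  if (is.null(df$motif)) df$motif <- NA_character_
  if (is.null(df$activity)) df$activity <- NA_character_
  df[, c("source_accession", "motif", "activity", "target_accession")]
}

#' Read protein sequences from FASTA
#'
#' @param file Path to an (uncompressed) amino-acid FASTA file.
#' @return Named character vector of sequences, names = accessions (first
#'   whitespace-delimited token of each header).
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readAAStringSet(file)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param sequences Named character vector of amino-acid sequences.
#' @param file Output path.
#' @export
write_fasta <- function(sequences, file) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), file)
  invisible(file)
}
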