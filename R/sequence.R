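#' Reverse complement of a DNA string
#' @param x Character scalar over the DNA alphabet.
#' @return Character scalar.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract the spliced sequence of a transcript
#'
#' Concatenates the requested segments in genomic order and reverse-complements
#' the whole string for minus-strand transcripts, i.e. the result reads 5' to
#' 3' in transcript orientation.
#'
#' @param x An [annotation_set()].
#' @param transcript_id Transcript id.
#' @param genome Named [Biostrings::DNAStringSet] (or named character vector).
#' @param which `"exon"` for cDNA, `"cds"` for the coding sequence.
#' @return Upper-case DNA string.
#' @export
extract_spliced_sequence <- function(x, transcript_id, genome,
                                     which = c("exon", "cds")) {
  which <- match.arg(which)
  parts <- if (which == "exon") transcript_exons(x, transcript_id)
           else transcript_cds(x, transcript_id)
  if (nrow(parts) == 0) {
    abort(paste0("transcript '", transcript_id, "' has no ", which, " segments"))
  }
  splice_intervals(parts$seq_id[1], parts$start, parts$end, parts$strand[1],
                   genome, id = transcript_id)
}

# Core splice-and-orient extraction over 0-based half-open intervals.
splice_intervals <- function(seq_id, starts, ends, strand, genome, id = "?") {
  seq <- genome_sequence(genome, seq_id)
  if (any(starts < 0) || any(ends > length(seq))) {
    abort(paste0("segment out of genome bounds for '", id, "' on ", seq_id))
  }
  ord <- order(starts)
  pieces <- vapply(ord, function(i) {
    as.character(Biostrings::subseq(seq, start = starts[i] + 1L, end = ends[i]))
  }, character(1))
  s <- toupper(paste(pieces, collapse = ""))
  if (identical(strand, "-")) s <- reverse_complement(s)
  s
}

stop_codons <- c("TAA", "TAG", "TGA")

#' Translate a coding sequence
#'
#' Standard genetic code, one symbol per complete codon; stop codons render
#' `"*"`; a codon containing anything outside A/C/G/T (e.g. N) renders `"X"`.
#' A trailing partial codon is ignored with a warning.
#'
#' @param cds_sequence DNA string of length >= 3.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds_sequence) {
  s <- toupper(cds_sequence)
  n <- nchar(s)
  if (n == 0) abort("cannot translate an empty sequence")
  if (n < 3) abort("coding sequence shorter than one codon")
  rem <- n %% 3
  if (rem != 0) {
    warn(paste0("trailing partial codon of ", rem, " base(s) ignored"))
    n <- n - rem
  }
  codons <- substring(s, seq(1, n, 3), seq(3, n, 3))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Longest ATG-initiated, stop-terminated ORF in a spliced sequence.
# Returns c(start, end) 0-based half-open (end past the stop codon), or NULL.
# Ties broken towards the leftmost start.
longest_orf <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  best <- NULL
  for (f in 0:2) {
    if (n - f < 3) next
    m <- (n - f) %/% 3
    starts <- seq(f + 1, by = 3, length.out = m)
    codons <- substring(s, starts, starts + 2)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% stop_codons)
    if (length(atg) == 0 || length(stp) == 0) next
    prev_stop <- 0L
    for (k in stp) {
      a <- atg[atg > prev_stop & atg < k]
      if (length(a) > 0) {
        len <- (k - a[1] + 1L) * 3L
        orf_start <- f + (a[1] - 1L) * 3L
        if (is.null(best) || len > best[3] ||
            (len == best[3] && orf_start < best[1])) {
          best <- c(orf_start, orf_start + len, len)
        }
      }
      prev_stop <- k
    }
  }
  if (is.null(best)) NULL else best[1:2]
}

# Map an interval [from, to) in spliced-transcript coordinates back to genomic
# intervals, given the transcript's exons (0-based, sorted by start) and strand.
spliced_to_genomic <- function(exons, strand, from, to) {
  ord <- if (identical(strand, "-")) order(-exons$start) else order(exons$start)
  starts <- exons$start[ord]; ends <- exons$end[ord]
  out_s <- integer(0); out_e <- integer(0)
  pos <- 0L
  for (i in seq_along(starts)) {
    len <- ends[i] - starts[i]
    lo <- max(from - pos, 0L); hi <- min(to - pos, len)
    if (hi > lo) {
      if (identical(strand, "-")) {
        out_s <- c(out_s, ends[i] - hi); out_e <- c(out_e, ends[i] - lo)
      } else {
        out_s <- c(out_s, starts[i] + lo); out_e <- c(out_e, starts[i] + hi)
      }
    }
    pos <- pos + len
  }
  o <- order(out_s)
  tibble(start = out_s[o], end = out_e[o])
}
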