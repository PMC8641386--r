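#' Read a genome from FASTA
#'
#' Sequence names are trimmed to the first whitespace-delimited token and
#' residues are stored upper-case.
#'
#' @param path FASTA file path.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g))) abort("duplicated sequence names in FASTA")
  if (any(Biostrings::width(g) < 1)) abort("zero-length sequence in FASTA")
  Biostrings::DNAStringSet(toupper(g))
}

#' Write a genome to FASTA (wrapped at 60 columns)
#'
#' @param genome A named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(genome, path, width = 60L)
  invisible(path)
}

# Accept a named character vector or DNAStringSet.
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && !is.null(names(genome))) {
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  abort("genome must be a named DNAStringSet or named character vector")
}

genome_sequence <- function(genome, seq_id) {
  genome <- as_genome(genome)
  if (!seq_id %in% names(genome)) {
    abort(paste0("sequence '", seq_id, "' not present in genome"))
  }
  genome[[seq_id]]
}
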