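validation_flags <- c("MISSING_FEATURE", "CDS_NOT_MULTIPLE_OF_THREE",
                      "PREMATURE_STOP", "MISSING_START", "MISSING_STOP",
                      "OUT_OF_BOUNDS", "CDS_OUTSIDE_EXON")

#' Structural and coding checks for one gene model
#'
#' Flags the error classes that make a gene model an interrupted ORF or a
#' formatting problem:
#'
#' * `MISSING_FEATURE` - a transcript lacks exons or CDS segments.
#' * `OUT_OF_BOUNDS` - a segment extends beyond its genome sequence.
#' * `CDS_OUTSIDE_EXON` - a CDS segment is not contained in a single exon.
#' * `CDS_NOT_MULTIPLE_OF_THREE` - total CDS length mod 3 is non-zero.
#' * `PREMATURE_STOP` - translation contains `*` before the final codon.
#' * `MISSING_START` - the first codon is not ATG.
#' * `MISSING_STOP` - the final complete codon is not TAA/TAG/TGA.
#'
#' A multi-transcript gene is flagged if any of its transcripts is flagged.
#'
#' @param x An [annotation_set()].
#' @param gene_id Gene id.
#' @param genome Named [Biostrings::DNAStringSet].
#' @return A list with `gene_id`, `flags` (character vector) and `details`
#'   (named messages).
#' @export
check_gene <- function(x, gene_id, genome) {
  genome <- as_genome(genome)
  g <- filter(x$genes, .data$gene_id == !!gene_id)
  if (nrow(g) == 0) abort(paste0("unknown gene id: ", gene_id))
  if (!g$seq_id %in% names(genome)) {
    abort(paste0("genome is missing sequence '", g$seq_id, "' needed by gene ", gene_id))
  }
  seq_len <- length(genome[[g$seq_id]])
  flags <- character(0)
  details <- list()
  add <- function(flag, msg) {
    flags <<- union(flags, flag)
    details[[flag]] <<- c(details[[flag]], msg)
  }
  txs <- x$transcripts$transcript_id[x$transcripts$gene_id == gene_id]
  if (length(txs) == 0) add("MISSING_FEATURE", paste0(gene_id, ": gene has no transcript"))
  for (t in txs) {
    ex <- transcript_exons(x, t)
    cd <- transcript_cds(x, t)
    if (nrow(ex) == 0) add("MISSING_FEATURE", paste0(t, ": no exons"))
    if (nrow(cd) == 0) {
      add("MISSING_FEATURE", paste0(t, ": no CDS"))
      next
    }
    parts <- bind_rows(ex, cd)
    if (any(parts$start < 0) || any(parts$end > seq_len)) {
      add("OUT_OF_BOUNDS", paste0(t, ": segment beyond [0, ", seq_len, ")"))
      next
    }
    if (nrow(ex) > 0) {
      contained <- vapply(seq_len(nrow(cd)), function(i) {
        any(ex$start <= cd$start[i] & cd$end[i] <= ex$end)
      }, logical(1))
      if (!all(contained)) {
        add("CDS_OUTSIDE_EXON",
            paste0(t, ": ", sum(!contained), " CDS segment(s) outside exons"))
      }
    }
    cds_len <- sum(cd$end - cd$start)
    if (cds_len %% 3L != 0L) {
      add("CDS_NOT_MULTIPLE_OF_THREE", paste0(t, ": CDS length ", cds_len))
    }
    if (cds_len >= 3) {
      dna <- splice_intervals(cd$seq_id[1], cd$start, cd$end, cd$strand[1],
                              genome, id = t)
      aa <- suppressWarnings(translate_cds(dna))
      body <- substr(aa, 1, nchar(aa) - 1)
      if (grepl("*", body, fixed = TRUE)) {
        add("PREMATURE_STOP", paste0(t, ": internal stop at codon ",
                                     regexpr("*", body, fixed = TRUE)[1]))
      }
      if (substr(dna, 1, 3) != "ATG") add("MISSING_START", paste0(t, ": first codon ", substr(dna, 1, 3)))
      last <- substr(dna, 3 * nchar(aa) - 2, 3 * nchar(aa))
      if (!last %in% stop_codons) add("MISSING_STOP", paste0(t, ": final codon ", last))
    }
  }
  list(gene_id = gene_id, flags = flags,
       details = vapply(details, paste, character(1), collapse = "; "))
}

#' Validate every gene of an annotation set
#'
#' @param x An [annotation_set()].
#' @param genome Named [Biostrings::DNAStringSet].
#' @return A `validation_report` tibble with one row per gene: `gene_id`,
#'   `n_flags`, `flags` (comma-joined), `flag_list` (list column), `details`.
#'   Use [glance()] for the per-flag summary counts.
#' @export
validate_set <- function(x, genome) {
  reports <- map(x$genes$gene_id, function(g) check_gene(x, g, genome))
  out <- tibble(
    gene_id = map_chr(reports, "gene_id"),
    n_flags = map_int(reports, function(r) length(r$flags)),
    flags = map_chr(reports, function(r) paste(sort(r$flags), collapse = ",")),
    flag_list = map(reports, "flags"),
    details = map_chr(reports, function(r) paste(r$details, collapse = " | "))
  )
  class(out) <- c("validation_report", class(out))
  out
}

#' @export
glance.validation_report <- function(x, ...) {
  per_flag <- table(factor(unlist(x$flag_list), levels = validation_flags))
  bind_cols(
    tibble(n_genes = nrow(x), n_flagged = sum(x$n_flags > 0)),
    as_tibble(as.list(per_flag))
  )
}

#' @export
tidy.validation_report <- function(x, ...) {
  select(as_tibble(x), "gene_id", "n_flags", "flags", "details")
}

#' Export the error-free subset of an annotation set
#'
#' @param x An [annotation_set()].
#' @param reports A `validation_report` from [validate_set()] for `x`.
#' @param treat_incomplete_as_error Should `MISSING_START`/`MISSING_STOP`
#'   exclude a gene from the clean set? Default `TRUE` (strict evidence
#'   filter: incomplete genes are errors).
#' @return An `annotation_set` containing exactly the unflagged genes, in
#'   their original order.
#' @export
export_clean <- function(x, reports, treat_incomplete_as_error = TRUE) {
  if (!setequal(reports$gene_id, x$genes$gene_id)) {
    abort("validation report does not match the annotation set's gene ids")
  }
  effective <- map_int(reports$flag_list, function(f) {
    if (!treat_incomplete_as_error) f <- setdiff(f, c("MISSING_START", "MISSING_STOP"))
    length(f)
  })
  clean <- reports$gene_id[effective == 0]
  filter_genes(x, clean)
}

#' Write a validation report to TSV
#' @param reports A `validation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_tsv <- function(reports, path) {
  utils::write.table(tidy(reports), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
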