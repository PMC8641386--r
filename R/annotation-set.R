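#' Construct an annotation set
#'
#' An annotation set is the package's core container for a gene -> transcript
#' -> exon/CDS hierarchy. It is a light S3 object holding four tibbles, all in
#' 0-based half-open coordinates:
#'
#' * `genes`: `gene_id`, `seq_id`, `start`, `end`, `strand`, `source`,
#'   `locus_name` (NA until [assign_locus_names()]), `putative_te` (FALSE until
#'   [label_putative_tes()]).
#' * `transcripts`: `transcript_id`, `gene_id`.
#' * `exons`: `transcript_id`, `seq_id`, `start`, `end`, `strand`.
#' * `cds`: `transcript_id`, `seq_id`, `start`, `end`, `strand`, `phase`.
#'
#' @param genes,transcripts,exons,cds Tibbles as described above. Missing
#'   optional columns are filled with defaults.
#' @param version_tag Character tag such as `"3.0"` or `"3.1"`.
#' @param validate Check structural invariants (unique gene ids, sorted
#'   non-overlapping exons, CDS within exons)?
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(genes, transcripts, exons, cds,
                           version_tag = "unversioned", validate = TRUE) {
  genes <- as_tibble(genes)
  if (!"source" %in% names(genes)) genes$source <- "."
  if (!"locus_name" %in% names(genes)) genes$locus_name <- NA_character_
  if (!"putative_te" %in% names(genes)) genes$putative_te <- FALSE
  genes <- genes[, c("gene_id", "seq_id", "start", "end", "strand",
                     "source", "locus_name", "putative_te")]
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  transcripts <- as_tibble(transcripts)[, c("transcript_id", "gene_id")]
  exons <- as_tibble(exons)[, c("transcript_id", "seq_id", "start", "end", "strand")]
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  cds <- as_tibble(cds)
  if (!"phase" %in% names(cds)) cds$phase <- NA_integer_
  cds <- cds[, c("transcript_id", "seq_id", "start", "end", "strand", "phase")]
  cds$start <- as.integer(cds$start); cds$end <- as.integer(cds$end)
  exons <- arrange(exons, .data$transcript_id, .data$start)
  cds <- arrange(cds, .data$transcript_id, .data$start)
  x <- structure(
    list(version_tag = version_tag, genes = genes,
         transcripts = transcripts, exons = exons, cds = cds),
    class = "annotation_set"
  )
  if (validate) validate_annotation_set(x)
  x
}

validate_annotation_set <- function(x) {
  g <- x$genes
  if (anyDuplicated(g$gene_id)) {
    abort(paste0("duplicated gene ids: ",
                 paste(unique(g$gene_id[duplicated(g$gene_id)]), collapse = ", ")))
  }
  if (any(g$start >= g$end)) abort("gene with start >= end")
  if (!all(g$strand %in% c("+", "-", "."))) abort("invalid gene strand symbol")
  if (anyDuplicated(x$transcripts$transcript_id)) abort("duplicated transcript ids")
  if (!all(x$transcripts$gene_id %in% g$gene_id)) abort("transcript with unknown gene id")
  if (nrow(x$exons) > 0 && !all(x$exons$transcript_id %in% x$transcripts$transcript_id)) {
    abort("exon with unknown transcript id")
  }
  if (nrow(x$cds) > 0 && !all(x$cds$transcript_id %in% x$transcripts$transcript_id)) {
    abort("CDS with unknown transcript id")
  }
  # exons of one transcript must be sorted and non-overlapping
  bad <- x$exons |>
    group_by(.data$transcript_id) |>
    summarise(bad = any(.data$start[-1] < .data$end[-length(.data$end)]),
              .groups = "drop") |>
    filter(.data$bad)
  if (nrow(bad) > 0) {
    abort(paste0("overlapping or unsorted exons in transcript(s): ",
                 paste(bad$transcript_id, collapse = ", ")))
  }
  invisible(x)
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> version", x$version_tag, "\n")
  cat("  genes:      ", nrow(x$genes), "\n")
  cat("  transcripts:", nrow(x$transcripts), "\n")
  cat("  exons:      ", nrow(x$exons), "  cds segments:", nrow(x$cds), "\n")
  invisible(x)
}

#' Number of genes in an annotation set
#' @param x An `annotation_set`.
#' @return Integer gene count.
#' @export
n_genes <- function(x) nrow(x$genes)

#' Subset an annotation set to a set of genes
#'
#' Keeps the listed genes (in their current order) together with their
#' transcripts, exons and CDS segments.
#'
#' @param x An `annotation_set`.
#' @param gene_ids Character vector of gene ids to keep.
#' @return An `annotation_set`.
#' @export
filter_genes <- function(x, gene_ids) {
  genes <- filter(x$genes, .data$gene_id %in% gene_ids)
  tx <- filter(x$transcripts, .data$gene_id %in% genes$gene_id)
  annotation_set(
    genes = genes, transcripts = tx,
    exons = filter(x$exons, .data$transcript_id %in% tx$transcript_id),
    cds = filter(x$cds, .data$transcript_id %in% tx$transcript_id),
    version_tag = x$version_tag, validate = FALSE
  )
}

# Bind two annotation sets (gene ids must stay unique).
bind_annotation_sets <- function(x, y) {
  annotation_set(
    genes = bind_rows(x$genes, y$genes),
    transcripts = bind_rows(x$transcripts, y$transcripts),
    exons = bind_rows(x$exons, y$exons),
    cds = bind_rows(x$cds, y$cds),
    version_tag = x$version_tag
  )
}

# Exons of one transcript, sorted by start.
transcript_exons <- function(x, transcript_id) {
  filter(x$exons, .data$transcript_id == !!transcript_id)
}

transcript_cds <- function(x, transcript_id) {
  filter(x$cds, .data$transcript_id == !!transcript_id)
}

# Union of exon intervals over all transcripts of a gene: tibble(start, end).
gene_exon_union <- function(x, gene_id) {
  tx <- x$transcripts$transcript_id[x$transcripts$gene_id == gene_id]
  e <- filter(x$exons, .data$transcript_id %in% tx)
  iv_reduce(e$start, e$end)
}

#' Tidy an annotation set into one feature table
#'
#' @param x An `annotation_set`.
#' @param ... Unused.
#' @return A tibble with one row per feature (`gene`, `mRNA`, `exon`, `CDS`),
#'   0-based half-open coordinates.
#' @export
tidy.annotation_set <- function(x, ...) {
  tx <- left_join(x$transcripts,
                  select(x$genes, "gene_id", "seq_id", "strand"), by = "gene_id")
  tx_span <- x$exons |>
    group_by(.data$transcript_id) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  tx <- left_join(tx, tx_span, by = "transcript_id")
  bind_rows(
    tibble(type = "gene", id = x$genes$gene_id, parent = NA_character_,
           seq_id = x$genes$seq_id, start = x$genes$start, end = x$genes$end,
           strand = x$genes$strand),
    tibble(type = "mRNA", id = tx$transcript_id, parent = tx$gene_id,
           seq_id = tx$seq_id, start = tx$start, end = tx$end, strand = tx$strand),
    tibble(type = "exon", id = NA_character_, parent = x$exons$transcript_id,
           seq_id = x$exons$seq_id, start = x$exons$start, end = x$exons$end,
           strand = x$exons$strand),
    tibble(type = "CDS", id = NA_character_, parent = x$cds$transcript_id,
           seq_id = x$cds$seq_id, start = x$cds$start, end = x$cds$end,
           strand = x$cds$strand)
  ) |> arrange(.data$seq_id, .data$start)
}

#' One-row summary of an annotation set
#' @param x An `annotation_set`.
#' @param ... Unused.
#' @return A one-row tibble with feature counts.
#' @export
glance.annotation_set <- function(x, ...) {
  tibble(
    version_tag = x$version_tag,
    n_genes = nrow(x$genes),
    n_transcripts = nrow(x$transcripts),
    n_exons = nrow(x$exons),
    n_cds_segments = nrow(x$cds),
    n_putative_te = sum(x$genes$putative_te)
  )
}
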