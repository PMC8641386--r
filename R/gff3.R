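# GFF3 I/O. This is the only place 1-based inclusive coordinates appear;
# everything internal is 0-based half-open.

parse_gff3_attributes <- function(s) {
  out <- list()
  if (is.na(s) || s == "." || s == "") return(out)
  for (kv in strsplit(s, ";", fixed = TRUE)[[1]]) {
    kv <- trimws(kv)
    if (kv == "") next
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) next
    out[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  out
}

format_gff3_attributes <- function(...) {
  kv <- list(...)
  kv <- kv[!vapply(kv, function(v) is.null(v) || is.na(v), logical(1))]
  if (length(kv) == 0) return(".")
  paste(paste0(names(kv), "=", unlist(kv)), collapse = ";")
}

# Parse a GFF3 file into a tibble of raw features (0-based half-open).
# Malformed lines abort with the offending line number.
read_gff3_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) {
    return(tibble(seq_id = character(), source = character(), type = character(),
                  start = integer(), end = integer(), score = character(),
                  strand = character(), phase = character(), attributes = list(),
                  line = integer()))
  }
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol != 9)) {
    bad <- keep[which(ncol != 9)[1]]
    abort(paste0("GFF3 parse error at line ", bad, ": expected 9 tab-separated columns, got ",
                 ncol[which(ncol != 9)[1]]))
  }
  m <- matrix(unlist(parts), ncol = 9, byrow = TRUE)
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start1) || anyNA(end1)) {
    bad <- keep[which(is.na(start1) | is.na(end1))[1]]
    abort(paste0("GFF3 parse error at line ", bad, ": non-numeric start/end"))
  }
  if (any(end1 < start1)) {
    bad <- keep[which(end1 < start1)[1]]
    abort(paste0("GFF3 parse error at line ", bad, ": end < start"))
  }
  if (!all(m[, 7] %in% c("+", "-", "."))) {
    bad <- keep[which(!m[, 7] %in% c("+", "-", "."))[1]]
    abort(paste0("GFF3 parse error at line ", bad, ": unknown strand symbol '",
                 m[which(!m[, 7] %in% c("+", "-", "."))[1], 7], "'"))
  }
  tibble(
    seq_id = m[, 1], source = m[, 2], type = m[, 3],
    start = start1 - 1L, end = end1,
    score = m[, 6], strand = m[, 7], phase = m[, 8],
    attributes = lapply(m[, 9], parse_gff3_attributes),
    line = keep
  )
}

#' Read a gene annotation from GFF3
#'
#' Expects the usual gene -> mRNA -> exon/CDS hierarchy via `Parent`
#' attributes. Coordinates are converted from GFF3's 1-based inclusive to the
#' package's 0-based half-open convention. `five_prime_UTR`/`three_prime_UTR`
#' features are counted but not stored; the exon minus CDS difference is
#' authoritative for UTRs. Genes lacking an explicit mRNA child get a
#' synthetic single transcript built from their exon/CDS children, so files
#' with missing features remain loadable for validation.
#'
#' @param path GFF3 file path.
#' @param feature_policy `"lenient"` keeps orphan features (a `Parent` pointing
#'   nowhere) by synthesizing their missing ancestors; `"strict"` aborts with
#'   the offending ids.
#' @param version_tag Version tag stored on the returned set.
#' @return An [annotation_set()]. The per-feature-type counts of the file are
#'   attached as attribute `"feature_counts"` (see [feature_counts()]).
#' @export
read_gff3 <- function(path, feature_policy = c("lenient", "strict"),
                      version_tag = "unversioned") {
  feature_policy <- match.arg(feature_policy)
  feats <- read_gff3_table(path)
  counts <- table(feats$type)
  attr_of <- function(row, key) {
    v <- feats$attributes[[row]][[key]]
    if (is.null(v)) NA_character_ else v
  }
  get_parents <- function(row) {
    p <- feats$attributes[[row]][["Parent"]]
    if (is.null(p)) character(0) else strsplit(p, ",", fixed = TRUE)[[1]]
  }

  gi <- which(feats$type == "gene")
  genes <- tibble(
    gene_id = vapply(gi, attr_of, character(1), key = "ID"),
    seq_id = feats$seq_id[gi], start = feats$start[gi], end = feats$end[gi],
    strand = feats$strand[gi], source = feats$source[gi],
    locus_name = vapply(gi, attr_of, character(1), key = "locus_name"),
    putative_te = !is.na(vapply(gi, attr_of, character(1), key = "putative_te"))
  )
  if (anyNA(genes$gene_id)) {
    abort(paste0("GFF3 parse error at line ",
                 feats$line[gi[which(is.na(genes$gene_id))[1]]],
                 ": gene feature without ID"))
  }

  ti <- which(feats$type %in% c("mRNA", "transcript"))
  tx <- tibble(
    transcript_id = vapply(ti, attr_of, character(1), key = "ID"),
    gene_id = vapply(ti, function(r) {
      p <- get_parents(r)
      if (length(p) == 0) NA_character_ else p[1]
    }, character(1))
  )
  if (anyNA(tx$transcript_id)) {
    abort(paste0("GFF3 parse error at line ",
                 feats$line[ti[which(is.na(tx$transcript_id))[1]]],
                 ": mRNA feature without ID"))
  }
  orphan_tx <- tx$transcript_id[is.na(tx$gene_id) | !tx$gene_id %in% genes$gene_id]
  if (length(orphan_tx) > 0 && feature_policy == "strict") {
    abort(paste0("orphan mRNA feature(s) with missing parent gene: ",
                 paste(orphan_tx, collapse = ", ")))
  }
  # lenient: synthesize one gene per orphan transcript
  tx$gene_id[is.na(tx$gene_id)] <- paste0(tx$transcript_id[is.na(tx$gene_id)], ".gene")
  missing_genes <- setdiff(tx$gene_id, genes$gene_id)

  part_rows <- function(types) {
    idx <- which(feats$type %in% types)
    if (length(idx) == 0) {
      return(tibble(transcript_id = character(), seq_id = character(),
                    start = integer(), end = integer(), strand = character(),
                    phase = character()))
    }
    purrr::map_dfr(idx, function(r) {
      p <- get_parents(r)
      if (length(p) == 0) p <- NA_character_
      tibble(transcript_id = p, seq_id = feats$seq_id[r],
             start = feats$start[r], end = feats$end[r],
             strand = feats$strand[r], phase = feats$phase[r], line = feats$line[r])
    })
  }
  exons <- part_rows("exon")
  cds <- part_rows("CDS")

  resolve_parts <- function(parts, label) {
    if (nrow(parts) == 0) return(parts)
    if (anyNA(parts$transcript_id)) {
      if (feature_policy == "strict") {
        abort(paste0("orphan ", label, " feature without Parent at line ",
                     parts$line[which(is.na(parts$transcript_id))[1]]))
      }
      parts$transcript_id[is.na(parts$transcript_id)] <-
        paste0("orphan.", label, ".", parts$line[is.na(parts$transcript_id)])
    }
    parts
  }
  exons <- resolve_parts(exons, "exon")
  cds <- resolve_parts(cds, "CDS")

  # parts whose Parent is a gene id: synthesize "<gene>.t1"
  remap_gene_parent <- function(parts) {
    hit <- parts$transcript_id %in% genes$gene_id
    parts$transcript_id[hit] <- paste0(parts$transcript_id[hit], ".t1")
    parts
  }
  exons <- remap_gene_parent(exons)
  cds <- remap_gene_parent(cds)

  known_parents <- c(tx$transcript_id)
  part_parents <- unique(c(exons$transcript_id, cds$transcript_id))
  unknown <- setdiff(part_parents, known_parents)
  # "<gene>.t1" synthetic ids are expected; anything else is an orphan
  synth <- unknown[sub("\\.t1$", "", unknown) %in% genes$gene_id |
                     grepl("^orphan\\.", unknown)]
  orphan_parts <- setdiff(unknown, synth)
  if (length(orphan_parts) > 0 && feature_policy == "strict") {
    abort(paste0("orphan exon/CDS feature(s) with missing parent: ",
                 paste(orphan_parts, collapse = ", ")))
  }
  extra_tx <- bind_rows(
    tibble(transcript_id = synth, gene_id = sub("\\.t1$", "", synth)),
    tibble(transcript_id = orphan_parts,
           gene_id = if (length(orphan_parts) > 0) paste0(orphan_parts, ".gene") else character(0))
  )
  if (nrow(extra_tx) > 0) tx <- bind_rows(tx, extra_tx)
  missing_genes <- setdiff(tx$gene_id, genes$gene_id)
  if (length(missing_genes) > 0) {
    spans <- bind_rows(exons, cds) |>
      left_join(tx, by = "transcript_id") |>
      filter(.data$gene_id %in% missing_genes) |>
      group_by(.data$gene_id) |>
      summarise(seq_id = .data$seq_id[1], start = min(.data$start),
                end = max(.data$end), strand = .data$strand[1], .groups = "drop")
    genes <- bind_rows(genes, mutate(spans, source = ".",
                                     locus_name = NA_character_,
                                     putative_te = FALSE))
  }
  # drop transcripts of genes that never materialized (no parts, no gene line)
  tx <- filter(tx, .data$gene_id %in% genes$gene_id)

  cds$phase <- suppressWarnings(as.integer(cds$phase))
  exons$line <- NULL; cds$line <- NULL
  out <- annotation_set(genes, tx, exons, cds, version_tag = version_tag)
  out <- recompute_missing_phases(out)
  attr(out, "feature_counts") <- counts
  out
}

#' Per-feature-type counts recorded by [read_gff3()]
#' @param x An `annotation_set` returned by [read_gff3()].
#' @return Named table of feature-type counts, or `NULL`.
#' @export
feature_counts <- function(x) attr(x, "feature_counts")

# GFF3 phase: bases to skip at segment start to reach a codon boundary.
# Recomputed from segment lengths (translation order) when absent/invalid.
compute_phases <- function(starts, ends, strand) {
  ord <- if (identical(strand, "-")) order(-starts) else order(starts)
  len <- (ends - starts)[ord]
  phase <- integer(length(len))
  cum <- 0L
  for (i in seq_along(len)) {
    phase[i] <- (3L - (cum %% 3L)) %% 3L
    cum <- cum + len[i]
  }
  phase[order(ord)]
}

recompute_missing_phases <- function(x) {
  if (nrow(x$cds) == 0) return(x)
  x$cds <- x$cds |>
    group_by(.data$transcript_id) |>
    mutate(phase = if (anyNA(.data$phase) || any(!.data$phase %in% 0:2)) {
      compute_phases(.data$start, .data$end, .data$strand[1])
    } else .data$phase) |>
    ungroup()
  x
}

#' Write an annotation set to GFF3
#'
#' Features are sorted by `seq_id` then start; coordinates are converted back
#' to 1-based inclusive; CDS phases are recomputed from segment lengths.
#' `read_gff3(write_gff3(x))` reproduces `x` up to attribute ordering.
#'
#' @param x An [annotation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(x, path) {
  x <- recompute_missing_phases(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  genes <- arrange(x$genes, .data$seq_id, .data$start, .data$end, .data$gene_id)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gat <- format_gff3_attributes(
      ID = g$gene_id,
      locus_name = if (!is.na(g$locus_name)) g$locus_name else NA,
      putative_te = if (isTRUE(g$putative_te)) "true" else NA
    )
    writeLines(paste(g$seq_id, g$source, "gene", g$start + 1L, g$end, ".",
                     g$strand, ".", gat, sep = "\t"), con)
    txs <- x$transcripts$transcript_id[x$transcripts$gene_id == g$gene_id]
    for (t in txs) {
      ex <- transcript_exons(x, t)
      cd <- transcript_cds(x, t)
      span <- if (nrow(ex) > 0) c(min(ex$start), max(ex$end)) else
        if (nrow(cd) > 0) c(min(cd$start), max(cd$end)) else c(g$start, g$end)
      writeLines(paste(g$seq_id, g$source, "mRNA", span[1] + 1L, span[2], ".",
                       g$strand, ".",
                       format_gff3_attributes(ID = t, Parent = g$gene_id),
                       sep = "\t"), con)
      if (nrow(ex) > 0) {
        writeLines(paste(ex$seq_id, g$source, "exon", ex$start + 1L, ex$end, ".",
                         ex$strand, ".",
                         format_gff3_attributes(Parent = t), sep = "\t"), con)
      }
      if (nrow(cd) > 0) {
        ph <- compute_phases(cd$start, cd$end, cd$strand[1])
        writeLines(paste(cd$seq_id, g$source, "CDS", cd$start + 1L, cd$end, ".",
                         cd$strand, ph,
                         format_gff3_attributes(Parent = t), sep = "\t"), con)
      }
    }
  }
  invisible(path)
}

evidence_kinds <- c("LONG_READ", "SHORT_READ_ASSEMBLY", "PROTEIN", "PRIOR_GENE")

#' Read evidence alignments from GFF3
#'
#' Evidence arrives as blocked alignments: one `match_part` line per block,
#' blocks of one alignment sharing an `ID` attribute, the evidence kind in a
#' `kind` attribute (falling back to the source column).
#'
#' @param path GFF3 file path.
#' @return A tibble with one row per block: `evidence_id`, `kind`, `seq_id`,
#'   `strand`, `start`, `end`, `source_label`.
#' @export
read_evidence_gff3 <- function(path) {
  feats <- read_gff3_table(path)
  if (nrow(feats) == 0) return(empty_evidence())
  ids <- vapply(feats$attributes, function(a) a[["ID"]] %||% NA_character_, character(1))
  kinds <- vapply(feats$attributes, function(a) a[["kind"]] %||% NA_character_, character(1))
  kinds[is.na(kinds)] <- feats$source[is.na(kinds)]
  if (!all(kinds %in% evidence_kinds)) {
    abort(paste0("unknown evidence kind(s): ",
                 paste(setdiff(unique(kinds), evidence_kinds), collapse = ", ")))
  }
  if (anyNA(ids)) abort("evidence block without ID attribute")
  tibble(evidence_id = ids, kind = kinds, seq_id = feats$seq_id,
         strand = feats$strand, start = feats$start, end = feats$end,
         source_label = feats$source) |>
    arrange(.data$evidence_id, .data$start)
}

#' An empty evidence tibble (the evidence-table schema)
#' @return A zero-row evidence tibble.
#' @export
empty_evidence <- function() {
  tibble(evidence_id = character(), kind = character(), seq_id = character(),
         strand = character(), start = integer(), end = integer(),
         source_label = character())
}

#' Write evidence alignments to GFF3
#' @param evidence Evidence tibble (see [read_evidence_gff3()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evidence_gff3 <- function(evidence, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  ev <- arrange(evidence, .data$seq_id, .data$start)
  if (nrow(ev) > 0) {
    writeLines(paste(ev$seq_id, ev$source_label, "match_part",
                     ev$start + 1L, ev$end, ".", ev$strand, ".",
                     paste0("ID=", ev$evidence_id, ";kind=", ev$kind),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read repeat features from GFF3
#' @param path GFF3 file path.
#' @return A tibble: `seq_id`, `start`, `end`, `strand`, `repeat_class`.
#' @export
read_repeats_gff3 <- function(path) {
  feats <- read_gff3_table(path)
  cls <- vapply(feats$attributes, function(a) a[["class"]] %||% NA_character_,
                character(1))
  cls[is.na(cls)] <- feats$type[is.na(cls)]
  tibble(seq_id = feats$seq_id, start = feats$start, end = feats$end,
         strand = feats$strand, repeat_class = cls)
}

#' Write repeat features to GFF3
#' @param repeats Repeat tibble (see [read_repeats_gff3()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeats_gff3 <- function(repeats, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  rp <- arrange(repeats, .data$seq_id, .data$start)
  if (nrow(rp) > 0) {
    writeLines(paste(rp$seq_id, "repeats", "dispersed_repeat",
                     rp$start + 1L, rp$end, ".", rp$strand, ".",
                     paste0("class=", rp$repeat_class), sep = "\t"), con)
  }
  invisible(path)
}

#' Read gene -> Pfam domain assignments from TSV
#'
#' @param path TSV with columns `gene_id`, `pfam_accession` (and optionally
#'   `description`), with a header row.
#' @return A tibble with those columns.
#' @export
read_domains_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "pfam_accession") %in% names(d))) {
    abort("domain TSV must have columns gene_id, pfam_accession")
  }
  as_tibble(d)
}
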