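# Deterministic synthetic-data generator: genomes, clean and corrupted
# annotations, evidence tracks, repeats and isoform sets with known ground
# truth. A single master seed fans out to per-operation substreams so adding
# one generator call never perturbs the others.

# sample() without the scalar-x surprise: always samples from the elements of
# `x`, even when length(x) == 1.
resample <- function(x, size = 1, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

sense_codons <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))

random_dna <- function(n, gc = 0.36) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

# Random DNA guaranteed to contain no ATG trinucleotide (used for 5' UTRs so
# the planted start codon is the first ATG of the transcript).
random_dna_no_atg <- function(n, gc = 0.36) {
  s <- random_dna(n, gc)
  while (grepl("ATG", s, fixed = TRUE)) {
    s <- sub("ATG", "ATT", s, fixed = TRUE)
  }
  s
}

#' Generate a reproducible synthetic genome
#'
#' Sequence names follow the linkage-group/scaffold patterns (`LG1`, `sc1`,
#' ...) so naming and TE summaries exercise both categories. Each sequence is
#' drawn from its own substream of `seed`, so regenerating with a different
#' `n_sequences` leaves earlier sequences identical.
#'
#' @param seed Integer master seed.
#' @param n_sequences Number of sequences.
#' @param lengths Integer vector of sequence lengths (recycled), each >= 5000.
#' @param gc GC content (default 0.36, Brassicaceae-like).
#' @param lg_fraction Fraction of sequences named as linkage groups.
#' @return A named [Biostrings::DNAStringSet].
#' @export
generate_genome <- function(seed, n_sequences = 2,
                            lengths = rep(100000L, n_sequences),
                            gc = 0.36, lg_fraction = 0.5) {
  lengths <- rep_len(as.integer(lengths), n_sequences)
  if (any(lengths < 5000)) abort("sequence lengths must be >= 5000")
  n_lg <- ceiling(n_sequences * lg_fraction)
  nm <- c(paste0("LG", seq_len(n_lg)),
          if (n_sequences > n_lg) paste0("sc", seq_len(n_sequences - n_lg)))
  seqs <- vapply(seq_len(n_sequences), function(i) {
    with_seed(substream(seed, i), random_dna(lengths[i], gc))
  }, character(1))
  names(seqs) <- nm
  Biostrings::DNAStringSet(seqs)
}

# Build one gene in gene-local coordinates (transcript orientation, introns
# included). Returns the gene string plus exon/CDS intervals and metadata.
build_gene_parts <- function(n_exons, cds_exon_length, intron_length,
                             utr_length, utr3_intron, gc) {
  cds_lens <- resample(seq(cds_exon_length[1], cds_exon_length[2], by = 3),
                       n_exons, replace = TRUE)
  total <- sum(cds_lens)
  utr5 <- resample(utr_length[1]:utr_length[2])
  utr3a <- resample(utr_length[1]:utr_length[2])
  cds_seq <- paste0("ATG",
                    paste(resample(sense_codons, total / 3 - 2, replace = TRUE),
                          collapse = ""),
                    resample(stop_codons))
  cds_pieces <- substring(cds_seq, cumsum(c(1, cds_lens[-n_exons])),
                          cumsum(cds_lens))
  introns <- if (n_exons > 1) {
    vapply(seq_len(n_exons - 1), function(i) {
      len <- resample(intron_length[1]:intron_length[2])
      paste0("GT", random_dna(len - 4, gc), "AG")
    }, character(1))
  } else character(0)
  utr5_seq <- random_dna_no_atg(utr5, gc)
  utr3a_seq <- random_dna(utr3a, gc)
  exon_seqs <- cds_pieces
  exon_seqs[1] <- paste0(utr5_seq, exon_seqs[1])
  exon_seqs[n_exons] <- paste0(exon_seqs[n_exons], utr3a_seq)
  pieces <- character(0)
  exon_iv <- matrix(0L, nrow = 0, ncol = 2)
  cds_iv <- matrix(0L, nrow = 0, ncol = 2)
  off <- 0L
  for (i in seq_len(n_exons)) {
    el <- nchar(exon_seqs[i])
    exon_iv <- rbind(exon_iv, c(off, off + el))
    cs <- off + if (i == 1) utr5 else 0L
    cds_iv <- rbind(cds_iv, c(cs, cs + cds_lens[i]))
    pieces <- c(pieces, exon_seqs[i])
    off <- off + el
    if (i < n_exons) {
      pieces <- c(pieces, introns[i])
      off <- off + nchar(introns[i])
    }
  }
  if (utr3_intron) {
    ilen <- resample(intron_length[1]:intron_length[2])
    utr_intron <- paste0("GT", random_dna(ilen - 4, gc), "AG")
    utr3b <- resample(6:12)
    pieces <- c(pieces, utr_intron, random_dna(utr3b, gc))
    off_utr <- off + ilen
    exon_iv <- rbind(exon_iv, c(off_utr, off_utr + utr3b))
    off <- off_utr + utr3b
  }
  list(seq = paste(pieces, collapse = ""), length = off,
       exons = exon_iv, cds = cds_iv, utr3_intron = utr3_intron)
}

# gene-local interval -> genomic interval given placement and strand
local_to_genomic <- function(iv, pos, gene_len, strand) {
  if (strand == "+") cbind(pos + iv[, 1], pos + iv[, 2])
  else cbind(pos + gene_len - iv[, 2], pos + gene_len - iv[, 1])
}

#' Plant clean gene models into a genome
#'
#' Writes gene sequences into the genome so every planted gene is error-free
#' by construction: ATG start, single terminal stop, no in-frame internal
#' stops, GT-AG introns, ATG-free 5' UTR. A fraction of genes carries an
#' intron in the 3' UTR so UTR-localized splicing events can be planted later.
#'
#' @param genome A [Biostrings::DNAStringSet] to plant into.
#' @param seed Integer seed.
#' @param n_genes Number of genes.
#' @param exons_per_gene Integer range of exon counts.
#' @param cds_exon_length Range of per-exon CDS lengths (bp, rounded to
#'   multiples of 3).
#' @param intron_length Range of intron lengths (bp).
#' @param utr_length Range of UTR margin lengths (bp).
#' @param utr3_intron_fraction Fraction of genes given a spliced 3' UTR.
#' @param minus_strand_fraction Probability a gene lies on the minus strand.
#' @param intergenic_gap Range of gaps between consecutive genes (bp).
#' @param gc GC content of filler sequence.
#' @return A list: `set` (the clean truth [annotation_set()]), `genome` (the
#'   modified genome), `gene_info` (tibble with `gene_id`, `strand`,
#'   `n_exons`, `has_utr3_intron`).
#' @export
plant_genes <- function(genome, seed, n_genes = 50,
                        exons_per_gene = c(1, 5),
                        cds_exon_length = c(60, 240),
                        intron_length = c(80, 220),
                        utr_length = c(3, 12),
                        utr3_intron_fraction = 0.25,
                        minus_strand_fraction = 0.5,
                        intergenic_gap = c(250, 600),
                        gc = 0.36) {
  genome <- as_genome(genome)
  chars <- as.character(genome)
  with_seed(seed, {
    cursors <- stats::setNames(rep(0L, length(chars)), names(chars))
    rows_g <- list(); rows_t <- list(); rows_e <- list(); rows_c <- list()
    info <- list()
    sq_i <- 0L
    for (k in seq_len(n_genes)) {
      n_ex <- resample(exons_per_gene[1]:exons_per_gene[2])
      strand <- if (stats::runif(1) < minus_strand_fraction) "-" else "+"
      utr3_intron <- n_ex >= 2 && stats::runif(1) < utr3_intron_fraction
      parts <- build_gene_parts(n_ex, cds_exon_length, intron_length,
                                utr_length, utr3_intron, gc)
      placed <- FALSE
      for (try in seq_along(chars)) {
        sq_i <- (sq_i %% length(chars)) + 1L
        sq <- names(chars)[sq_i]
        pos <- cursors[sq] + resample(intergenic_gap[1]:intergenic_gap[2])
        if (pos + parts$length + 50 <= nchar(chars[sq])) {
          gene_str <- if (strand == "-") reverse_complement(parts$seq) else parts$seq
          substr(chars[sq], pos + 1, pos + parts$length) <- gene_str
          cursors[sq] <- pos + parts$length
          gid <- sprintf("g%04d", k)
          ex <- local_to_genomic(parts$exons, pos, parts$length, strand)
          cd <- local_to_genomic(parts$cds, pos, parts$length, strand)
          rows_g[[k]] <- tibble(gene_id = gid, seq_id = sq,
                                start = min(ex[, 1]), end = max(ex[, 2]),
                                strand = strand)
          tid <- paste0(gid, ".t1")
          rows_t[[k]] <- tibble(transcript_id = tid, gene_id = gid)
          rows_e[[k]] <- tibble(transcript_id = tid, seq_id = sq,
                                start = ex[, 1], end = ex[, 2], strand = strand)
          rows_c[[k]] <- tibble(transcript_id = tid, seq_id = sq,
                                start = cd[, 1], end = cd[, 2], strand = strand,
                                phase = NA_integer_)
          info[[k]] <- tibble(gene_id = gid, strand = strand, n_exons = n_ex,
                              has_utr3_intron = utr3_intron)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(paste0("insufficient genome space to plant gene ", k, " of ", n_genes))
      }
    }
    set <- annotation_set(bind_rows(rows_g), bind_rows(rows_t),
                          bind_rows(rows_e), bind_rows(rows_c),
                          version_tag = "truth")
    set <- recompute_missing_phases(set)
    list(set = set, genome = Biostrings::DNAStringSet(chars),
         gene_info = bind_rows(info))
  })
}

# Replace bases of a genome (character-level helper).
write_bases <- function(chars, seq_id, start, replacement) {
  substr(chars[seq_id], start + 1, start + nchar(replacement)) <- replacement
  chars
}

# Genomic interval of the codon at spliced-CDS offset `c0` (0-based, multiple
# of 3) of a transcript; NULL if the codon straddles segments.
codon_genomic <- function(cds, strand, c0) {
  ord <- if (strand == "-") order(-cds$start) else order(cds$start)
  s <- cds$start[ord]; e <- cds$end[ord]
  cum <- 0L
  for (i in seq_along(s)) {
    len <- e[i] - s[i]
    if (c0 >= cum && c0 + 3 <= cum + len) {
      o <- c0 - cum
      if (strand == "+") return(c(s[i] + o, s[i] + o + 3L))
      return(c(e[i] - o - 3L, e[i] - o))
    }
    cum <- cum + len
  }
  NULL
}

#' Corrupt an annotation with planted, recorded errors
#'
#' Applies exactly the requested corruptions to randomly chosen distinct
#' genes, never touching genes listed in `exclude`:
#'
#' * `premature_stop` - a mid-CDS codon is mutated to TGA in the genome.
#' * `cds_mod3` - the translation-final CDS segment is shrunk by 1 bp.
#' * `missing_feature` - the transcript's CDS features are deleted.
#' * `fusion` - two adjacent same-strand genes are replaced by one spanning
#'   model (the classic incorrectly merged prediction).
#' * `fission` - a multi-exon gene is split between exons into two fragment
#'   models (the classic incorrectly split prediction).
#'
#' @param x The clean truth [annotation_set()].
#' @param genome The genome the genes were planted into.
#' @param seed Integer seed.
#' @param recipe Named list of corruption counts (see above).
#' @param exclude Gene ids that must stay untouched.
#' @return A list: `set` (the corrupted "predicted" annotation), `genome`
#'   (possibly mutated), `truth` (tibble `corruption`, `source_ids`,
#'   `product_ids`, `expected_flag`).
#' @export
corrupt_annotation <- function(x, genome, seed,
                               recipe = list(premature_stop = 0, cds_mod3 = 0,
                                             missing_feature = 0,
                                             fusion = 0, fission = 0),
                               exclude = character(0)) {
  genome <- as_genome(genome)
  chars <- as.character(genome)
  get_n <- function(nm) recipe[[nm]] %||% 0L
  with_seed(seed, {
    set <- x
    truth <- list()
    taken <- exclude
    genes_sorted <- arrange(x$genes, .data$seq_id, .data$start)

    # fusions: disjoint pairs of adjacent same-strand genes
    n_fus <- get_n("fusion")
    if (n_fus > 0) {
      pairs <- list()
      for (sq in unique(genes_sorted$seq_id)) {
        g <- filter(genes_sorted, .data$seq_id == sq)
        if (nrow(g) < 2) next
        for (i in seq_len(nrow(g) - 1)) {
          if (g$strand[i] == g$strand[i + 1]) {
            pairs[[length(pairs) + 1L]] <- c(g$gene_id[i], g$gene_id[i + 1])
          }
        }
      }
      chosen <- list()
      ord <- sample(seq_along(pairs))
      for (pi in ord) {
        p <- pairs[[pi]]
        if (any(p %in% taken)) next
        chosen[[length(chosen) + 1L]] <- p
        taken <- c(taken, p)
        if (length(chosen) == n_fus) break
      }
      if (length(chosen) < n_fus) abort("not enough adjacent same-strand gene pairs to fuse")
      for (k in seq_along(chosen)) {
        p <- chosen[[k]]
        new_id <- sprintf("fused%03d", k)
        gg <- filter(set$genes, .data$gene_id %in% p)
        txs <- set$transcripts$transcript_id[set$transcripts$gene_id %in% p]
        ex <- filter(set$exons, .data$transcript_id %in% txs)
        cd <- filter(set$cds, .data$transcript_id %in% txs)
        new_tx <- paste0(new_id, ".t1")
        keep <- filter_genes(set, setdiff(set$genes$gene_id, p))
        set <- annotation_set(
          genes = bind_rows(keep$genes, tibble(
            gene_id = new_id, seq_id = gg$seq_id[1],
            start = min(gg$start), end = max(gg$end), strand = gg$strand[1],
            source = ".", locus_name = NA_character_, putative_te = FALSE)),
          transcripts = bind_rows(keep$transcripts,
                                  tibble(transcript_id = new_tx, gene_id = new_id)),
          exons = bind_rows(keep$exons, mutate(ex, transcript_id = new_tx)),
          cds = bind_rows(keep$cds, mutate(cd, transcript_id = new_tx)),
          version_tag = set$version_tag)
        truth[[length(truth) + 1L]] <- tibble(
          corruption = "fusion", source_ids = list(p),
          product_ids = list(new_id), expected_flag = NA_character_)
      }
    }

    # fissions: one multi-exon gene -> two fragments split between exons
    n_fis <- get_n("fission")
    if (n_fis > 0) {
      multi <- set$exons |>
        count(.data$transcript_id) |>
        filter(.data$n >= 2) |>
        left_join(set$transcripts, by = "transcript_id") |>
        filter(!.data$gene_id %in% taken, .data$gene_id %in% x$genes$gene_id)
      if (nrow(multi) < n_fis) abort("not enough multi-exon genes to split")
      chosen <- resample(multi$gene_id, n_fis)
      taken <- c(taken, chosen)
      for (k in seq_along(chosen)) {
        gid <- chosen[k]
        g <- filter(set$genes, .data$gene_id == !!gid)
        tid <- set$transcripts$transcript_id[set$transcripts$gene_id == gid][1]
        ex <- arrange(filter(set$exons, .data$transcript_id == tid), .data$start)
        cut <- floor(nrow(ex) / 2)
        ids <- paste0(gid, c(".fa", ".fb"))
        mk <- function(part_ex, new_id) {
          cd <- filter(set$cds, .data$transcript_id == tid,
                       .data$start >= min(part_ex$start),
                       .data$end <= max(part_ex$end))
          new_tx <- paste0(new_id, ".t1")
          list(genes = tibble(gene_id = new_id, seq_id = g$seq_id,
                              start = min(part_ex$start), end = max(part_ex$end),
                              strand = g$strand, source = ".",
                              locus_name = NA_character_, putative_te = FALSE),
               transcripts = tibble(transcript_id = new_tx, gene_id = new_id),
               exons = mutate(part_ex, transcript_id = new_tx),
               cds = mutate(cd, transcript_id = new_tx))
        }
        pa <- mk(ex[seq_len(cut), ], ids[1])
        pb <- mk(ex[seq(cut + 1, nrow(ex)), ], ids[2])
        keep <- filter_genes(set, setdiff(set$genes$gene_id, gid))
        set <- annotation_set(
          genes = bind_rows(keep$genes, pa$genes, pb$genes),
          transcripts = bind_rows(keep$transcripts, pa$transcripts, pb$transcripts),
          exons = bind_rows(keep$exons, pa$exons, pb$exons),
          cds = bind_rows(keep$cds, pa$cds, pb$cds),
          version_tag = set$version_tag)
        truth[[length(truth) + 1L]] <- tibble(
          corruption = "fission", source_ids = list(gid),
          product_ids = list(ids), expected_flag = NA_character_)
      }
    }

    pick <- function(n) {
      pool <- setdiff(x$genes$gene_id, taken)
      pool <- intersect(pool, set$genes$gene_id)
      if (length(pool) < n) abort("more corruptions requested than available genes")
      got <- resample(pool, n)
      taken <<- c(taken, got)
      got
    }

    for (gid in pick(get_n("premature_stop"))) {
      tid <- set$transcripts$transcript_id[set$transcripts$gene_id == gid][1]
      cd <- transcript_cds(set, tid)
      strand <- cd$strand[1]
      cds_len <- sum(cd$end - cd$start)
      target <- NULL
      for (ci in c(floor(cds_len / 6), seq(2, cds_len / 3 - 2))) {
        target <- codon_genomic(cd, strand, as.integer(3 * ci))
        if (!is.null(target) && 3 * ci >= 3 && 3 * ci <= cds_len - 6) break
        target <- NULL
      }
      if (is.null(target)) abort(paste0("no codon slot for premature stop in ", gid))
      codon <- if (strand == "+") "TGA" else reverse_complement("TGA")
      chars <- write_bases(chars, cd$seq_id[1], target[1], codon)
      truth[[length(truth) + 1L]] <- tibble(
        corruption = "premature_stop", source_ids = list(gid),
        product_ids = list(gid), expected_flag = "PREMATURE_STOP")
    }

    for (gid in pick(get_n("cds_mod3"))) {
      tid <- set$transcripts$transcript_id[set$transcripts$gene_id == gid][1]
      cd <- transcript_cds(set, tid)
      strand <- cd$strand[1]
      if (strand == "+") {
        i <- which.max(cd$end)
        set$cds$end[set$cds$transcript_id == tid & set$cds$start == cd$start[i]] <-
          cd$end[i] - 1L
      } else {
        i <- which.min(cd$start)
        set$cds$start[set$cds$transcript_id == tid & set$cds$end == cd$end[i]] <-
          cd$start[i] + 1L
      }
      truth[[length(truth) + 1L]] <- tibble(
        corruption = "cds_mod3", source_ids = list(gid),
        product_ids = list(gid), expected_flag = "CDS_NOT_MULTIPLE_OF_THREE")
    }

    for (gid in pick(get_n("missing_feature"))) {
      tid <- set$transcripts$transcript_id[set$transcripts$gene_id == gid][1]
      set$cds <- filter(set$cds, .data$transcript_id != tid)
      truth[[length(truth) + 1L]] <- tibble(
        corruption = "missing_feature", source_ids = list(gid),
        product_ids = list(gid), expected_flag = "MISSING_FEATURE")
    }

    set$version_tag <- "predicted"
    set <- recompute_missing_phases(set)
    list(set = set, genome = Biostrings::DNAStringSet(chars),
         truth = if (length(truth) == 0) {
           tibble(corruption = character(), source_ids = list(),
                  product_ids = list(), expected_flag = character())
         } else bind_rows(truth))
  })
}

#' Emit evidence alignments matching the true genes
#'
#' LONG_READ evidence copies true exon chains (optionally 5'-truncated),
#' PROTEIN evidence copies CDS extents, SHORT_READ_ASSEMBLY copies exon
#' chains, and PRIOR_GENE evidence copies the true genes with a recorded id
#' map.
#'
#' @param x The truth [annotation_set()].
#' @param seed Integer seed.
#' @param profile Named list of per-kind inclusion probabilities
#'   (`protein`, `long_read`, `short_read`, `prior`) plus
#'   `long_read_truncation`, the probability a long read loses its 5'-most
#'   exon.
#' @return An evidence tibble (one row per block).
#' @export
emit_evidence <- function(x, seed,
                          profile = list(protein = 1, long_read = 1,
                                         short_read = 0, prior = 1,
                                         long_read_truncation = 0)) {
  p <- function(nm) profile[[nm]] %||% 0
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(x$genes))) {
      gid <- x$genes$gene_id[i]
      tid <- x$transcripts$transcript_id[x$transcripts$gene_id == gid][1]
      ex <- transcript_exons(x, tid)
      cd <- transcript_cds(x, tid)
      sq <- x$genes$seq_id[i]; strand <- x$genes$strand[i]
      if (stats::runif(1) < p("protein") && nrow(cd) > 0) {
        rows[[length(rows) + 1L]] <- tibble(
          evidence_id = paste0("prot_", gid), kind = "PROTEIN", seq_id = sq,
          strand = strand, start = cd$start, end = cd$end,
          source_label = "PROTEIN")
      }
      if (stats::runif(1) < p("long_read") && nrow(ex) > 0) {
        blocks <- ex
        if (stats::runif(1) < p("long_read_truncation") && nrow(ex) > 1) {
          blocks <- if (strand == "+") ex[-1, ] else ex[-nrow(ex), ]
        }
        rows[[length(rows) + 1L]] <- tibble(
          evidence_id = paste0("lr_", gid), kind = "LONG_READ", seq_id = sq,
          strand = strand, start = blocks$start, end = blocks$end,
          source_label = "LONG_READ")
      }
      if (stats::runif(1) < p("short_read") && nrow(ex) > 0) {
        rows[[length(rows) + 1L]] <- tibble(
          evidence_id = paste0("sr_", gid), kind = "SHORT_READ_ASSEMBLY",
          seq_id = sq, strand = strand, start = ex$start, end = ex$end,
          source_label = "SHORT_READ_ASSEMBLY")
      }
      if (stats::runif(1) < p("prior") && nrow(ex) > 0) {
        rows[[length(rows) + 1L]] <- tibble(
          evidence_id = paste0("prior_", gid), kind = "PRIOR_GENE", seq_id = sq,
          strand = strand, start = ex$start, end = ex$end,
          source_label = "PRIOR_GENE")
      }
    }
    if (length(rows) == 0) empty_evidence() else bind_rows(rows)
  })
}

#' Copy an annotation set as a prior version with renamed ids
#' @param x An [annotation_set()].
#' @param prefix Prefix prepended to every gene/transcript id.
#' @param version_tag Version tag of the copy.
#' @return An `annotation_set`.
#' @export
make_prior_set <- function(x, prefix = "v0_", version_tag = "prior") {
  annotation_set(
    genes = mutate(x$genes, gene_id = paste0(prefix, .data$gene_id)),
    transcripts = mutate(x$transcripts,
                         gene_id = paste0(prefix, .data$gene_id),
                         transcript_id = paste0(prefix, .data$transcript_id)),
    exons = mutate(x$exons, transcript_id = paste0(prefix, .data$transcript_id)),
    cds = mutate(x$cds, transcript_id = paste0(prefix, .data$transcript_id)),
    version_tag = version_tag
  )
}

#' Plant repeats over genes and record putative-TE truth
#'
#' Covers `n_te_genes` gene spans at `te_coverage` (>= the labeling threshold)
#' and `n_partial` further genes at `partial_coverage` (below it), plus short
#' background repeats; all intervals are classed `LTR/Gypsy`.
#'
#' @param x The truth [annotation_set()].
#' @param seed Integer seed.
#' @param n_te_genes,te_coverage Genes to cover and their coverage fraction.
#' @param n_partial,partial_coverage Sub-threshold negative controls.
#' @param exclude Gene ids not to touch.
#' @return A list: `repeats` tibble, `te_gene_ids`, `partial_gene_ids`.
#' @export
emit_repeats <- function(x, seed, n_te_genes = 10, te_coverage = 0.6,
                         n_partial = 5, partial_coverage = 0.35,
                         exclude = character(0)) {
  with_seed(seed, {
    pool <- setdiff(x$genes$gene_id, exclude)
    if (length(pool) < n_te_genes + n_partial) {
      abort("not enough genes for the requested repeat placements")
    }
    ids <- resample(pool, n_te_genes + n_partial)
    te_ids <- ids[seq_len(n_te_genes)]
    part_ids <- setdiff(ids, te_ids)
    mk <- function(gid, frac) {
      g <- filter(x$genes, .data$gene_id == !!gid)
      len <- g$end - g$start
      tibble(seq_id = g$seq_id, start = g$start,
             end = g$start + as.integer(ceiling(len * frac)),
             strand = ".", repeat_class = "LTR/Gypsy")
    }
    reps <- bind_rows(
      purrr::map_dfr(te_ids, mk, frac = te_coverage),
      purrr::map_dfr(part_ids, mk, frac = partial_coverage)
    )
    list(repeats = reps, te_gene_ids = te_ids, partial_gene_ids = part_ids)
  })
}

# -- isoform planting ---------------------------------------------------------

# Add one isoform to a gene. `cds_rows` supplies the isoform's CDS directly
# (tibble start/end); when NULL the CDS is recomputed as the longest ORF of
# the spliced isoform.
add_isoform <- function(set, gid, new_ex, genome_chars, cds_rows = NULL) {
  tid2 <- paste0(gid, ".t", sum(set$transcripts$gene_id == gid) + 1L)
  g <- filter(set$genes, .data$gene_id == !!gid)
  set$transcripts <- bind_rows(set$transcripts,
                               tibble(transcript_id = tid2, gene_id = gid))
  set$exons <- bind_rows(set$exons,
                         mutate(new_ex, transcript_id = tid2))
  if (is.null(cds_rows)) {
    genome <- Biostrings::DNAStringSet(genome_chars)
    eu <- arrange(new_ex, .data$start)
    spliced <- splice_intervals(g$seq_id, eu$start, eu$end, g$strand, genome,
                                id = tid2)
    orf <- longest_orf(spliced)
    if (!is.null(orf)) {
      cds_rows <- spliced_to_genomic(eu, g$strand, orf[1], orf[2])
    }
  }
  if (!is.null(cds_rows) && nrow(cds_rows) > 0) {
    set$cds <- bind_rows(set$cds, tibble(
      transcript_id = tid2, seq_id = g$seq_id, start = cds_rows$start,
      end = cds_rows$end, strand = g$strand, phase = NA_integer_))
  }
  set
}

#' Plant alternative-splicing isoforms with known event truth
#'
#' Adds one extra isoform per selected gene realizing the requested event
#' type. Alternative splice sites are written only inside existing introns, so
#' the primary gene models stay clean. Planting uses plus-strand genes;
#' strand-awareness of the classifier is exercised separately.
#'
#' Supported rows of `recipe`: `type` in ES/AA/AD/MX/IR, `n`, `canonical`
#' (only AA/AD support non-canonical planting), `in_utr` (supported for
#' AA/AD/IR via genes with a spliced 3' UTR).
#'
#' @param x The truth [annotation_set()].
#' @param genome The planted genome.
#' @param seed Integer seed.
#' @param recipe Tibble with columns `type`, `n`, `canonical`, `in_utr`.
#' @param gene_info The `gene_info` tibble from [plant_genes()].
#' @param exclude Gene ids not to use.
#' @return A list: `set` (isoform [annotation_set()]), `genome` (modified),
#'   `truth` (tibble `gene_id`, `type`, `canonical`, `in_utr`).
#' @export
plant_isoforms <- function(x, genome, seed,
                           recipe = tibble(
                             type = c("ES", "IR", "IR", "AA", "AA", "AD", "MX"),
                             n = c(2, 1, 1, 1, 1, 1, 1),
                             canonical = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
                             in_utr = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)),
                           gene_info, exclude = character(0)) {
  genome <- as_genome(genome)
  chars <- as.character(genome)
  with_seed(seed, {
    set <- x
    truth <- list()
    used <- exclude
    plus_info <- filter(gene_info, .data$strand == "+", !.data$gene_id %in% exclude)

    pick_gene <- function(min_cds_exons, need_utr_intron = FALSE) {
      pool <- plus_info |>
        filter(!.data$gene_id %in% used, .data$n_exons >= min_cds_exons,
               if (need_utr_intron) .data$has_utr3_intron else TRUE)
      if (nrow(pool) == 0) abort("no eligible gene left for isoform planting")
      gid <- resample(pool$gene_id)
      used <<- c(used, gid)
      gid
    }

    # exons of the primary transcript, sorted; CDS-bearing exons only
    primary <- function(gid) {
      tid <- x$transcripts$transcript_id[x$transcripts$gene_id == gid][1]
      ex <- arrange(transcript_exons(x, tid), .data$start)
      cd <- arrange(transcript_cds(x, tid), .data$start)
      list(tid = tid, ex = ex, cd = cd,
           n_cds_ex = nrow(cd),
           seq_id = ex$seq_id[1])
    }
    cds_len_before <- function(pr, pos) {
      sum(pmax(0L, pmin(pr$cd$end, pos) - pr$cd$start))
    }

    # Smallest t >= t_min with (consumed + t) %% 3 == 0: positions a planted
    # TAA on a codon boundary of the isoform's reading frame.
    frame_slot <- function(consumed, t_min) {
      t <- t_min
      while ((consumed + t) %% 3L != 0L) t <- t + 1L
      as.integer(t)
    }
    copy_cds <- function(pr) select(pr$cd, "start", "end")

    for (r in seq_len(nrow(recipe))) {
      type <- recipe$type[r]; canon <- recipe$canonical[r]
      in_utr <- recipe$in_utr[r]
      for (dup in seq_len(recipe$n[r])) {
        cds_rows <- NULL  # NULL -> longest-ORF recomputation in add_isoform
        if (type == "ES") {
          gid <- pick_gene(3)
          pr <- primary(gid)
          k <- resample(2:(pr$n_cds_ex - 1))   # internal CDS exon
          new_ex <- pr$ex[-k, ]
        } else if (type == "IR") {
          if (in_utr) {
            gid <- pick_gene(2, need_utr_intron = TRUE)
            pr <- primary(gid)
            # retain the UTR intron: merge the last two exons; the ORF is
            # untouched, so the isoform keeps the primary CDS
            n <- nrow(pr$ex)
            new_ex <- pr$ex[-n, ]
            new_ex$end[n - 1] <- pr$ex$end[n]
            cds_rows <- copy_cds(pr)
          } else {
            gid <- pick_gene(2)
            pr <- primary(gid)
            k <- resample(seq_len(pr$n_cds_ex - 1))  # intron after CDS exon k
            a <- pr$ex$end[k]
            new_ex <- pr$ex
            new_ex$end[k] <- new_ex$end[k + 1]
            new_ex <- new_ex[-(k + 1), ]
            # premature-termination isoform: plant an in-frame TAA just inside
            # the retained intron and end the isoform's CDS there
            t <- frame_slot(cds_len_before(pr, a), 4L)
            chars <- write_bases(chars, pr$seq_id, a + t, "TAA")
            cds_rows <- filter(copy_cds(pr), .data$end <= a)
            cds_rows$end[which.max(cds_rows$end)] <- a + t + 3L
          }
        } else if (type %in% c("AA", "AD")) {
          gid <- pick_gene(2, need_utr_intron = in_utr)
          pr <- primary(gid)
          n <- nrow(pr$ex)
          if (in_utr) { k <- n - 1L } else { k <- resample(seq_len(pr$n_cds_ex - 1)) }
          a <- pr$ex$end[k]; b <- pr$ex$start[k + 1]
          d <- 15L  # shift of the alternative site into the intron
          new_ex <- pr$ex
          if (type == "AA") {
            # plus strand: acceptor = intron 3' end; exon k+1 extends left
            new_ex$start[k + 1] <- b - d
            chars <- write_bases(chars, pr$seq_id, b - d - 2L,
                                 if (canon) "AG" else "CT")
            if (in_utr) {
              cds_rows <- copy_cds(pr)
            } else {
              t <- frame_slot(cds_len_before(pr, a), 3L)
              chars <- write_bases(chars, pr$seq_id, b - d + t, "TAA")
              cds_rows <- bind_rows(filter(copy_cds(pr), .data$end <= a),
                                    tibble(start = b - d, end = b - d + t + 3L))
            }
          } else {
            # plus strand: donor = intron 5' end; exon k extends right
            new_ex$end[k] <- a + d
            chars <- write_bases(chars, pr$seq_id, a + d,
                                 if (canon) "GT" else "CA")
            if (in_utr) {
              cds_rows <- copy_cds(pr)
            } else {
              t <- frame_slot(cds_len_before(pr, a), 3L)
              chars <- write_bases(chars, pr$seq_id, a + t, "TAA")
              cds_rows <- filter(copy_cds(pr), .data$end <= a)
              cds_rows$end[which.max(cds_rows$end)] <- a + t + 3L
            }
          }
        } else if (type == "MX") {
          gid <- pick_gene(3)
          pr <- primary(gid)
          k <- resample(2:(pr$n_cds_ex - 1))
          d1 <- pr$ex$end[k]                 # end of original exon k
          b <- pr$ex$start[k + 1]            # start of next exon
          c2 <- d1 + 12L; d2 <- c2 + 21L     # alternative exon inside intron k
          new_ex <- pr$ex
          new_ex$start[k] <- c2; new_ex$end[k] <- d2
          chars <- write_bases(chars, pr$seq_id, c2 - 2L,
                               if (canon) "AG" else "CT")
          chars <- write_bases(chars, pr$seq_id, d2,
                               if (canon) "GT" else "CA")
        } else abort(paste0("unsupported isoform recipe type: ", type))
        set <- add_isoform(set, gid, new_ex, chars, cds_rows = cds_rows)
        truth[[length(truth) + 1L]] <- tibble(
          gene_id = gid, type = type, canonical = canon, in_utr = in_utr)
      }
    }
    set$version_tag <- "isoforms"
    list(set = set, genome = Biostrings::DNAStringSet(chars),
         truth = if (length(truth) == 0) {
           tibble(gene_id = character(), type = character(),
                  canonical = logical(), in_utr = logical())
         } else bind_rows(truth))
  })
}

#' Generate a complete synthetic study bundle
#'
#' Orchestrates the generator: genome, clean truth annotation, isoform set
#' with planted splicing events, corrupted "predicted" annotation (fusions,
#' fissions, sequence/format corruptions), evidence tracks, repeats, domain
#' assignments and a prior-version copy — all deterministic in `seed`, with
#' ground truth for every planting.
#'
#' @param seed Integer master seed.
#' @param n_genes Number of true genes (default 200).
#' @param n_sequences,seq_length Genome shape.
#' @param n_fusions,n_fissions Structural corruption counts (default 20 each).
#' @param corruption_recipe Counts of sequence/format corruptions (default 4
#'   premature stops, 4 frame errors, 4 missing-feature deletions).
#' @param n_te_genes TE-covered genes (default 20).
#' @param isoform_recipe Recipe tibble for [plant_isoforms()].
#' @return A list with elements `genome`, `truth_set`, `predicted_set`,
#'   `isoform_set`, `prior_set`, `evidence`, `repeats`, `domains`, and
#'   `truth` (a list of truth tables).
#' @export
simulate_bundle <- function(seed, n_genes = 200, n_sequences = 4,
                            seq_length = 170000L,
                            n_fusions = 20, n_fissions = 20,
                            corruption_recipe = list(premature_stop = 4,
                                                     cds_mod3 = 4,
                                                     missing_feature = 4),
                            n_te_genes = 20,
                            isoform_recipe = NULL) {
  genome <- generate_genome(seed, n_sequences,
                            lengths = rep(seq_length, n_sequences))
  pg <- plant_genes(genome, substream(seed, 11), n_genes = n_genes,
                    exons_per_gene = c(2, 5))
  iso_args <- list(x = pg$set, genome = pg$genome,
                   seed = substream(seed, 12), gene_info = pg$gene_info)
  if (!is.null(isoform_recipe)) iso_args$recipe <- isoform_recipe
  iso <- do.call(plant_isoforms, iso_args)
  iso_genes <- unique(iso$truth$gene_id)
  recipe <- c(corruption_recipe, list(fusion = n_fusions, fission = n_fissions))
  cor <- corrupt_annotation(pg$set, iso$genome, substream(seed, 13),
                            recipe = recipe, exclude = iso_genes)
  corrupted_sources <- unique(unlist(cor$truth$source_ids))
  evidence <- emit_evidence(pg$set, substream(seed, 14))
  reps <- emit_repeats(pg$set, substream(seed, 15), n_te_genes = n_te_genes,
                       n_partial = 10,
                       exclude = c(iso_genes, corrupted_sources))
  dom_pool <- setdiff(pg$set$genes$gene_id,
                      c(reps$te_gene_ids, reps$partial_gene_ids,
                        corrupted_sources, iso_genes))
  n_dom_te <- min(5L, length(dom_pool) %/% 2L)
  dom_te <- with_seed(substream(seed, 16), resample(dom_pool, n_dom_te))
  other_pool <- setdiff(dom_pool, dom_te)
  domains <- bind_rows(
    tibble(gene_id = dom_te, pfam_accession = "PF03732",
           description = "Retrotransposon gag protein"),
    tibble(gene_id = with_seed(substream(seed, 17),
                               resample(other_pool,
                                        min(10L, length(other_pool)))),
           pfam_accession = "PF00069", description = "Protein kinase domain")
  )
  list(
    genome = cor$genome,
    truth_set = pg$set,
    predicted_set = cor$set,
    isoform_set = iso$set,
    prior_set = make_prior_set(pg$set),
    evidence = evidence,
    repeats = reps$repeats,
    domains = domains,
    truth = list(corruptions = cor$truth, events = iso$truth,
                 te_gene_ids = reps$te_gene_ids,
                 te_domain_gene_ids = dom_te,
                 partial_te_gene_ids = reps$partial_gene_ids,
                 gene_info = pg$gene_info)
  )
}

#' Write a simulated bundle to a directory
#'
#' Emits `genome.fa`, `true.gff3`, `predicted.gff3`, `isoforms.gff3`,
#' `prior.gff3`, `evidence.gff3`, `repeats.gff3`, `domains.tsv` and
#' `truth.json`.
#'
#' @param bundle A list from [simulate_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_genome(bundle$genome, file.path(dir, "genome.fa"))
  write_gff3(bundle$truth_set, file.path(dir, "true.gff3"))
  write_gff3(bundle$predicted_set, file.path(dir, "predicted.gff3"))
  write_gff3(bundle$isoform_set, file.path(dir, "isoforms.gff3"))
  write_gff3(bundle$prior_set, file.path(dir, "prior.gff3"))
  write_evidence_gff3(bundle$evidence, file.path(dir, "evidence.gff3"))
  write_repeats_gff3(bundle$repeats, file.path(dir, "repeats.gff3"))
  utils::write.table(bundle$domains, file.path(dir, "domains.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- bundle$truth
  truth$corruptions <- tibble(
    corruption = truth$corruptions$corruption,
    source_ids = map_chr(truth$corruptions$source_ids, paste, collapse = ","),
    product_ids = map_chr(truth$corruptions$product_ids, paste, collapse = ","),
    expected_flag = truth$corruptions$expected_flag
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
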