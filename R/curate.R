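#' Configuration for evidence-driven curation
#'
#' The split/merge/rescue criteria are qualitative in manual curation
#' workflows ("several proteins and full-length transcripts supported
#' splitting"); this object fixes them as reproducible, tunable rules.
#'
#' @param min_reciprocal_overlap_fraction Minimum fraction of a gene's exonic
#'   length an evidence alignment must cover to support merging that gene into
#'   a run (default 0.5).
#' @param min_cluster_gap Blocks closer than this many bp (overlapping or
#'   abutting) join one evidence cluster (default 1).
#' @param required_merge_support Minimum number of evidences spanning every
#'   gene of a merge run (default 2; at least one must be PROTEIN or
#'   LONG_READ).
#' @param rescue_min_protein_coverage Minimum fraction of a prior gene's span
#'   covered by protein evidence for rescue (default 0.5).
#' @param same_strand_required Restrict evidence support to the gene's strand
#'   (default TRUE).
#' @return A list of class `curation_config`.
#' @export
curation_config <- function(min_reciprocal_overlap_fraction = 0.5,
                            min_cluster_gap = 1L,
                            required_merge_support = 2L,
                            rescue_min_protein_coverage = 0.5,
                            same_strand_required = TRUE) {
  stopifnot(min_reciprocal_overlap_fraction > 0, min_reciprocal_overlap_fraction <= 1,
            rescue_min_protein_coverage > 0, rescue_min_protein_coverage <= 1,
            min_cluster_gap >= 1, required_merge_support >= 1)
  structure(list(
    min_reciprocal_overlap_fraction = min_reciprocal_overlap_fraction,
    min_cluster_gap = as.integer(min_cluster_gap),
    required_merge_support = as.integer(required_merge_support),
    rescue_min_protein_coverage = rescue_min_protein_coverage,
    same_strand_required = same_strand_required
  ), class = "curation_config")
}

# One row per evidence alignment with its merged extent.
evidence_extents <- function(evidence) {
  if (nrow(evidence) == 0) {
    return(tibble(evidence_id = character(), kind = character(),
                  seq_id = character(), strand = character(),
                  start = integer(), end = integer()))
  }
  evidence |>
    group_by(.data$evidence_id) |>
    summarise(kind = .data$kind[1], seq_id = .data$seq_id[1],
              strand = .data$strand[1], start = min(.data$start),
              end = max(.data$end), .groups = "drop")
}

#' Cluster evidence alignments on one sequence
#'
#' Connected components under "extents overlap or abut within
#' `min_cluster_gap`", keeping strands apart when
#' `same_strand_required`.
#'
#' @param evidence Evidence tibble (one row per block) on a single `seq_id`.
#' @param config A [curation_config()].
#' @return A tibble with one row per cluster: `cluster_id`, `seq_id`,
#'   `strand`, `start`, `end`, `evidence_ids` (list), `kinds` (list).
#' @export
cluster_evidence <- function(evidence, config = curation_config()) {
  ext <- evidence_extents(evidence)
  if (nrow(ext) == 0) {
    return(tibble(cluster_id = integer(), seq_id = character(),
                  strand = character(), start = integer(), end = integer(),
                  evidence_ids = list(), kinds = list()))
  }
  if (length(unique(ext$seq_id)) > 1) abort("cluster_evidence expects one seq_id")
  grp <- if (config$same_strand_required) ext$strand else rep("*", nrow(ext))
  out <- list()
  for (g in unique(grp)) {
    e <- arrange(ext[grp == g, ], .data$start, .data$end)
    cl <- integer(nrow(e)); cur <- 1L; cur_end <- e$end[1]; cl[1] <- 1L
    if (nrow(e) > 1) {
      for (i in 2:nrow(e)) {
        if (e$start[i] - cur_end < config$min_cluster_gap) {
          cl[i] <- cur
          cur_end <- max(cur_end, e$end[i])
        } else {
          cur <- cur + 1L; cl[i] <- cur; cur_end <- e$end[i]
        }
      }
    }
    e$cl <- cl
    out[[g]] <- e |>
      group_by(.data$cl) |>
      summarise(seq_id = .data$seq_id[1], strand = .data$strand[1],
                start = min(.data$start), end = max(.data$end),
                evidence_ids = list(.data$evidence_id),
                kinds = list(.data$kind), .groups = "drop")
  }
  res <- bind_rows(out) |> arrange(.data$start, .data$end)
  res$cluster_id <- seq_len(nrow(res))
  select(res, "cluster_id", "seq_id", "strand", "start", "end",
         "evidence_ids", "kinds")
}

#' Detect incorrectly merged gene models (split candidates)
#'
#' A gene is a split candidate iff the evidence overlapping it falls into two
#' or more clusters, every cluster contains a PROTEIN or PRIOR_GENE alignment,
#' and no single alignment bridges two clusters (a bridging alignment merges
#' them by construction). Proposed boundaries are the midpoints of the
#' inter-cluster gaps.
#'
#' @param x An [annotation_set()].
#' @param evidence Evidence tibble.
#' @param config A [curation_config()].
#' @return A tibble: `gene_id`, `boundaries` (list of integer positions),
#'   `clusters` (list of cluster tibbles), `evidence_ids` (list).
#' @export
detect_split_candidates <- function(x, evidence, config = curation_config()) {
  empty <- tibble(gene_id = character(), boundaries = list(),
                  clusters = list(), evidence_ids = list())
  if (nrow(evidence) == 0 || nrow(x$genes) == 0) return(empty)
  ext <- evidence_extents(evidence)
  cand <- purrr::map_dfr(seq_len(nrow(x$genes)), function(i) {
    g <- x$genes[i, ]
    ov <- ext$seq_id == g$seq_id & ext$start < g$end & ext$end > g$start
    if (config$same_strand_required) ov <- ov & ext$strand == g$strand
    sub <- filter(evidence, .data$evidence_id %in% ext$evidence_id[ov])
    if (nrow(sub) == 0) return(NULL)
    cl <- cluster_evidence(sub, config)
    if (nrow(cl) < 2) return(NULL)
    anchored <- map_lgl(cl$kinds, function(k) any(k %in% c("PROTEIN", "PRIOR_GENE")))
    if (!all(anchored)) return(NULL)
    cl <- arrange(cl, .data$start)
    bounds <- as.integer(floor((cl$end[-nrow(cl)] + cl$start[-1]) / 2))
    tibble(gene_id = g$gene_id, boundaries = list(bounds),
           clusters = list(cl), evidence_ids = list(unlist(cl$evidence_ids)))
  })
  if (nrow(cand) == 0) empty else cand
}

# Coverage of a gene's exon union by one evidence alignment's blocks.
gene_evidence_coverage <- function(x, gene_id, evidence_blocks) {
  eu <- gene_exon_union(x, gene_id)
  elen <- sum(eu$end - eu$start)
  if (elen == 0) return(0)
  cov <- sum(vapply(seq_len(nrow(eu)), function(i) {
    iv_cover_length(eu$start[i], eu$end[i], evidence_blocks$start, evidence_blocks$end)
  }, numeric(1)))
  cov / elen
}

#' Detect incorrectly split gene predictions (merge candidates)
#'
#' A maximal run of same-strand, coordinate-adjacent genes is a merge
#' candidate iff at least `required_merge_support` evidences each cover every
#' gene of the run by at least `min_reciprocal_overlap_fraction` of that
#' gene's exonic length, with at least one supporting PROTEIN or LONG_READ.
#'
#' @param x An [annotation_set()].
#' @param evidence Evidence tibble.
#' @param config A [curation_config()].
#' @return A tibble: `gene_ids` (list), `evidence_ids` (list), `seq_id`,
#'   `start`, `end`.
#' @export
detect_merge_candidates <- function(x, evidence, config = curation_config()) {
  empty <- tibble(gene_ids = list(), evidence_ids = list(),
                  seq_id = character(), start = integer(), end = integer())
  if (nrow(evidence) == 0 || nrow(x$genes) < 2) return(empty)
  ext <- evidence_extents(evidence)
  out <- list()
  for (sq in unique(x$genes$seq_id)) {
    genes <- arrange(filter(x$genes, .data$seq_id == sq), .data$start, .data$end)
    if (nrow(genes) < 2) next
    # evidence supporting each gene above threshold
    ev_sq <- filter(evidence, .data$seq_id == sq)
    supporters <- map(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      ids <- ext$evidence_id[ext$seq_id == sq & ext$start < g$end & ext$end > g$start &
                               (!config$same_strand_required | ext$strand == g$strand)]
      keep(ids, function(e) {
        blocks <- filter(ev_sq, .data$evidence_id == e)
        gene_evidence_coverage(x, g$gene_id, blocks) >=
          config$min_reciprocal_overlap_fraction
      })
    })
    i <- 1L
    while (i < nrow(genes)) {
      run_support <- function(j) {
        # evidences supporting every gene in genes[i..j]
        common <- supporters[[i]]
        for (k in seq(i + 1L, j)) common <- intersect(common, supporters[[k]])
        common
      }
      best_j <- i
      j <- i + 1L
      while (j <= nrow(genes) && genes$strand[j] == genes$strand[i]) {
        common <- run_support(j)
        kinds <- ext$kind[match(common, ext$evidence_id)]
        if (length(common) >= config$required_merge_support &&
            any(kinds %in% c("PROTEIN", "LONG_READ"))) {
          best_j <- j
          j <- j + 1L
        } else break
      }
      if (best_j > i) {
        run <- genes[i:best_j, ]
        out[[length(out) + 1L]] <- tibble(
          gene_ids = list(run$gene_id),
          evidence_ids = list(run_support(best_j)),
          seq_id = sq, start = min(run$start), end = max(run$end)
        )
        i <- best_j + 1L
      } else i <- i + 1L
    }
  }
  if (length(out) == 0) empty else bind_rows(out)
}

# Copy a gene (with transcripts/exons/cds) under a new id.
copy_gene_as <- function(src, gene_id, new_id) {
  g <- filter(src$genes, .data$gene_id == !!gene_id)
  g$gene_id <- new_id
  tx <- filter(src$transcripts, .data$gene_id == !!gene_id)
  old_tx <- tx$transcript_id
  tx$transcript_id <- paste0(new_id, ".t", seq_len(nrow(tx)))
  tx$gene_id <- new_id
  remap <- stats::setNames(tx$transcript_id, old_tx)
  ex <- filter(src$exons, .data$transcript_id %in% old_tx)
  ex$transcript_id <- unname(remap[ex$transcript_id])
  cd <- filter(src$cds, .data$transcript_id %in% old_tx)
  cd$transcript_id <- unname(remap[cd$transcript_id])
  list(genes = g, transcripts = tx, exons = ex, cds = cd)
}

# Trim a gene's first transcript to [s, e); returns part tibbles or NULL if
# the cut leaves a CDS that is not a multiple of three.
trim_gene_to <- function(x, gene_id, s, e, new_id) {
  g <- filter(x$genes, .data$gene_id == !!gene_id)
  txs <- x$transcripts$transcript_id[x$transcripts$gene_id == gene_id]
  ex <- filter(x$exons, .data$transcript_id %in% txs,
               .data$end > s, .data$start < e) |>
    mutate(start = pmax(.data$start, s), end = pmin(.data$end, e))
  cd <- filter(x$cds, .data$transcript_id %in% txs,
               .data$end > s, .data$start < e) |>
    mutate(start = pmax(.data$start, s), end = pmin(.data$end, e))
  if (nrow(ex) == 0) return(NULL)
  if (nrow(cd) > 0 && sum(cd$end - cd$start) %% 3L != 0L) return(NULL)
  new_tx <- paste0(new_id, ".t1")
  ex$transcript_id <- new_tx; cd$transcript_id <- new_tx
  ex <- distinct(ex); cd <- distinct(cd)
  list(
    genes = tibble(gene_id = new_id, seq_id = g$seq_id,
                   start = min(ex$start), end = max(ex$end),
                   strand = g$strand, source = g$source,
                   locus_name = NA_character_, putative_te = FALSE),
    transcripts = tibble(transcript_id = new_tx, gene_id = new_id),
    exons = ex, cds = cd
  )
}

empty_curation_log <- function() {
  structure(
    tibble(action = character(), input_ids = list(), output_ids = list(),
           evidence_ids = list(), seq_id = character(),
           start = integer(), end = integer()),
    class = c("curation_log", "tbl_df", "tbl", "data.frame")
  )
}

#' Apply split and merge actions to an annotation set
#'
#' SPLIT replaces a gene with one gene per evidence cluster; the replacement's
#' exon/CDS structure is copied from the prior-version gene overlapping that
#' cluster when one exists, otherwise trimmed from the original model at the
#' proposed boundaries. MERGE replaces a run of genes with a single gene whose
#' transcript is the union of their exons; when a genome is supplied the CDS
#' is recomputed as the longest ATG-initiated, stop-terminated ORF of the
#' spliced union. A split whose boundary cuts a CDS out of frame with no prior
#' model to fall back on is skipped and logged as UNRESOLVED.
#'
#' @param x An [annotation_set()].
#' @param split_candidates From [detect_split_candidates()].
#' @param merge_candidates From [detect_merge_candidates()].
#' @param prior_set Optional prior-version [annotation_set()] guiding splits.
#' @param genome Optional genome for ORF recomputation after merges.
#' @param config A [curation_config()].
#' @return A list with `set` (the curated `annotation_set`) and `log`
#'   (a `curation_log` tibble).
#' @export
apply_actions <- function(x, split_candidates = NULL, merge_candidates = NULL,
                          prior_set = NULL, genome = NULL,
                          config = curation_config()) {
  log <- empty_curation_log()
  removed <- character(0)
  added <- list(genes = list(), transcripts = list(), exons = list(), cds = list())
  push <- function(parts) {
    added$genes[[length(added$genes) + 1L]] <<- parts$genes
    added$transcripts[[length(added$transcripts) + 1L]] <<- parts$transcripts
    added$exons[[length(added$exons) + 1L]] <<- parts$exons
    added$cds[[length(added$cds) + 1L]] <<- parts$cds
  }
  log_action <- function(action, inputs, outputs, ev, seq_id, s, e) {
    log <<- bind_rows(log, tibble(
      action = action, input_ids = list(inputs), output_ids = list(outputs),
      evidence_ids = list(ev), seq_id = seq_id,
      start = as.integer(s), end = as.integer(e)))
  }

  # --- splits, left to right ------------------------------------------------
  if (!is.null(split_candidates) && nrow(split_candidates) > 0) {
    g_order <- x$genes |>
      filter(.data$gene_id %in% split_candidates$gene_id) |>
      arrange(.data$seq_id, .data$start)
    split_candidates <- split_candidates[match(g_order$gene_id, split_candidates$gene_id), ]
    for (i in seq_len(nrow(split_candidates))) {
      gid <- split_candidates$gene_id[i]
      if (gid %in% removed) next
      cl <- split_candidates$clusters[[i]]
      bounds <- split_candidates$boundaries[[i]]
      g <- filter(x$genes, .data$gene_id == !!gid)
      seg_lo <- c(g$start, bounds)
      seg_hi <- c(bounds, g$end)
      parts_list <- list()
      ok <- TRUE
      for (k in seq_len(nrow(cl))) {
        new_id <- paste0(gid, ".s", k)
        prior <- NULL
        if (!is.null(prior_set)) {
          cand <- prior_set$genes |>
            filter(.data$seq_id == g$seq_id, .data$strand == g$strand,
                   .data$start < cl$end[k], .data$end > cl$start[k])
          if (nrow(cand) > 0) {
            ov <- iv_overlap(cand$start, cand$end, cl$start[k], cl$end[k])
            prior <- cand$gene_id[which.max(ov)]
          }
        }
        if (!is.null(prior)) {
          p <- copy_gene_as(prior_set, prior, new_id)
          parts_list[[k]] <- p
        } else {
          p <- trim_gene_to(x, gid, seg_lo[k], seg_hi[k], new_id)
          if (is.null(p)) { ok <- FALSE; break }
          parts_list[[k]] <- p
        }
      }
      if (!ok) {
        log_action("UNRESOLVED", gid, character(0),
                   split_candidates$evidence_ids[[i]], g$seq_id, g$start, g$end)
        next
      }
      for (p in parts_list) push(p)
      removed <- c(removed, gid)
      log_action("SPLIT", gid, map_chr(parts_list, function(p) p$genes$gene_id),
                 split_candidates$evidence_ids[[i]], g$seq_id, g$start, g$end)
    }
  }

  # --- merges, left to right ------------------------------------------------
  if (!is.null(merge_candidates) && nrow(merge_candidates) > 0) {
    merge_candidates <- arrange(merge_candidates, .data$seq_id, .data$start)
    for (i in seq_len(nrow(merge_candidates))) {
      gids <- merge_candidates$gene_ids[[i]]
      if (any(gids %in% removed)) next
      gg <- filter(x$genes, .data$gene_id %in% gids)
      new_id <- paste0(gids[1], ".m")
      txs <- x$transcripts$transcript_id[x$transcripts$gene_id %in% gids]
      ex_all <- filter(x$exons, .data$transcript_id %in% txs)
      eu <- iv_reduce(ex_all$start, ex_all$end)
      new_tx <- paste0(new_id, ".t1")
      ex <- tibble(transcript_id = new_tx, seq_id = gg$seq_id[1],
                   start = eu$start, end = eu$end, strand = gg$strand[1])
      cd <- tibble(transcript_id = character(), seq_id = character(),
                   start = integer(), end = integer(), strand = character(),
                   phase = integer())
      if (!is.null(genome)) {
        spliced <- splice_intervals(gg$seq_id[1], eu$start, eu$end,
                                    gg$strand[1], genome, id = new_id)
        orf <- longest_orf(spliced)
        if (!is.null(orf)) {
          giv <- spliced_to_genomic(eu, gg$strand[1], orf[1], orf[2])
          cd <- tibble(transcript_id = new_tx, seq_id = gg$seq_id[1],
                       start = giv$start, end = giv$end, strand = gg$strand[1],
                       phase = NA_integer_)
        }
      } else {
        cd_all <- filter(x$cds, .data$transcript_id %in% txs)
        cu <- iv_reduce(cd_all$start, cd_all$end)
        cd <- tibble(transcript_id = new_tx, seq_id = gg$seq_id[1],
                     start = cu$start, end = cu$end, strand = gg$strand[1],
                     phase = NA_integer_)
      }
      push(list(
        genes = tibble(gene_id = new_id, seq_id = gg$seq_id[1],
                       start = min(eu$start), end = max(eu$end),
                       strand = gg$strand[1], source = gg$source[1],
                       locus_name = NA_character_, putative_te = FALSE),
        transcripts = tibble(transcript_id = new_tx, gene_id = new_id),
        exons = ex, cds = cd
      ))
      removed <- c(removed, gids)
      log_action("MERGE", gids, new_id, merge_candidates$evidence_ids[[i]],
                 gg$seq_id[1], min(gg$start), max(gg$end))
    }
  }

  kept <- filter_genes(x, setdiff(x$genes$gene_id, removed))
  new_set <- annotation_set(
    genes = bind_rows(kept$genes, bind_rows(added$genes)),
    transcripts = bind_rows(kept$transcripts, bind_rows(added$transcripts)),
    exons = bind_rows(kept$exons, bind_rows(added$exons)),
    cds = bind_rows(kept$cds, bind_rows(added$cds)),
    version_tag = x$version_tag
  )
  new_set <- recompute_missing_phases(new_set)
  assert_curation_bookkeeping(n_genes(x), n_genes(new_set), log)
  list(set = new_set, log = log)
}

#' Assert the curation bookkeeping identity
#'
#' Checks `|genes_out| = |genes_in| - split inputs + split outputs - merge
#' inputs + merge outputs + rescues` against a curation log; UNRESOLVED
#' actions contribute nothing.
#'
#' @param n_in,n_out Gene counts before and after curation.
#' @param log A `curation_log`.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
assert_curation_bookkeeping <- function(n_in, n_out, log) {
  real <- filter(log, .data$action != "UNRESOLVED")
  expected <- n_in -
    sum(lengths(real$input_ids)) + sum(lengths(real$output_ids))
  if (n_out != expected) {
    abort(paste0("curation bookkeeping identity violated: expected ",
                 expected, " genes, got ", n_out))
  }
  invisible(TRUE)
}

#' Rescue prior-version genes missing from a new annotation
#'
#' Adds every prior gene that validates clean, overlaps no new gene on the
#' same strand, and whose span is covered at least
#' `rescue_min_protein_coverage` by PROTEIN evidence. Rescued genes keep their
#' structure and get new ids (`<old>.res`).
#'
#' @param prior_set Prior-version [annotation_set()].
#' @param new_set New [annotation_set()].
#' @param protein_evidence Evidence tibble (only PROTEIN rows are used).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param config A [curation_config()].
#' @return A list: `additions` (annotation_set of rescued genes), `log`
#'   (`curation_log` of RESCUE actions).
#' @export
rescue_missing <- function(prior_set, new_set, protein_evidence, genome,
                           config = curation_config()) {
  log <- empty_curation_log()
  prot <- filter(protein_evidence, .data$kind == "PROTEIN")
  reports <- validate_set(prior_set, genome)
  clean <- reports$gene_id[reports$n_flags == 0]
  rescued <- list()
  for (gid in clean) {
    g <- filter(prior_set$genes, .data$gene_id == !!gid)
    hit <- new_set$genes |>
      filter(.data$seq_id == g$seq_id, .data$strand == g$strand,
             .data$start < g$end, .data$end > g$start)
    if (nrow(hit) > 0) next
    blocks <- filter(prot, .data$seq_id == g$seq_id,
                     (!config$same_strand_required | .data$strand == g$strand))
    cov <- iv_cover_length(g$start, g$end, blocks$start, blocks$end) /
      (g$end - g$start)
    if (cov < config$rescue_min_protein_coverage) next
    new_id <- paste0(gid, ".res")
    rescued[[length(rescued) + 1L]] <- copy_gene_as(prior_set, gid, new_id)
    ev_ids <- unique(blocks$evidence_id[blocks$start < g$end & blocks$end > g$start])
    log <- bind_rows(log, tibble(
      action = "RESCUE", input_ids = list(character(0)),
      output_ids = list(new_id), evidence_ids = list(ev_ids),
      seq_id = g$seq_id, start = g$start, end = g$end))
  }
  additions <- if (length(rescued) == 0) {
    annotation_set(new_set$genes[0, ], new_set$transcripts[0, ],
                   new_set$exons[0, ], new_set$cds[0, ],
                   version_tag = new_set$version_tag)
  } else {
    annotation_set(
      genes = bind_rows(map(rescued, "genes")),
      transcripts = bind_rows(map(rescued, "transcripts")),
      exons = bind_rows(map(rescued, "exons")),
      cds = bind_rows(map(rescued, "cds")),
      version_tag = new_set$version_tag
    )
  }
  list(additions = additions, log = log)
}

#' @export
tidy.curation_log <- function(x, ...) {
  tibble(
    action = x$action,
    inputs = map_chr(x$input_ids, paste, collapse = ","),
    outputs = map_chr(x$output_ids, paste, collapse = ","),
    evidence_ids = map_chr(x$evidence_ids, paste, collapse = ","),
    seq_id = x$seq_id, start = x$start, end = x$end
  )
}

#' @export
glance.curation_log <- function(x, ...) {
  tibble(
    n_split = sum(x$action == "SPLIT"),
    n_split_outputs = sum(lengths(x$output_ids[x$action == "SPLIT"])),
    n_merge = sum(x$action == "MERGE"),
    n_merge_inputs = sum(lengths(x$input_ids[x$action == "MERGE"])),
    n_rescue = sum(x$action == "RESCUE"),
    n_unresolved = sum(x$action == "UNRESOLVED")
  )
}

#' Write a curation log to TSV
#' @param log A `curation_log`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curation_log_tsv <- function(log, path) {
  utils::write.table(tidy(log), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
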