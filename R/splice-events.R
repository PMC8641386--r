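#' Splice-site rules
#'
#' Canonical splicing defaults to GT donors and AG acceptors; GC-AG or AT-AC
#' can be added via the arguments. "Basic splicing rules" are implemented as
#' the minimum intron length plus donor-before-acceptor ordering.
#'
#' @param canonical_donors Set of donor 2-mers (default `"GT"`).
#' @param canonical_acceptors Set of acceptor 2-mers (default `"AG"`).
#' @param min_intron_length Minimum intron length in bp (default 20).
#' @return A list of class `splice_site_rules`.
#' @export
splice_site_rules <- function(canonical_donors = "GT",
                              canonical_acceptors = "AG",
                              min_intron_length = 20L) {
  stopifnot(all(nchar(canonical_donors) == 2), all(nchar(canonical_acceptors) == 2))
  structure(list(canonical_donors = toupper(canonical_donors),
                 canonical_acceptors = toupper(canonical_acceptors),
                 min_intron_length = as.integer(min_intron_length)),
            class = "splice_site_rules")
}

# Introns of one transcript: tibble(start, end), sorted, from exon gaps.
intron_chain <- function(exons) {
  if (nrow(exons) < 2) return(tibble(start = integer(), end = integer()))
  e <- arrange(exons, .data$start)
  tibble(start = e$end[-nrow(e)], end = e$start[-1])
}

#' Group transcripts into loci by exonic overlap
#'
#' Transitive closure of "shares an exonic base on the same strand": sense and
#' antisense transcripts fall into separate loci.
#'
#' @param x An [annotation_set()].
#' @return A tibble `transcript_id`, `locus_id`.
#' @export
group_loci <- function(x) {
  tx <- x$exons |>
    group_by(.data$transcript_id) |>
    summarise(seq_id = .data$seq_id[1], strand = .data$strand[1],
              .groups = "drop")
  if (nrow(tx) == 0) return(tibble(transcript_id = character(), locus_id = character()))
  g <- igraph::make_empty_graph(directed = FALSE) |>
    igraph::add_vertices(nrow(tx), name = tx$transcript_id)
  for (key in unique(paste(tx$seq_id, tx$strand))) {
    ids <- tx$transcript_id[paste(tx$seq_id, tx$strand) == key]
    ex <- filter(x$exons, .data$transcript_id %in% ids)
    ir <- iv_ranges(ex$start, ex$end)
    hits <- IRanges::findOverlaps(ir, ir)
    a <- ex$transcript_id[S4Vectors::queryHits(hits)]
    b <- ex$transcript_id[S4Vectors::subjectHits(hits)]
    keep <- a < b
    if (any(keep)) g <- igraph::add_edges(g, rbind(a[keep], b[keep]))
  }
  comp <- igraph::components(g)
  tibble(transcript_id = names(comp$membership),
         locus_id = paste0("locus_", comp$membership))
}

# Classify the differing intron substructure of one variation cluster.
classify_cluster <- function(iA, iB, strand) {
  nA <- nrow(iA); nB <- nrow(iB)
  res <- function(type, vs, ve) list(type = type, var_start = vs, var_end = ve)
  if (xor(nA == 0, nB == 0)) {
    one <- if (nA > 0) iA else iB
    if (nrow(one) == 1) return(res("IR", one$start, one$end))
    return(res("COMPLEX", min(one$start), max(one$end)))
  }
  if (nA == 1 && nB == 1) {
    if (iA$start == iB$start && iA$end != iB$end) {
      type <- if (strand == "+") "AA" else "AD"
      return(res(type, min(iA$end, iB$end), max(iA$end, iB$end)))
    }
    if (iA$end == iB$end && iA$start != iB$start) {
      type <- if (strand == "+") "AD" else "AA"
      return(res(type, min(iA$start, iB$start), max(iA$start, iB$start)))
    }
    return(res("COMPLEX", min(iA$start, iB$start), max(iA$end, iB$end)))
  }
  if ((nA == 1 && nB == 2) || (nA == 2 && nB == 1)) {
    one <- if (nA == 1) iA else iB
    two <- if (nA == 1) iB else iA
    if (two$start[1] == one$start && two$end[2] == one$end &&
        two$end[1] < two$start[2]) {
      return(res("ES", two$end[1], two$start[2]))
    }
    return(res("COMPLEX", min(one$start, two$start), max(one$end, two$end)))
  }
  if (nA == 2 && nB == 2) {
    same_outer <- iA$start[1] == iB$start[1] && iA$end[2] == iB$end[2]
    exA <- c(iA$end[1], iA$start[2]); exB <- c(iB$end[1], iB$start[2])
    disjoint <- exA[2] <= exB[1] || exB[2] <= exA[1]
    if (same_outer && disjoint && exA[1] < exA[2] && exB[1] < exB[2]) {
      return(res("MX", min(exA[1], exB[1]), max(exA[2], exB[2])))
    }
  }
  res("COMPLEX", min(c(iA$start, iB$start)), max(c(iA$end, iB$end)))
}

# Events between one transcript pair: differing introns within the pair's
# overlap region, clustered by overlap/abutment, one event per cluster.
pair_events <- function(exA, exB, strand) {
  oS <- max(min(exA$start), min(exB$start))
  oE <- min(max(exA$end), max(exB$end))
  if (oE <= oS) return(NULL)
  inA <- filter(intron_chain(exA), .data$start >= oS, .data$end <= oE)
  inB <- filter(intron_chain(exB), .data$start >= oS, .data$end <= oE)
  keyA <- paste(inA$start, inA$end); keyB <- paste(inB$start, inB$end)
  dA <- inA[!keyA %in% keyB, ]; dB <- inB[!keyB %in% keyA, ]
  if (nrow(dA) + nrow(dB) == 0) return(NULL)
  all_iv <- bind_rows(mutate(dA, side = "A"), mutate(dB, side = "B")) |>
    arrange(.data$start, .data$end)
  cl <- integer(nrow(all_iv)); cur <- 1L; cur_end <- all_iv$end[1]; cl[1] <- 1L
  if (nrow(all_iv) > 1) {
    for (i in 2:nrow(all_iv)) {
      if (all_iv$start[i] <= cur_end) {
        cl[i] <- cur; cur_end <- max(cur_end, all_iv$end[i])
      } else {
        cur <- cur + 1L; cl[i] <- cur; cur_end <- all_iv$end[i]
      }
    }
  }
  all_iv$cl <- cl
  purrr::map_dfr(unique(cl), function(k) {
    sub <- all_iv[all_iv$cl == k, ]
    iA <- arrange(sub[sub$side == "A", c("start", "end")], .data$start)
    iB <- arrange(sub[sub$side == "B", c("start", "end")], .data$start)
    out <- classify_cluster(iA, iB, strand)
    tibble(event_type = out$type,
           flank_left = min(sub$start), flank_right = max(sub$end),
           variable_start = out$var_start, variable_end = out$var_end,
           introns_a = list(iA), introns_b = list(iB))
  })
}

#' Extract elementary alternative-splicing events of each locus
#'
#' For every transcript pair of a locus, the differing intron substructure
#' between shared flanking positions is emitted as one event and classified as
#' exon skipping (ES), intron retention (IR), alternative acceptor (AA),
#' alternative donor (AD), mutually exclusive exons (MX), or COMPLEX. Events
#' are defined pairwise and deduplicated across pairs by their flanks and
#' variant intron structures.
#'
#' @param x An [annotation_set()] whose transcripts are the isoforms.
#' @param loci Optional locus table from [group_loci()]; computed when absent.
#' @return An `as_events` tibble: `locus_id`, `event_type`, `seq_id`,
#'   `strand`, `flank_left`, `flank_right`, `variable_start`, `variable_end`,
#'   `transcripts_a`/`transcripts_b` (list), `introns` (list of all
#'   participating introns).
#' @export
extract_events <- function(x, loci = NULL) {
  if (is.null(loci)) loci <- group_loci(x)
  ex_by_tx <- split(x$exons, x$exons$transcript_id)
  rows <- list()
  for (lid in unique(loci$locus_id)) {
    txs <- sort(loci$transcript_id[loci$locus_id == lid])
    if (length(txs) < 2) next
    seq_id <- ex_by_tx[[txs[1]]]$seq_id[1]
    strand <- ex_by_tx[[txs[1]]]$strand[1]
    for (i in seq_len(length(txs) - 1)) {
      for (j in seq(i + 1, length(txs))) {
        ev <- pair_events(ex_by_tx[[txs[i]]], ex_by_tx[[txs[j]]], strand)
        if (is.null(ev) || nrow(ev) == 0) next
        ev$locus_id <- lid; ev$seq_id <- seq_id; ev$strand <- strand
        ev$tx_a <- txs[i]; ev$tx_b <- txs[j]
        rows[[length(rows) + 1L]] <- ev
      }
    }
  }
  empty <- tibble(locus_id = character(), event_type = character(),
                  seq_id = character(), strand = character(),
                  flank_left = integer(), flank_right = integer(),
                  variable_start = integer(), variable_end = integer(),
                  transcripts_a = list(), transcripts_b = list(),
                  introns = list())
  if (length(rows) == 0) {
    class(empty) <- c("as_events", class(empty))
    return(empty)
  }
  ev <- bind_rows(rows)
  iv_key <- function(iv) paste(iv$start, iv$end, sep = "-", collapse = ";")
  ev$key_a <- map_chr(ev$introns_a, iv_key)
  ev$key_b <- map_chr(ev$introns_b, iv_key)
  # canonical side order so dedup is order-invariant
  swap <- ev$key_b < ev$key_a
  tmp_k <- ev$key_a[swap]; ev$key_a[swap] <- ev$key_b[swap]; ev$key_b[swap] <- tmp_k
  tmp_i <- ev$introns_a[swap]; ev$introns_a[swap] <- ev$introns_b[swap]; ev$introns_b[swap] <- tmp_i
  tmp_t <- ev$tx_a[swap]; ev$tx_a[swap] <- ev$tx_b[swap]; ev$tx_b[swap] <- tmp_t
  out <- ev |>
    group_by(.data$locus_id, .data$flank_left, .data$flank_right,
             .data$key_a, .data$key_b) |>
    summarise(event_type = .data$event_type[1], seq_id = .data$seq_id[1],
              strand = .data$strand[1],
              variable_start = .data$variable_start[1],
              variable_end = .data$variable_end[1],
              transcripts_a = list(sort(unique(.data$tx_a))),
              transcripts_b = list(sort(unique(.data$tx_b))),
              introns = list(distinct(bind_rows(.data$introns_a[[1]],
                                                .data$introns_b[[1]]))),
              .groups = "drop") |>
    select("locus_id", "event_type", "seq_id", "strand", "flank_left",
           "flank_right", "variable_start", "variable_end",
           "transcripts_a", "transcripts_b", "introns") |>
    arrange(.data$seq_id, .data$flank_left, .data$event_type)
  class(out) <- c("as_events", class(out))
  out
}

# Canonicality of a single intron (0-based half-open), strand-aware.
intron_is_canonical <- function(seq_id, start, end, strand, genome, rules) {
  seq <- genome_sequence(genome, seq_id)
  if (start < 0 || end > length(seq)) {
    abort(paste0("intron out of genome bounds on ", seq_id))
  }
  if (end - start < rules$min_intron_length) return(FALSE)
  s <- toupper(as.character(Biostrings::subseq(seq, start + 1L, end)))
  if (identical(strand, "-")) s <- reverse_complement(s)
  donor <- substr(s, 1, 2)
  acceptor <- substr(s, nchar(s) - 1, nchar(s))
  donor %in% rules$canonical_donors && acceptor %in% rules$canonical_acceptors
}

#' Flag canonical alternative-splicing events
#'
#' An event is canonical iff every intron participating on either side has a
#' canonical donor and acceptor 2-mer (strand-aware) and meets the minimum
#' intron length.
#'
#' @param events An `as_events` tibble from [extract_events()].
#' @param genome Named [Biostrings::DNAStringSet].
#' @param rules A [splice_site_rules()].
#' @return `events` with a logical `canonical` column.
#' @export
is_canonical <- function(events, genome, rules = splice_site_rules()) {
  events$canonical <- vapply(seq_len(nrow(events)), function(i) {
    iv <- events$introns[[i]]
    if (nrow(iv) == 0) return(TRUE)
    all(vapply(seq_len(nrow(iv)), function(k) {
      intron_is_canonical(events$seq_id[i], iv$start[k], iv$end[k],
                          events$strand[i], genome, rules)
    }, logical(1)))
  }, logical(1))
  events
}

#' Localize events to UTR vs CDS
#'
#' `in_utr` is TRUE iff the variable region overlaps the CDS of no transcript
#' in the locus. A locus without any CDS localizes to UTR with a warning.
#'
#' @param events An `as_events` tibble.
#' @param x The [annotation_set()] the events came from.
#' @param loci Optional locus table from [group_loci()].
#' @return `events` with a logical `in_utr` column.
#' @export
localize_events <- function(events, x, loci = NULL) {
  if (is.null(loci)) loci <- group_loci(x)
  cds_by_locus <- x$cds |>
    left_join(loci, by = "transcript_id") |>
    filter(!is.na(.data$locus_id))
  warned <- FALSE
  events$in_utr <- vapply(seq_len(nrow(events)), function(i) {
    cd <- filter(cds_by_locus, .data$locus_id == events$locus_id[i])
    if (nrow(cd) == 0) {
      if (!warned) {
        warn(paste0("locus ", events$locus_id[i],
                    " carries no CDS; event localized to UTR"))
        warned <<- TRUE
      }
      return(TRUE)
    }
    iv_cover_length(events$variable_start[i], events$variable_end[i],
                    cd$start, cd$end) == 0
  }, logical(1))
  events
}

#' Classify alternative-splicing events end to end
#'
#' Convenience wrapper: [group_loci()] then [extract_events()], plus canonical
#' flags and UTR localization when a genome is supplied.
#'
#' @param x An [annotation_set()] of isoforms.
#' @param genome Optional genome for canonical-splice-site checks.
#' @param rules A [splice_site_rules()].
#' @return An `as_events` tibble.
#' @export
classify_splice_events <- function(x, genome = NULL,
                                   rules = splice_site_rules()) {
  loci <- group_loci(x)
  ev <- extract_events(x, loci)
  if (!is.null(genome) && nrow(ev) > 0) ev <- is_canonical(ev, genome, rules)
  if (nrow(ev) > 0) ev <- localize_events(ev, x, loci)
  ev
}

#' @export
glance.as_events <- function(x, ...) {
  counts <- table(factor(x$event_type,
                         levels = c("ES", "AA", "AD", "MX", "IR", "COMPLEX")))
  out <- as_tibble(as.list(counts))
  out$total <- nrow(x)
  out$classified <- nrow(x) - sum(x$event_type == "COMPLEX")
  if ("canonical" %in% names(x)) out$canonical <- sum(x$canonical)
  if ("in_utr" %in% names(x)) out$in_utr <- sum(x$in_utr)
  out
}

#' @export
tidy.as_events <- function(x, ...) {
  out <- tibble(
    locus_id = x$locus_id, event_type = x$event_type, seq_id = x$seq_id,
    strand = x$strand, flank_left = x$flank_left, flank_right = x$flank_right,
    transcripts_a = map_chr(x$transcripts_a, paste, collapse = ","),
    transcripts_b = map_chr(x$transcripts_b, paste, collapse = ",")
  )
  if ("canonical" %in% names(x)) out$canonical <- x$canonical
  if ("in_utr" %in% names(x)) out$in_utr <- x$in_utr
  out
}

#' Write an AS-event table to TSV
#' @param events An `as_events` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(tidy(events), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
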