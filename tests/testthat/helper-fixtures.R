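# Shared helpers: compact constructors for hand-built annotation sets and an
# independent base-level oracle for alternative-splicing event counts.

# Build an annotation set from a list of genes; each gene is
# list(id, seq, strand, exons = list(c(s,e), ...), cds = list(c(s,e), ...)).
make_set <- function(genes, version = "test") {
  g <- list(); tx <- list(); ex <- list(); cd <- list()
  for (gn in genes) {
    ex_m <- do.call(rbind, gn$exons)
    cd_m <- if (!is.null(gn$cds)) do.call(rbind, gn$cds) else NULL
    tid <- paste0(gn$id, ".t1")
    g[[length(g) + 1]] <- tibble::tibble(
      gene_id = gn$id, seq_id = gn$seq, start = min(ex_m[, 1]),
      end = max(ex_m[, 2]), strand = gn$strand)
    tx[[length(tx) + 1]] <- tibble::tibble(transcript_id = tid, gene_id = gn$id)
    ex[[length(ex) + 1]] <- tibble::tibble(
      transcript_id = tid, seq_id = gn$seq, start = ex_m[, 1], end = ex_m[, 2],
      strand = gn$strand)
    if (!is.null(cd_m)) {
      cd[[length(cd) + 1]] <- tibble::tibble(
        transcript_id = tid, seq_id = gn$seq, start = cd_m[, 1], end = cd_m[, 2],
        strand = gn$strand, phase = NA_integer_)
    }
  }
  cd_all <- if (length(cd) > 0) dplyr::bind_rows(cd) else
    tibble::tibble(transcript_id = character(), seq_id = character(),
                   start = integer(), end = integer(), strand = character(),
                   phase = integer())
  annotation_set(dplyr::bind_rows(g), dplyr::bind_rows(tx),
                 dplyr::bind_rows(ex), cd_all, version_tag = version)
}

# Build an isoform set: one gene, several transcripts with given exon lists.
make_isoform_set <- function(seq, strand, isoforms, cds = NULL, gene = "g1") {
  tx <- tibble::tibble(transcript_id = names(isoforms), gene_id = gene)
  ex <- dplyr::bind_rows(lapply(names(isoforms), function(t) {
    m <- do.call(rbind, isoforms[[t]])
    tibble::tibble(transcript_id = t, seq_id = seq, start = m[, 1], end = m[, 2],
                   strand = strand)
  }))
  cd <- if (is.null(cds)) {
    tibble::tibble(transcript_id = character(), seq_id = character(),
                   start = integer(), end = integer(), strand = character(),
                   phase = integer())
  } else {
    dplyr::bind_rows(lapply(names(cds), function(t) {
      m <- do.call(rbind, cds[[t]])
      tibble::tibble(transcript_id = t, seq_id = seq, start = m[, 1], end = m[, 2],
                     strand = strand, phase = NA_integer_)
    }))
  }
  genes <- tibble::tibble(gene_id = gene, seq_id = seq,
                          start = min(ex$start), end = max(ex$end),
                          strand = strand)
  annotation_set(genes, tx, ex, cd)
}

# Simple evidence-row builder: one alignment with the given blocks.
ev_rows <- function(id, kind, seq, strand, blocks) {
  m <- do.call(rbind, blocks)
  tibble::tibble(evidence_id = id, kind = kind, seq_id = seq, strand = strand,
                 start = m[, 1], end = m[, 2], source_label = kind)
}

# ---------------------------------------------------------------------------
# Independent brute-force oracle for typed AS-event counts.
# Works at base resolution: per-position exonic indicators per transcript pair,
# variation clusters as runs of non-shared-exonic positions containing a
# disagreement, then classification from the runs of intronic positions.
oracle_event_counts <- function(isoform_exons, strand) {
  # isoform_exons: named list of matrices with columns start, end (0-based)
  ids <- sort(names(isoform_exons))
  events <- character(0)
  keys <- character(0)
  runs_of <- function(v, lo) {
    # maximal TRUE runs of logical vector v, as 0-based intervals offset by lo
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    cbind(lo + starts[r$values], lo + ends[r$values])
  }
  for (i in seq_len(length(ids) - 1)) {
    for (j in seq(i + 1, length(ids))) {
      A <- isoform_exons[[ids[i]]]; B <- isoform_exons[[ids[j]]]
      lo <- max(min(A[, 1]), min(B[, 1]))
      hi <- min(max(A[, 2]), max(B[, 2]))
      if (hi <= lo) next
      pos <- lo:(hi - 1)
      covA <- rep(FALSE, length(pos)); covB <- rep(FALSE, length(pos))
      for (k in seq_len(nrow(A))) covA[pos >= A[k, 1] & pos < A[k, 2]] <- TRUE
      for (k in seq_len(nrow(B))) covB[pos >= B[k, 1] & pos < B[k, 2]] <- TRUE
      anyintron <- !covA | !covB
      differs <- covA != covB
      cl <- runs_of(anyintron, lo)
      if (nrow(cl) == 0) next
      for (k in seq_len(nrow(cl))) {
        sel <- pos >= cl[k, 1] & pos < cl[k, 2]
        if (!any(differs[sel])) next
        sub <- which(sel)  # contiguous by construction (one run)
        iA <- runs_of((!covA)[sub], cl[k, 1])
        iB <- runs_of((!covB)[sub], cl[k, 1])
        type <- oracle_classify(iA, iB, strand)
        key <- paste(cl[k, 1], cl[k, 2],
                     paste(sort(c(paste(iA, collapse = ","),
                                  paste(iB, collapse = ","))), collapse = "|"))
        if (!key %in% keys) {
          keys <- c(keys, key)
          events <- c(events, type)
        }
      }
    }
  }
  table(factor(events, levels = c("ES", "AA", "AD", "MX", "IR", "COMPLEX")))
}

oracle_classify <- function(iA, iB, strand) {
  nA <- nrow(iA); nB <- nrow(iB)
  if (xor(nA == 0, nB == 0)) {
    return(if (max(nA, nB) == 1) "IR" else "COMPLEX")
  }
  if (nA == 1 && nB == 1) {
    if (iA[1, 1] == iB[1, 1] && iA[1, 2] != iB[1, 2]) {
      return(if (strand == "+") "AA" else "AD")
    }
    if (iA[1, 2] == iB[1, 2] && iA[1, 1] != iB[1, 1]) {
      return(if (strand == "+") "AD" else "AA")
    }
    return("COMPLEX")
  }
  one <- if (nA == 1) iA else if (nB == 1) iB else NULL
  two <- if (nA == 2 && nB == 1) iA else if (nB == 2 && nA == 1) iB else NULL
  if (!is.null(one) && !is.null(two)) {
    if (two[1, 1] == one[1, 1] && two[2, 2] == one[1, 2]) return("ES")
    return("COMPLEX")
  }
  if (nA == 2 && nB == 2 &&
      iA[1, 1] == iB[1, 1] && iA[2, 2] == iB[2, 2]) {
    exA <- c(iA[1, 2], iA[2, 1]); exB <- c(iB[1, 2], iB[2, 1])
    if ((exA[2] <= exB[1] || exB[2] <= exA[1])) return("MX")
  }
  "COMPLEX"
}

# Random locus generator for the oracle-equivalence property: transcripts are
# random exon/intron patterns over a shared segment grid with jittered intron
# boundaries (so alternative donor/acceptor events arise).
random_locus <- function(n_iso = 3, n_seg = 8, seg_len = 60) {
  bounds <- seq(0, by = seg_len, length.out = n_seg + 1)
  iso <- list()
  for (t in seq_len(n_iso)) {
    exonic <- c(TRUE, stats::runif(n_seg - 2) < 0.6, TRUE)
    r <- rle(exonic)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths
    ex <- cbind(bounds[starts[r$values] + 1], bounds[ends[r$values] + 1])
    # jitter internal boundaries to create AA/AD variation
    if (nrow(ex) > 1) {
      for (k in seq_len(nrow(ex) - 1)) {
        ex[k, 2] <- ex[k, 2] - sample(c(0L, 0L, 7L), 1)
        ex[k + 1, 1] <- ex[k + 1, 1] + sample(c(0L, 0L, 7L), 1)
      }
    }
    iso[[paste0("t", t)]] <- ex
  }
  iso
}

# Minimal two-gene bundle for quick pipeline tests.
small_bundle <- function(seed = 42, ...) {
  simulate_bundle(seed, n_genes = 60, n_sequences = 2, seq_length = 130000L,
                  n_fusions = 3, n_fissions = 3,
                  corruption_recipe = list(premature_stop = 2, cds_mod3 = 2,
                                           missing_feature = 2),
                  n_te_genes = 4, ...)
}
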