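test_that("evidence clustering separates disjoint alignments and joins bridged ones", {
  cfg <- curation_config()
  two <- dplyr::bind_rows(
    ev_rows("p1", "PROTEIN", "chr1", "+", list(c(0L, 900L))),
    ev_rows("p2", "PROTEIN", "chr1", "+", list(c(1100L, 2000L))))
  expect_equal(nrow(cluster_evidence(two, cfg)), 2L)

  bridged <- dplyr::bind_rows(two,
    ev_rows("lr", "LONG_READ", "chr1", "+", list(c(800L, 1300L))))
  expect_equal(nrow(cluster_evidence(bridged, cfg)), 1L)

  expect_equal(nrow(cluster_evidence(empty_evidence(), cfg)), 0L)
})

split_fixture <- function(extra_ev = NULL) {
  x <- make_set(list(list(id = "gene1", seq = "chr1", strand = "+",
                          exons = list(c(0L, 2000L)), cds = list(c(0L, 2000L)))))
  ev <- dplyr::bind_rows(
    ev_rows("p1", "PROTEIN", "chr1", "+", list(c(0L, 900L))),
    ev_rows("p2", "PROTEIN", "chr1", "+", list(c(1100L, 2000L))),
    extra_ev)
  list(x = x, ev = ev)
}

test_that("split candidates require two anchored clusters and no bridging evidence", {
  f <- split_fixture()
  cand <- detect_split_candidates(f$x, f$ev)
  expect_equal(cand$gene_id, "gene1")
  expect_equal(cand$boundaries[[1]], 1000L)

  bridged <- split_fixture(ev_rows("lr", "LONG_READ", "chr1", "+",
                                   list(c(500L, 1500L))))
  expect_equal(nrow(detect_split_candidates(bridged$x, bridged$ev)), 0L)

  single <- split_fixture()
  single$ev <- single$ev[single$ev$evidence_id == "p1", ]
  expect_equal(nrow(detect_split_candidates(single$x, single$ev)), 0L)

  # a cluster of expression-only evidence does not anchor a split
  lr_only <- split_fixture()
  lr_only$ev$kind[lr_only$ev$evidence_id == "p2"] <- "SHORT_READ_ASSEMBLY"
  expect_equal(nrow(detect_split_candidates(lr_only$x, lr_only$ev)), 0L)
})

merge_fixture <- function(strand2 = "+") {
  x <- make_set(list(
    list(id = "a", seq = "chr1", strand = "+",
         exons = list(c(0L, 500L)), cds = list(c(0L, 500L))),
    list(id = "b", seq = "chr1", strand = strand2,
         exons = list(c(700L, 1200L)), cds = list(c(700L, 1200L)))))
  ev <- dplyr::bind_rows(
    ev_rows("p", "PROTEIN", "chr1", "+", list(c(50L, 1150L))),
    ev_rows("lr", "LONG_READ", "chr1", "+", list(c(0L, 1200L))))
  list(x = x, ev = ev)
}

test_that("merge candidates need spanning support on one strand", {
  f <- merge_fixture()
  cand <- detect_merge_candidates(f$x, f$ev)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$gene_ids[[1]], c("a", "b"))

  opp <- merge_fixture(strand2 = "-")
  expect_equal(nrow(detect_merge_candidates(opp$x, opp$ev)), 0L)
})

test_that("pairwise-only evidence yields two-gene merge runs, not a triple", {
  x <- make_set(list(
    list(id = "a", seq = "chr1", strand = "+", exons = list(c(0L, 400L)),
         cds = list(c(0L, 400L))),
    list(id = "b", seq = "chr1", strand = "+", exons = list(c(500L, 900L)),
         cds = list(c(500L, 900L))),
    list(id = "c", seq = "chr1", strand = "+", exons = list(c(1000L, 1400L)),
         cds = list(c(1000L, 1400L)))))
  ev <- dplyr::bind_rows(
    ev_rows("p_ab", "PROTEIN", "chr1", "+", list(c(0L, 900L))),
    ev_rows("lr_ab", "LONG_READ", "chr1", "+", list(c(0L, 900L))),
    ev_rows("p_bc", "PROTEIN", "chr1", "+", list(c(500L, 1400L))),
    ev_rows("lr_bc", "LONG_READ", "chr1", "+", list(c(500L, 1400L))))
  cand <- detect_merge_candidates(x, ev)
  expect_true(all(lengths(cand$gene_ids) == 2))
})

test_that("apply_actions: split copies prior structures; empty input is the identity", {
  f <- split_fixture()
  prior <- make_set(list(
    list(id = "pA", seq = "chr1", strand = "+", exons = list(c(0L, 900L)),
         cds = list(c(0L, 900L))),
    list(id = "pB", seq = "chr1", strand = "+", exons = list(c(1100L, 2000L)),
         cds = list(c(1100L, 2000L)))), version = "prior")
  cand <- detect_split_candidates(f$x, f$ev)
  res <- apply_actions(f$x, cand, NULL, prior_set = prior)
  expect_equal(n_genes(res$set), 2L)
  expect_setequal(res$set$genes$start, c(0L, 1100L))
  expect_setequal(res$set$genes$end, c(900L, 2000L))
  expect_equal(res$log$action, "SPLIT")

  id <- apply_actions(f$x, NULL, NULL)
  expect_equal(n_genes(id$set), 1L)
  expect_equal(nrow(id$log), 0L)
})

test_that("a split cutting a CDS out of frame without a prior model is UNRESOLVED", {
  x <- make_set(list(list(id = "gene1", seq = "chr1", strand = "+",
                          exons = list(c(0L, 300L)), cds = list(c(0L, 300L)))))
  ev <- dplyr::bind_rows(
    ev_rows("p1", "PROTEIN", "chr1", "+", list(c(0L, 101L))),
    ev_rows("p2", "PROTEIN", "chr1", "+", list(c(202L, 300L))))
  cand <- detect_split_candidates(x, ev)
  expect_equal(cand$boundaries[[1]], 151L)  # 151 % 3 != 0
  res <- apply_actions(x, cand, NULL, prior_set = NULL)
  expect_equal(res$log$action, "UNRESOLVED")
  expect_equal(n_genes(res$set), 1L)
})

test_that("merging planted fission fragments restores the true gene", {
  g <- generate_genome(41, 1, lengths = 60000)
  pg <- plant_genes(g, 42, n_genes = 8, exons_per_gene = c(3, 4))
  cor <- corrupt_annotation(pg$set, pg$genome, 43, recipe = list(fission = 2))
  ev <- emit_evidence(pg$set, 44)
  cand <- detect_merge_candidates(cor$set, ev)
  expect_equal(nrow(cand), 2L)
  res <- apply_actions(cor$set, NULL, cand, genome = cor$genome)
  truth_spans <- with(pg$set$genes, paste(seq_id, start, end, strand))
  cur_spans <- with(res$set$genes, paste(seq_id, start, end, strand))
  expect_true(all(truth_spans %in% cur_spans))
  # the rebuilt ORF equals the true gene's CDS
  fissioned <- cor$truth$source_ids[[1]]
  merged_id <- res$log$output_ids[[1]]
  true_tid <- paste0(res$log$input_ids[[1]][1]) # e.g. gXXXX.fa
  src <- sub("\\.f[ab]$", "", true_tid)
  true_cds <- extract_spliced_sequence(pg$set, paste0(src, ".t1"),
                                       cor$genome, "cds")
  new_cds <- extract_spliced_sequence(res$set, paste0(merged_id, ".t1"),
                                      cor$genome, "cds")
  expect_equal(new_cds, true_cds)
})

test_that("bookkeeping identity holds and violations are caught", {
  log <- dplyr::bind_rows(
    tibble::tibble(action = "SPLIT", input_ids = list("a"),
                   output_ids = list(c("a1", "a2")), evidence_ids = list("e"),
                   seq_id = "chr1", start = 0L, end = 10L))
  expect_true(assert_curation_bookkeeping(10L, 11L, log))
  expect_error(assert_curation_bookkeeping(10L, 10L, log), "bookkeeping")
})

test_that("rescue honours validation, overlap and the coverage threshold", {
  g <- generate_genome(51, 1, lengths = 40000)
  pg <- plant_genes(g, 52, n_genes = 4, exons_per_gene = c(1, 2))
  prior <- pg$set
  gid <- prior$genes$gene_id[1]
  span <- prior$genes[1, ]
  new_set <- filter_genes(pg$set, setdiff(pg$set$genes$gene_id, gid))
  len <- span$end - span$start
  cover <- function(frac) ev_rows("pr", "PROTEIN", span$seq_id, span$strand,
                                  list(c(span$start,
                                         span$start + as.integer(ceiling(len * frac)))))
  res <- rescue_missing(prior, new_set, cover(0.9), pg$genome)
  expect_equal(res$log$action, "RESCUE")
  expect_equal(n_genes(res$additions), 1L)
  expect_equal(res$additions$genes$start, span$start)

  # exactly at threshold: >= semantics
  res_at <- rescue_missing(prior, new_set, cover(0.5), pg$genome)
  expect_equal(n_genes(res_at$additions), 1L)

  res_below <- rescue_missing(prior, new_set, cover(0.4), pg$genome)
  expect_equal(n_genes(res_below$additions), 0L)

  # overlapping a new gene on the same strand blocks the rescue
  res_ov <- rescue_missing(prior, pg$set, cover(0.9), pg$genome)
  expect_equal(n_genes(res_ov$additions), 0L)
})
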