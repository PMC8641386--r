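test_that("loci group by same-strand exonic overlap with transitive closure", {
  same <- make_isoform_set("chr1", "+", list(
    t1 = list(c(0L, 100L), c(200L, 300L)),
    t2 = list(c(50L, 100L), c(200L, 250L))))
  expect_equal(length(unique(group_loci(same)$locus_id)), 1L)

  anti <- annotation_set(
    genes = tibble::tibble(gene_id = c("g1", "g2"), seq_id = "chr1",
                           start = 0L, end = 300L, strand = c("+", "-")),
    transcripts = tibble::tibble(transcript_id = c("t1", "t2"),
                                 gene_id = c("g1", "g2")),
    exons = tibble::tibble(transcript_id = c("t1", "t2"), seq_id = "chr1",
                           start = 0L, end = 300L, strand = c("+", "-")),
    cds = tibble::tibble(transcript_id = character(), seq_id = character(),
                         start = integer(), end = integer(),
                         strand = character(), phase = integer()))
  expect_equal(length(unique(group_loci(anti)$locus_id)), 2L)

  chain <- make_isoform_set("chr1", "+", list(
    t1 = list(c(0L, 100L)), t2 = list(c(50L, 200L)), t3 = list(c(150L, 300L))))
  expect_equal(length(unique(group_loci(chain)$locus_id)), 1L)
})

test_that("each elementary event type is classified from its defining structure", {
  # reference transcript: 3 exons, introns [100,200) and [300,400)
  ref <- list(c(0L, 100L), c(200L, 300L), c(400L, 500L))
  cases <- list(
    ES = list(c(0L, 100L), c(400L, 500L)),                 # skips exon 2
    IR = list(c(0L, 100L), c(200L, 500L)),                 # retains intron 2
    AA = list(c(0L, 100L), c(180L, 300L), c(400L, 500L)),  # acceptor moved
    AD = list(c(0L, 120L), c(200L, 300L), c(400L, 500L)),  # donor moved
    MX = list(c(0L, 100L), c(320L, 380L), c(400L, 500L)))  # swapped middle exon
  for (type in names(cases)) {
    x <- make_isoform_set("chr1", "+", list(t1 = ref, t2 = cases[[type]]))
    ev <- extract_events(x)
    expect_equal(nrow(ev), 1L, info = type)
    expect_equal(ev$event_type, type, info = type)
  }
})

test_that("AA and AD swap on the minus strand", {
  ref <- list(c(0L, 100L), c(200L, 300L))
  alt <- list(c(0L, 100L), c(180L, 300L))  # intron end moved
  plus <- make_isoform_set("chr1", "+", list(t1 = ref, t2 = alt))
  minus <- make_isoform_set("chr1", "-", list(t1 = ref, t2 = alt))
  expect_equal(extract_events(plus)$event_type, "AA")
  expect_equal(extract_events(minus)$event_type, "AD")
})

test_that("events deduplicate across pairs and are permutation invariant", {
  ref <- list(c(0L, 100L), c(200L, 300L), c(400L, 500L))
  skip2 <- list(c(0L, 100L), c(400L, 500L))
  # two distinct isoforms sharing the same skip, plus the reference
  x <- make_isoform_set("chr1", "+",
                        list(t1 = ref, t2 = skip2, t3 = skip2))
  ev <- extract_events(x)
  expect_equal(nrow(ev), 1L)
  expect_setequal(unlist(c(ev$transcripts_a, ev$transcripts_b)),
                  c("t1", "t2", "t3"))
  xr <- make_isoform_set("chr1", "+",
                         list(t1 = skip2, t2 = ref, t3 = skip2))
  evr <- extract_events(xr)
  expect_equal(evr$event_type, ev$event_type)
  expect_equal(evr$flank_left, ev$flank_left)
  expect_equal(evr$flank_right, ev$flank_right)
})

test_that("single-transcript loci yield no events", {
  x <- make_isoform_set("chr1", "+", list(t1 = list(c(0L, 100L), c(200L, 300L))))
  expect_equal(nrow(extract_events(x)), 0L)
})

test_that("canonical flags follow GT-AG dinucleotides, strand and minimum length", {
  # genome with GT..AG intron at [100,200) on plus strand
  s <- strrep("A", 500)
  substr(s, 101, 102) <- "GT"; substr(s, 199, 200) <- "AG"
  genome <- c(chr1 = s)
  ref <- list(c(0L, 100L), c(200L, 300L))
  ir <- list(c(0L, 300L))
  x <- make_isoform_set("chr1", "+", list(t1 = ref, t2 = ir))
  ev <- is_canonical(extract_events(x), genome)
  expect_true(ev$canonical)

  # same intron read on the minus strand is CT..AC: non-canonical
  xm <- make_isoform_set("chr1", "-", list(t1 = ref, t2 = ir))
  evm <- is_canonical(extract_events(xm), genome)
  expect_false(evm$canonical)

  # a GT..AG intron shorter than the basic-rules minimum is not canonical
  s2 <- strrep("A", 100)
  substr(s2, 41, 42) <- "GT"; substr(s2, 49, 50) <- "AG"
  g2 <- c(chr1 = s2)
  short <- make_isoform_set("chr1", "+", list(
    t1 = list(c(0L, 40L), c(50L, 100L)), t2 = list(c(0L, 100L))))
  ev2 <- is_canonical(extract_events(short), g2,
                      splice_site_rules(min_intron_length = 20))
  expect_false(ev2$canonical)
  ev3 <- is_canonical(extract_events(short), g2,
                      splice_site_rules(min_intron_length = 5))
  expect_true(ev3$canonical)
})

test_that("events localize to UTR only when no locus CDS overlaps the variable region", {
  ref <- list(c(0L, 100L), c(200L, 300L), c(400L, 500L))
  ir2 <- list(c(0L, 100L), c(200L, 500L))   # retains intron [300,400)
  # CDS ends at 250: the retained intron is downstream UTR
  utr_case <- make_isoform_set("chr1", "+", list(t1 = ref, t2 = ir2),
                               cds = list(t1 = list(c(10L, 100L), c(200L, 250L))))
  ev <- localize_events(extract_events(utr_case), utr_case)
  expect_true(ev$in_utr)

  # CDS spans into exon 3: the same event now touches coding sequence
  cds_case <- make_isoform_set("chr1", "+", list(t1 = ref, t2 = ir2),
                               cds = list(t1 = list(c(10L, 100L), c(200L, 300L),
                                                    c(400L, 450L)),
                                          t2 = list(c(10L, 100L), c(200L, 320L))))
  ev2 <- localize_events(extract_events(cds_case), cds_case)
  expect_false(ev2$in_utr)

  # a CDS-less locus localizes to UTR with a warning
  nocds <- make_isoform_set("chr1", "+", list(t1 = ref, t2 = ir2))
  expect_warning(ev3 <- localize_events(extract_events(nocds), nocds),
                 "no CDS")
  expect_true(ev3$in_utr)
})

test_that("typed event counts match the brute-force oracle on random loci", {
  withr::with_seed(99, {
    for (rep in 1:40) {
      iso <- random_locus(n_iso = sample(2:5, 1), n_seg = sample(4:10, 1))
      x <- make_isoform_set("chr1", "+", lapply(iso, function(m) {
        lapply(seq_len(nrow(m)), function(i) m[i, ])
      }))
      ev <- extract_events(x)
      got <- table(factor(ev$event_type,
                          levels = c("ES", "AA", "AD", "MX", "IR", "COMPLEX")))
      want <- oracle_event_counts(iso, "+")
      expect_equal(as.integer(got), as.integer(want),
                   info = paste("locus rep", rep))
    }
  })
})

test_that("classified and canonical counts nest inside the total", {
  b <- small_bundle(3)
  ev <- classify_splice_events(b$isoform_set, b$genome)
  expect_lte(sum(ev$canonical), nrow(ev))
  expect_lte(sum(ev$event_type != "COMPLEX"), nrow(ev))
  g <- glance(ev)
  expect_equal(g$total, nrow(ev))
  expect_equal(g$classified, sum(ev$event_type != "COMPLEX"))
})
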