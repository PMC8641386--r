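test_that("GFF3 coordinates are converted to 0-based half-open on read", {
  tf <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\t.\tgene\t11\t20\t.\t+\t.\tID=g1"), tf)
  x <- read_gff3(tf)
  expect_equal(x$genes$start, 10L)
  expect_equal(x$genes$end, 20L)
})

test_that("malformed GFF3 lines abort with the line number", {
  tf <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\t.\tgene\t11\t20\t.\t+\t.\tID=g1",
               "chr1\t.\tgene\t30\t20\t.\t+\t.\tID=g2"), tf)
  expect_error(read_gff3(tf), "line 3.*end < start")
  writeLines(c("chr1\t.\tgene\t11\t20\t.\t+\t.", ""), tf)
  expect_error(read_gff3(tf), "line 1.*9 tab-separated")
  writeLines("chr1\t.\tgene\t11\t20\t.\t?\t.\tID=g1", tf)
  expect_error(read_gff3(tf), "unknown strand")
})

test_that("orphan mRNA features follow the feature policy", {
  tf <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\t.\tmRNA\t11\t20\t.\t+\t.\tID=m1;Parent=gX",
               "chr1\t.\texon\t11\t20\t.\t+\t.\tParent=m1"), tf)
  expect_error(read_gff3(tf, feature_policy = "strict"), "m1")
  x <- read_gff3(tf, feature_policy = "lenient")
  expect_equal(n_genes(x), 1L)
  expect_true("m1" %in% x$transcripts$transcript_id)
})

test_that("per-feature-type counts match the file", {
  tf <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\t.\tgene\t1\t500\t.\t+\t.\tID=g1",
    "chr1\t.\tmRNA\t1\t500\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\t.\tmRNA\t1\t400\t.\t+\t.\tID=g1.t2;Parent=g1",
    "chr1\t.\texon\t1\t100\t.\t+\t.\tParent=g1.t1",
    "chr1\t.\texon\t201\t500\t.\t+\t.\tParent=g1.t1",
    "chr1\t.\texon\t1\t100\t.\t+\t.\tParent=g1.t2",
    "chr1\t.\texon\t201\t400\t.\t+\t.\tParent=g1.t2",
    "chr1\t.\tgene\t601\t900\t.\t-\t.\tID=g2",
    "chr1\t.\tmRNA\t601\t900\t.\t-\t.\tID=g2.t1;Parent=g2",
    "chr1\t.\texon\t601\t700\t.\t-\t.\tParent=g2.t1",
    "chr1\t.\texon\t801\t900\t.\t-\t.\tParent=g2.t1",
    "chr1\t.\texon\t751\t780\t.\t-\t.\tParent=g2.t1"
  ), tf)
  x <- read_gff3(tf)
  fc <- feature_counts(x)
  expect_equal(unname(fc[["gene"]]), 2)
  expect_equal(unname(fc[["mRNA"]]), 3)
  expect_equal(unname(fc[["exon"]]), 7)
})

test_that("genes without an mRNA child get a synthetic transcript", {
  tf <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\t.\tgene\t1\t100\t.\t+\t.\tID=g1",
               "chr1\t.\texon\t1\t100\t.\t+\t.\tParent=g1",
               "chr1\t.\tCDS\t10\t90\t.\t+\t0\tParent=g1"), tf)
  x <- read_gff3(tf)
  expect_equal(x$transcripts$transcript_id, "g1.t1")
  expect_equal(nrow(x$exons), 1L)
  expect_equal(nrow(x$cds), 1L)
})

test_that("GFF3 write/read round trip is the identity on canonical form", {
  g <- generate_genome(3, 1, lengths = 40000)
  pg <- plant_genes(g, 5, n_genes = 6, exons_per_gene = c(1, 4))
  tf <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(pg$set, tf)
  back <- read_gff3(tf, version_tag = pg$set$version_tag)
  cols <- c("gene_id", "seq_id", "start", "end", "strand")
  expect_equal(dplyr::arrange(back$genes[cols], gene_id),
               dplyr::arrange(pg$set$genes[cols], gene_id))
  srt <- function(d) as.data.frame(dplyr::arrange(d, transcript_id, start))
  expect_equal(srt(back$exons), srt(pg$set$exons))
  expect_equal(srt(back$cds[1:5]), srt(pg$set$cds[1:5]))
  # second round trip is byte-identical
  tf2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(back, tf2)
  expect_identical(readLines(tf), readLines(tf2))
})

test_that("an empty set writes only the version pragma and start 0 prints as 1", {
  empty <- filter_genes(make_set(list(
    list(id = "g", seq = "chr1", strand = "+", exons = list(c(0L, 10L))))),
    character(0))
  tf <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(empty, tf)
  expect_equal(readLines(tf), "##gff-version 3")
  one <- make_set(list(list(id = "g", seq = "chr1", strand = "+",
                            exons = list(c(0L, 10L)))))
  write_gff3(one, tf)
  expect_match(readLines(tf)[2], "\tgene\t1\t10\t")
})

test_that("reader coordinates agree with rtracklayer on a fixture", {
  skip_if_not_installed("rtracklayer")
  g <- generate_genome(3, 1, lengths = 40000)
  pg <- plant_genes(g, 5, n_genes = 4, exons_per_gene = c(2, 3))
  tf <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(pg$set, tf)
  gr <- rtracklayer::import(tf, format = "gff3")
  ref <- gr[gr$type == "gene"]
  mine <- read_gff3(tf)$genes
  mine <- mine[order(mine$start), ]
  ref <- ref[order(BiocGenerics::start(ref))]
  expect_equal(mine$start + 1L, BiocGenerics::start(ref))
  expect_equal(mine$end, BiocGenerics::end(ref))
})

test_that("spliced sequence extraction honours order and strand", {
  genome <- c(chr1 = "ATGCCAGGTTTT")
  x <- make_set(list(list(id = "g", seq = "chr1", strand = "+",
                          exons = list(c(0L, 6L)))))
  expect_equal(extract_spliced_sequence(x, "g.t1", genome, "exon"), "ATGCCA")
  xm <- make_set(list(list(id = "g", seq = "chr1", strand = "-",
                           exons = list(c(0L, 6L)))))
  expect_equal(extract_spliced_sequence(xm, "g.t1", genome, "exon"), "TGGCAT")
})

test_that("minus-strand multi-segment CDS equals reverse complement of the plus-strand concatenation", {
  genome <- c(chr1 = "AAACCCGGGTTTAAACCCGGGTTTAAACCC")
  segs <- list(c(2L, 10L), c(18L, 25L))
  plus <- paste0(substr(genome, 3, 10), substr(genome, 19, 25))
  xm <- make_set(list(list(id = "g", seq = "chr1", strand = "-",
                           exons = segs, cds = segs)))
  expect_equal(extract_spliced_sequence(xm, "g.t1", genome, "cds"),
               reverse_complement(plus))
})

test_that("out-of-bounds segments raise an error naming the transcript", {
  genome <- c(chr1 = "ATGCCA")
  x <- make_set(list(list(id = "g", seq = "chr1", strand = "+",
                          exons = list(c(0L, 10L)))))
  expect_error(extract_spliced_sequence(x, "g.t1", genome, "exon"),
               "g.t1")
})

test_that("translation follows the standard code with * stops and X ambiguity", {
  expect_equal(translate_cds("ATGGCTTAA"), "MA*")
  expect_equal(translate_cds("ATGTGATAA"), "M**")
  expect_warning(aa <- translate_cds("ATGGC"), "partial codon")
  expect_equal(aa, "M")
  expect_equal(translate_cds("ATGNNNTAA"), "MX*")
  expect_error(translate_cds(""), "empty")
})

test_that("translation length is floor(len/3) for random coding sequences", {
  withr::with_seed(9, {
    for (i in 1:20) {
      n <- sample(3:50, 1)
      s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
      aa <- suppressWarnings(translate_cds(s))
      expect_equal(nchar(aa), n %/% 3)
    }
  })
})

test_that("evidence and repeat GFF3 round-trip", {
  ev <- dplyr::bind_rows(
    ev_rows("e1", "PROTEIN", "chr1", "+", list(c(0L, 50L), c(80L, 120L))),
    ev_rows("e2", "LONG_READ", "chr1", "-", list(c(200L, 400L))))
  tf <- withr::local_tempfile(fileext = ".gff3")
  write_evidence_gff3(ev, tf)
  back <- read_evidence_gff3(tf)
  expect_equal(dplyr::arrange(back, evidence_id, start),
               dplyr::arrange(ev, evidence_id, start))
  reps <- tibble::tibble(seq_id = "chr1", start = 5L, end = 50L, strand = ".",
                         repeat_class = "LTR/Gypsy")
  write_repeats_gff3(reps, tf)
  expect_equal(read_repeats_gff3(tf), reps)
})
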