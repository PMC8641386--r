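test_that("percent reproduces printed ratio formatting (half away from zero)", {
  expect_equal(percent(589, 789, 1), 74.7)
  expect_equal(percent(0, 7, 1), 0)
  expect_equal(percent(721, 1772, 2), 40.69)
  expect_equal(percent(1, 8, 1), 12.5)   # exact .5 rounds away from zero
  expect_equal(percent(1, 800, 1), 0.1)
  expect_error(percent(1, 0), "denominator")
})

test_that("identical annotations map one-to-one with fraction 1", {
  x <- make_set(list(
    list(id = "a", seq = "chr1", strand = "+", exons = list(c(0L, 100L))),
    list(id = "b", seq = "chr1", strand = "-", exons = list(c(200L, 400L)))))
  vm <- map_versions(x, x)
  expect_true(all(vm$relation == "ONE_TO_ONE"))
  expect_true(all(vm$overlap_fraction_of_shorter == 1))
})

test_that("one old gene split into four and nine fragments joined into one", {
  old1 <- make_set(list(list(id = "big", seq = "chr1", strand = "+",
                             exons = list(c(0L, 4000L)))))
  new4 <- make_set(lapply(1:4, function(i) {
    list(id = paste0("n", i), seq = "chr1", strand = "+",
         exons = list(c((i - 1) * 1000L, i * 1000L - 100L)))
  }))
  vm <- map_versions(old1, new4)
  expect_equal(vm$relation, "ONE_TO_MANY")
  expect_equal(length(vm$new_ids[[1]]), 4L)

  old9 <- make_set(lapply(1:9, function(i) {
    list(id = paste0("o", i), seq = "chr1", strand = "+",
         exons = list(c((i - 1) * 300L, i * 300L - 50L)))
  }))
  new1 <- make_set(list(list(id = "joined", seq = "chr1", strand = "+",
                             exons = list(c(0L, 2700L)))))
  vm9 <- map_versions(old9, new1)
  expect_equal(vm9$relation, "MANY_TO_ONE")
  expect_equal(length(vm9$old_ids[[1]]), 9L)
})

test_that("strand and threshold rules gate the edges", {
  old <- make_set(list(list(id = "o", seq = "chr1", strand = "+",
                            exons = list(c(0L, 1000L)))))
  flipped <- make_set(list(list(id = "n", seq = "chr1", strand = "-",
                                exons = list(c(0L, 1000L)))))
  vm <- map_versions(old, flipped)
  expect_setequal(vm$relation, c("OLD_ONLY", "NEW_ONLY"))

  # overlap 400 of a 1000-bp shorter gene: edge at 0.4 but not at 0.5
  part <- make_set(list(list(id = "n", seq = "chr1", strand = "+",
                             exons = list(c(600L, 1600L)))))
  expect_equal(map_versions(old, part, min_fraction = 0.4)$relation, "ONE_TO_ONE")
  expect_setequal(map_versions(old, part, min_fraction = 0.5)$relation,
                  c("OLD_ONLY", "NEW_ONLY"))
})

test_that("mapping is symmetric and partitions every gene exactly once", {
  b <- small_bundle(5)
  vm <- map_versions(b$prior_set, b$predicted_set)
  rev <- map_versions(b$predicted_set, b$prior_set)
  flip <- c(ONE_TO_ONE = "ONE_TO_ONE", ONE_TO_MANY = "MANY_TO_ONE",
            MANY_TO_ONE = "ONE_TO_MANY", MANY_TO_MANY = "MANY_TO_MANY",
            OLD_ONLY = "NEW_ONLY", NEW_ONLY = "OLD_ONLY")
  expect_equal(sort(unname(flip[vm$relation])), sort(rev$relation))
  expect_setequal(unlist(vm$old_ids), b$prior_set$genes$gene_id)
  expect_setequal(unlist(vm$new_ids), b$predicted_set$genes$gene_id)
  expect_equal(length(unlist(vm$old_ids)), n_genes(b$prior_set))
  expect_equal(length(unlist(vm$new_ids)), n_genes(b$predicted_set))
})

test_that("raising min_fraction never adds edges", {
  b <- small_bundle(5)
  edge_count <- function(th) {
    vm <- map_versions(b$prior_set, b$predicted_set, min_fraction = th)
    sum(vm$relation %in% c("ONE_TO_ONE", "ONE_TO_MANY", "MANY_TO_ONE",
                           "MANY_TO_MANY"))
  }
  counts <- vapply(c(0.3, 0.5, 0.7), edge_count, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("summarize_mapping reports novel genes and recovered broken genes", {
  b <- small_bundle(5)
  # plant 2 novel genes in the new set only
  novel <- make_set(list(
    list(id = "novel1", seq = "LG1", strand = "+", exons = list(c(80000L, 80500L))),
    list(id = "novel2", seq = "sc1", strand = "-", exons = list(c(80000L, 80400L)))))
  new_plus <- annotation_set(
    genes = dplyr::bind_rows(b$predicted_set$genes, novel$genes),
    transcripts = dplyr::bind_rows(b$predicted_set$transcripts, novel$transcripts),
    exons = dplyr::bind_rows(b$predicted_set$exons, novel$exons),
    cds = dplyr::bind_rows(b$predicted_set$cds, novel$cds))
  vm <- map_versions(b$prior_set, new_plus)
  s <- summarize_mapping(vm)
  expect_equal(s$count[s$metric == "new_only"], 2)

  # the premature-stop plantings broke two prior genes in the mutated genome
  rep <- validate_set(b$prior_set, b$genome)
  s2 <- summarize_mapping(vm, old_reports = rep)
  expect_equal(s2$count[s2$metric == "old_broken"],
               sum(b$truth$corruptions$corruption == "premature_stop"))
  expect_lte(s2$count[s2$metric == "broken_recovered"],
             s2$count[s2$metric == "old_broken"])

  # with a clean old set, recovery rows are reported as zero
  clean_old <- make_set(list(list(id = "a", seq = "chr1", strand = "+",
                                  exons = list(c(0L, 90L)),
                                  cds = list(c(0L, 90L)))))
  g0 <- c(chr1 = paste0("ATG", strrep("AAA", 28), "TAG"))
  s3 <- summarize_mapping(map_versions(clean_old, clean_old),
                          old_reports = validate_set(clean_old, g0))
  expect_equal(s3$count[s3$metric == "broken_recovered"], 0)
})
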