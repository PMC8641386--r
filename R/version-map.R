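#' Printed-style percentage
#'
#' `100 * numerator / denominator`, rounded half-away-from-zero to `digits`
#' decimals — the convention used when reporting annotation bookkeeping
#' ratios.
#'
#' @param numerator,denominator Counts; `denominator` must be positive.
#' @param digits Decimal places (default 1).
#' @return A numeric percentage.
#' @export
percent <- function(numerator, denominator, digits = 1) {
  if (any(denominator <= 0)) abort("percent(): denominator must be positive")
  stopifnot(digits >= 0)
  x <- 100 * numerator / denominator
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Map genes between two annotation versions by coordinate overlap
#'
#' An edge between an old and a new gene exists iff they share `seq_id` and
#' strand and overlap by at least `min_fraction` of the shorter gene's span
#' length. Connected components of the bipartite edge graph become entries
#' whose relation follows the component shape; edge-less genes become
#' `OLD_ONLY`/`NEW_ONLY`.
#'
#' @param old_set,new_set [annotation_set()]s to compare.
#' @param min_fraction Minimum overlap as a fraction of the shorter gene
#'   (default 0.5, `>=` semantics).
#' @return A `version_map` tibble: `relation`, `old_ids` (list), `new_ids`
#'   (list), `overlap_fraction_of_shorter` (max over the component's edges).
#' @export
map_versions <- function(old_set, new_set, min_fraction = 0.5) {
  og <- old_set$genes
  ng <- new_set$genes
  edges <- purrr::map_dfr(seq_len(nrow(og)), function(i) {
    cand <- which(ng$seq_id == og$seq_id[i] & ng$strand == og$strand[i] &
                    ng$start < og$end[i] & ng$end > og$start[i])
    if (length(cand) == 0) return(NULL)
    ov <- iv_overlap(og$start[i], og$end[i], ng$start[cand], ng$end[cand])
    shorter <- pmin(og$end[i] - og$start[i], ng$end[cand] - ng$start[cand])
    frac <- ov / shorter
    keep <- frac >= min_fraction
    if (!any(keep)) return(NULL)
    tibble(old = og$gene_id[i], new = ng$gene_id[cand[keep]], frac = frac[keep])
  })
  old_v <- paste0("O:", og$gene_id)
  new_v <- paste0("N:", ng$gene_id)
  g <- igraph::make_empty_graph(directed = FALSE) |>
    igraph::add_vertices(length(old_v) + length(new_v),
                         name = c(old_v, new_v))
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(paste0("O:", edges$old), paste0("N:", edges$new)))
  }
  comp <- igraph::components(g)
  entries <- purrr::map_dfr(seq_len(comp$no), function(k) {
    vs <- names(comp$membership)[comp$membership == k]
    olds <- sub("^O:", "", vs[startsWith(vs, "O:")])
    news <- sub("^N:", "", vs[startsWith(vs, "N:")])
    relation <- if (length(news) == 0) "OLD_ONLY"
      else if (length(olds) == 0) "NEW_ONLY"
      else if (length(olds) == 1 && length(news) == 1) "ONE_TO_ONE"
      else if (length(olds) == 1) "ONE_TO_MANY"
      else if (length(news) == 1) "MANY_TO_ONE"
      else "MANY_TO_MANY"
    frac <- if (nrow(edges) == 0) 0 else {
      sub <- edges$frac[edges$old %in% olds & edges$new %in% news]
      if (length(sub) == 0) 0 else max(sub)
    }
    tibble(relation = relation, old_ids = list(sort(olds)),
           new_ids = list(sort(news)), overlap_fraction_of_shorter = frac)
  })
  class(entries) <- c("version_map", class(entries))
  entries
}

#' @export
tidy.version_map <- function(x, ...) {
  tibble(
    relation = x$relation,
    old_ids = map_chr(x$old_ids, paste, collapse = ","),
    new_ids = map_chr(x$new_ids, paste, collapse = ","),
    fraction = x$overlap_fraction_of_shorter
  )
}

#' @export
glance.version_map <- function(x, ...) {
  counts <- table(factor(x$relation, levels = c(
    "ONE_TO_ONE", "ONE_TO_MANY", "MANY_TO_ONE", "MANY_TO_MANY",
    "OLD_ONLY", "NEW_ONLY")))
  as_tibble(as.list(counts))
}

#' Summarize a cross-version gene mapping
#'
#' Counts mapped/unmapped genes, the fraction of new genes with no old-version
#' counterpart (newly predicted), and — when validation reports of the old set
#' are supplied — how many old broken genes were recovered, stratified into
#' one-to-one vs multi-gene relations.
#'
#' @param entries A `version_map` from [map_versions()].
#' @param old_reports Optional `validation_report` of the old set.
#' @param te_labels Optional character vector of putative-TE gene ids to
#'   report alongside.
#' @return A tibble of `metric`, `count`, `percent` rows. Percentages use
#'   [percent()]; rows whose denominator is unavailable carry `NA`.
#' @export
summarize_mapping <- function(entries, old_reports = NULL, te_labels = NULL) {
  n_old <- length(unlist(entries$old_ids))
  n_new <- length(unlist(entries$new_ids))
  new_only <- unlist(entries$new_ids[entries$relation == "NEW_ONLY"])
  old_only <- unlist(entries$old_ids[entries$relation == "OLD_ONLY"])
  mapped_old <- n_old - length(old_only)
  rows <- tibble(
    metric = c("old_genes", "new_genes", "old_mapped", "old_unmapped", "new_only"),
    count = c(n_old, n_new, mapped_old, length(old_only), length(new_only)),
    percent = c(NA, NA,
                if (n_old > 0) percent(mapped_old, n_old, 1) else NA,
                if (n_old > 0) percent(length(old_only), n_old, 1) else NA,
                if (n_new > 0) percent(length(new_only), n_new, 1) else NA)
  )
  if (!is.null(old_reports)) {
    broken <- old_reports$gene_id[old_reports$n_flags > 0]
    if (length(broken) == 0) {
      rows <- bind_rows(rows, tibble(
        metric = c("old_broken", "broken_recovered"),
        count = c(0L, 0L), percent = c(NA_real_, NA_real_)))
    } else {
      rec_one <- entries |>
        filter(.data$relation == "ONE_TO_ONE") |>
        pull("old_ids") |> unlist()
      rec_multi <- entries |>
        filter(.data$relation %in% c("ONE_TO_MANY", "MANY_TO_ONE", "MANY_TO_MANY")) |>
        pull("old_ids") |> unlist()
      n_rec_one <- sum(broken %in% rec_one)
      n_rec_multi <- sum(broken %in% rec_multi)
      n_rec <- n_rec_one + n_rec_multi
      rows <- bind_rows(rows, tibble(
        metric = c("old_broken", "broken_recovered",
                   "broken_recovered_one_to_one", "broken_recovered_multi"),
        count = c(length(broken), n_rec, n_rec_one, n_rec_multi),
        percent = c(NA,
                    percent(n_rec, length(broken), 1),
                    if (n_rec > 0) percent(n_rec_one, n_rec, 1) else NA,
                    if (n_rec > 0) percent(n_rec_multi, n_rec, 1) else NA)))
    }
  }
  if (!is.null(te_labels)) {
    n_te_new_only <- sum(new_only %in% te_labels)
    rows <- bind_rows(rows, tibble(
      metric = "new_only_putative_te", count = n_te_new_only,
      percent = if (length(new_only) > 0) percent(n_te_new_only, length(new_only), 1) else NA))
  }
  rows
}

#' Write a version map to TSV
#' @param entries A `version_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_version_map_tsv <- function(entries, path) {
  utils::write.table(tidy(entries), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
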