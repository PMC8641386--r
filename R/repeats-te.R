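#' Pfam accessions treated as transposable-element domains
#'
#' Reverse transcriptase (PF00078, PF07727, PF13456, PF13966), integrase
#' (PF00665, PF13976), retrotransposon (PF03732, PF08284) and LTR (PF14223,
#' PF14244) domains.
#'
#' @return Character vector of Pfam accessions.
#' @export
te_domain_table <- function() {
  c("PF00078", "PF07727", "PF13456", "PF13966",
    "PF00665", "PF13976",
    "PF03732", "PF08284",
    "PF14223", "PF14244")
}

#' Repeat coverage of gene spans
#'
#' Fraction of each gene's genomic span covered by the union of repeat
#' intervals, strand-agnostic.
#'
#' @param x An [annotation_set()].
#' @param repeats Repeat tibble (`seq_id`, `start`, `end`, ...).
#' @return A tibble `gene_id`, `te_coverage` in the gene order of `x`.
#' @export
te_coverage <- function(x, repeats) {
  g <- x$genes
  if (any(g$end <= g$start)) abort("zero-length gene span")
  cov <- vapply(seq_len(nrow(g)), function(i) {
    r <- filter(repeats, .data$seq_id == g$seq_id[i])
    iv_cover_length(g$start[i], g$end[i], r$start, r$end) /
      (g$end[i] - g$start[i])
  }, numeric(1))
  tibble(gene_id = g$gene_id, te_coverage = cov)
}

#' Label putative transposable-element genes
#'
#' A gene is labeled `putative_te` iff its span is covered by repeats at or
#' above `coverage_threshold` ("50% or more"), or its Pfam domain set
#' intersects the TE domain table. Labeling only sets the attribute; gene
#' structures are never mutated.
#'
#' @param x An [annotation_set()].
#' @param repeats Repeat tibble.
#' @param domains Optional tibble `gene_id`, `pfam_accession`.
#' @param coverage_threshold Minimum repeat-coverage fraction (default 0.5,
#'   `>=` semantics).
#' @param te_domains Pfam accessions counted as TE domains.
#' @param lg_pattern,sc_pattern Regexes classifying `seq_id`s into linkage
#'   groups vs scaffolds for the summary.
#' @return The labeled `annotation_set`; the summary tibble is attached as
#'   attribute `"te_summary"` (see [te_label_summary()]).
#' @export
label_putative_tes <- function(x, repeats, domains = NULL,
                               coverage_threshold = 0.5,
                               te_domains = te_domain_table(),
                               lg_pattern = "^LG", sc_pattern = "^(sc|scaffold)") {
  cov <- te_coverage(x, repeats)
  by_cov <- cov$te_coverage >= coverage_threshold
  by_dom <- rep(FALSE, nrow(x$genes))
  if (!is.null(domains) && nrow(domains) > 0) {
    hits <- domains |>
      filter(.data$pfam_accession %in% te_domains) |>
      pull("gene_id") |> unique()
    by_dom <- x$genes$gene_id %in% hits
  }
  x$genes$putative_te <- by_cov | by_dom
  category <- dplyr::case_when(
    str_detect(x$genes$seq_id, lg_pattern) ~ "LG",
    str_detect(x$genes$seq_id, sc_pattern) ~ "scaffold",
    TRUE ~ "other"
  )
  labeled <- x$genes$putative_te
  summary <- tibble(
    n_genes = nrow(x$genes),
    n_putative_te = sum(labeled),
    n_by_coverage = sum(by_cov),
    n_by_domain = sum(by_dom),
    n_by_both = sum(by_cov & by_dom),
    n_te_lg = sum(labeled & category == "LG"),
    n_te_scaffold = sum(labeled & category == "scaffold"),
    pct_te_lg = if (sum(labeled) > 0) percent(sum(labeled & category == "LG"), sum(labeled), 2) else 0,
    pct_te_scaffold = if (sum(labeled) > 0) percent(sum(labeled & category == "scaffold"), sum(labeled), 2) else 0
  )
  attr(x, "te_summary") <- summary
  x
}

#' Summary table recorded by [label_putative_tes()]
#' @param x A labeled `annotation_set`.
#' @return A one-row tibble, or `NULL` if the set was never labeled.
#' @export
te_label_summary <- function(x) attr(x, "te_summary")
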