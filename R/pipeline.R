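#' One row of an alternative-splicing summary table
#'
#' Turns raw event counts into the canonical-percentage bookkeeping row used
#' in annotation reports: canonical events as a percentage of all events, and
#' classified-canonical events as a percentage of classified events.
#'
#' @param total_events,canonical_events,classified_events,classified_canonical
#'   Event counts.
#' @param label Row label.
#' @return A one-row tibble with counts and `pct_canonical`,
#'   `pct_classified_canonical` via [percent()].
#' @export
as_table_row <- function(total_events, canonical_events, classified_events,
                         classified_canonical, label = "isoforms") {
  tibble(
    label = label,
    total_events = total_events,
    canonical_events = canonical_events,
    pct_canonical = if (total_events > 0) percent(canonical_events, total_events, 1) else 0,
    classified_events = classified_events,
    classified_canonical = classified_canonical,
    pct_classified_canonical = if (classified_events > 0) {
      percent(classified_canonical, classified_events, 1)
    } else 0
  )
}

#' Build the report bundle from stage outputs
#'
#' Produces the two summary tables of the workflow: an alternative-splicing
#' table (total events, canonical count and percent, classified count,
#' classified-canonical count and percent, UTR-localized canonical count and
#' percent) and a versions table (raw genes, interrupted ORFs, putative TEs,
#' total correct genes). All percentages go through [percent()].
#'
#' @param events Optional `as_events` tibble (with `canonical`/`in_utr`).
#' @param validation Optional `validation_report` of the final set.
#' @param set Optional final [annotation_set()] (for TE and gene counts).
#' @param log Optional `curation_log`.
#' @param label Label for the AS table row.
#' @return A list of tibbles: `as_table`, `versions_table`, `curation_table`.
#' @export
build_report <- function(events = NULL, validation = NULL, set = NULL,
                         log = NULL, label = "isoforms") {
  as_table <- NULL
  if (!is.null(events)) {
    total <- nrow(events)
    canon <- if ("canonical" %in% names(events)) sum(events$canonical) else NA_integer_
    classified <- sum(events$event_type != "COMPLEX")
    class_canon <- if ("canonical" %in% names(events)) {
      sum(events$canonical & events$event_type != "COMPLEX")
    } else NA_integer_
    as_table <- as_table_row(total, canon, classified, class_canon, label)
    if (all(c("canonical", "in_utr") %in% names(events))) {
      utr_canon <- sum(events$canonical & events$in_utr)
      as_table$canonical_in_utr <- utr_canon
      as_table$pct_canonical_in_utr <-
        if (canon > 0) percent(utr_canon, canon, 1) else 0
    }
  }
  versions_table <- NULL
  if (!is.null(set)) {
    n_raw <- n_genes(set)
    n_interrupted <- if (!is.null(validation)) sum(validation$n_flags > 0) else NA_integer_
    n_te <- sum(set$genes$putative_te)
    n_correct <- if (!is.null(validation)) {
      clean <- validation$gene_id[validation$n_flags == 0]
      sum(clean %in% set$genes$gene_id[!set$genes$putative_te])
    } else NA_integer_
    versions_table <- tibble(
      metric = c("raw_genes", "interrupted_orfs", "putative_tes", "total_correct"),
      count = c(n_raw, n_interrupted, n_te, n_correct)
    )
  }
  curation_table <- if (!is.null(log)) glance(log) else NULL
  list(as_table = as_table, versions_table = versions_table,
       curation_table = curation_table)
}

#' Run the post-prediction curation workflow end to end
#'
#' Stage order: validate, curate (split/merge), rescue, TE-label, rename,
#' version-map, AS-classify, report. The curation bookkeeping identity is
#' asserted on every run. Stages whose inputs are absent are skipped.
#'
#' @param predicted The predicted [annotation_set()] to curate.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param evidence Evidence tibble (may be empty).
#' @param prior_set Optional prior-version [annotation_set()] (guides splits,
#'   rescue and version mapping).
#' @param repeats Optional repeat tibble for TE labeling.
#' @param domains Optional `gene_id`/`pfam_accession` tibble.
#' @param isoforms Optional isoform [annotation_set()] for AS classification.
#' @param scheme A [naming_scheme()].
#' @param config A [curation_config()].
#' @param rules A [splice_site_rules()].
#' @param out_dir Optional directory for TSV/GFF3/JSON outputs.
#' @return A list: `set` (curated, labeled, renamed annotation), `validation`
#'   (input-set report), `final_validation`, `log` (`curation_log`),
#'   `version_map`, `map_summary`, `events`, `report`.
#' @export
run_pipeline <- function(predicted, genome, evidence = empty_evidence(),
                         prior_set = NULL, repeats = NULL, domains = NULL,
                         isoforms = NULL, scheme = naming_scheme(),
                         config = curation_config(),
                         rules = splice_site_rules(), out_dir = NULL) {
  stage <- function(name, code) {
    tryCatch(force(code), error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  validation <- stage("validate", validate_set(predicted, genome))
  cur <- stage("curate", {
    splits <- detect_split_candidates(predicted, evidence, config)
    merges <- detect_merge_candidates(predicted, evidence, config)
    apply_actions(predicted, splits, merges, prior_set = prior_set,
                  genome = genome, config = config)
  })
  curated <- cur$set
  log <- cur$log
  if (!is.null(prior_set)) {
    res <- stage("rescue", rescue_missing(prior_set, curated, evidence, genome,
                                          config))
    if (n_genes(res$additions) > 0) {
      curated <- bind_annotation_sets(curated, res$additions)
    }
    log <- bind_rows(log, res$log)
    class(log) <- class(empty_curation_log())
    assert_curation_bookkeeping(n_genes(predicted), n_genes(curated), log)
  }
  if (!is.null(repeats)) {
    curated <- stage("te-label",
                     label_putative_tes(curated, repeats, domains = domains))
  }
  curated <- stage("rename", assign_locus_names(curated, scheme))
  vm <- NULL; vm_summary <- NULL
  if (!is.null(prior_set)) {
    vm <- stage("version-map", map_versions(prior_set, curated))
    vm_summary <- summarize_mapping(vm, old_reports = NULL)
  }
  events <- NULL
  if (!is.null(isoforms)) {
    events <- stage("as-classify", classify_splice_events(isoforms, genome, rules))
  }
  final_validation <- stage("final-validate", validate_set(curated, genome))
  report <- build_report(events = events, validation = final_validation,
                         set = curated, log = log)
  out <- list(set = curated, validation = validation,
              final_validation = final_validation, log = log,
              version_map = vm, map_summary = vm_summary,
              events = events, report = report)
  if (!is.null(out_dir)) write_report_bundle(out, out_dir)
  out
}

#' Write a pipeline result bundle to a directory
#'
#' @param result A list from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_gff3(result$set, file.path(dir, "curated.gff3"))
  write_validation_tsv(result$validation, file.path(dir, "validation.tsv"))
  write_curation_log_tsv(result$log, file.path(dir, "actions.tsv"))
  if (!is.null(result$version_map)) {
    write_version_map_tsv(result$version_map, file.path(dir, "version_map.tsv"))
  }
  if (!is.null(result$events)) {
    write_events_tsv(result$events, file.path(dir, "as_events.tsv"))
  }
  nm <- locus_name_map(result$set)
  if (!is.null(nm)) {
    utils::write.table(nm, file.path(dir, "idmap.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  report <- result$report
  json <- list(
    as_table = report$as_table,
    versions_table = report$versions_table,
    curation_table = report$curation_table,
    te_summary = te_label_summary(result$set),
    map_summary = result$map_summary
  )
  jsonlite::write_json(json[!vapply(json, is.null, logical(1))],
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
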