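#' Systematic locus naming scheme
#'
#' Locus names look like `Aa31LG1G10`: species prefix, annotation version
#' digits, sequence label (linkage group or scaffold with its number), and a
#' gene number that starts at `start_number` for the first gene at the 5' end
#' of each sequence and increases by `step`, leaving free numbers between tens
#' for future annotations.
#'
#' @param species_prefix Species prefix (default `"Aa"`).
#' @param version_digits Annotation version digits (default `"31"`).
#' @param lg_pattern Regex with one capture group extracting the linkage-group
#'   number from a `seq_id`.
#' @param scaffold_pattern Regex with one capture group extracting the
#'   scaffold number.
#' @param start_number First gene number per sequence (default 10).
#' @param step Increment between consecutive genes (default 10).
#' @return A list of class `naming_scheme`.
#' @export
naming_scheme <- function(species_prefix = "Aa", version_digits = "31",
                          lg_pattern = "^LG(\\d+)$",
                          scaffold_pattern = "^sc(?:affold)?[_]?(\\d+)$",
                          start_number = 10L, step = 10L) {
  stopifnot(step >= 1)
  structure(list(species_prefix = species_prefix,
                 version_digits = version_digits,
                 lg_pattern = lg_pattern, scaffold_pattern = scaffold_pattern,
                 start_number = as.integer(start_number),
                 step = as.integer(step)),
            class = "naming_scheme")
}

#' Assign systematic locus names
#'
#' Genes are ordered by start coordinate within each sequence (ties broken by
#' end then old id) and numbered `start_number, start_number + step, ...`.
#' Ordering uses the sequence's left end regardless of gene strand, the only
#' well-defined order for mixed-strand gene sets.
#'
#' @param x An [annotation_set()].
#' @param scheme A [naming_scheme()].
#' @return The set with `locus_name` filled; the old-id to new-name table is
#'   attached as attribute `"name_map"` (see [locus_name_map()]).
#' @export
assign_locus_names <- function(x, scheme = naming_scheme()) {
  seq_label <- function(seq_id) {
    lg <- str_match(seq_id, scheme$lg_pattern)[, 2]
    sc <- str_match(seq_id, scheme$scaffold_pattern)[, 2]
    if (!is.na(lg) && !is.na(sc)) {
      abort(paste0("sequence '", seq_id, "' matches both LG and scaffold patterns"))
    }
    if (!is.na(lg)) return(paste0("LG", lg))
    if (!is.na(sc)) return(paste0("sc", sc))
    abort(paste0("sequence '", seq_id, "' matches neither the LG nor the scaffold pattern"))
  }
  labels <- vapply(unique(x$genes$seq_id), seq_label, character(1))
  ordered <- x$genes |>
    arrange(.data$seq_id, .data$start, .data$end, .data$gene_id) |>
    group_by(.data$seq_id) |>
    mutate(number = scheme$start_number + (row_number() - 1L) * scheme$step) |>
    ungroup() |>
    mutate(locus_name = paste0(scheme$species_prefix, scheme$version_digits,
                               labels[.data$seq_id], "G", .data$number))
  map_tbl <- select(ordered, old_id = "gene_id", new_name = "locus_name")
  x$genes$locus_name <- map_tbl$new_name[match(x$genes$gene_id, map_tbl$old_id)]
  attr(x, "name_map") <- map_tbl
  x
}

#' Old-id to locus-name mapping recorded by [assign_locus_names()]
#' @param x A named `annotation_set`.
#' @return A tibble `old_id`, `new_name`, or `NULL`.
#' @export
locus_name_map <- function(x) attr(x, "name_map")
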