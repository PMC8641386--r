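# ggplot2 autoplot methods for the result objects.

#' @export
autoplot.validation_report <- function(object, ...) {
  counts <- table(factor(unlist(object$flag_list), levels = validation_flags))
  df <- tibble(flag = names(counts), n = as.integer(counts))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$flag, y = .data$n)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "flagged genes",
                  title = "Gene-model validation flags") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.as_events <- function(object, ...) {
  df <- count(as_tibble(object), .data$event_type,
              name = "n")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$event_type, y = .data$n)) +
    ggplot2::geom_col(fill = "#31a354") +
    ggplot2::labs(x = "event type", y = "events",
                  title = "Alternative-splicing events") +
    ggplot2::theme_minimal()
  if ("canonical" %in% names(object)) {
    df2 <- count(as_tibble(object), .data$event_type, .data$canonical, name = "n")
    p <- ggplot2::ggplot(df2, ggplot2::aes(x = .data$event_type, y = .data$n,
                                           fill = .data$canonical)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "event type", y = "events",
                    title = "Alternative-splicing events") +
      ggplot2::theme_minimal()
  }
  p
}

#' @export
autoplot.version_map <- function(object, ...) {
  df <- count(tibble(relation = object$relation), .data$relation, name = "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$relation, y = .data$n)) +
    ggplot2::geom_col(fill = "#756bb1") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "entries",
                  title = "Cross-version gene relations") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.curation_log <- function(object, ...) {
  df <- count(tibble(action = object$action), .data$action, name = "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$action, y = .data$n)) +
    ggplot2::geom_col(fill = "#d95f0e") +
    ggplot2::labs(x = NULL, y = "actions", title = "Curation actions") +
    ggplot2::theme_minimal()
}
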