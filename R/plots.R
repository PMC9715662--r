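# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_boxplot geom_step labs scale_y_log10 facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot the cohort substitution spectrum
#'
#' @param object An `aid_tracking` object.
#' @param top_n Number of most-mutated channels to show (default 30).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.aid_tracking <- function(object, top_n = 30, ...) {
  m <- .spectrum_matrix(object$matrix)
  totals <- colSums(m)
  d <- tibble(channel = names(totals), count = as.numeric(totals)) %>%
    mutate(substitution = stringr::str_extract(channel, "(?<=\\[).+(?=\\])")) %>%
    arrange(desc(count)) %>%
    head(top_n) %>%
    mutate(channel = factor(channel, levels = rev(channel)))
  ggplot(d, aes(x = count, y = channel, fill = .data$substitution)) +
    geom_col() +
    labs(x = "mutations", y = NULL, fill = "substitution",
         title = "Top tetranucleotide substitution channels") +
    theme_minimal()
}

#' @rdname domain_load
#' @param object A `domain_load` object.
#' @export
autoplot.domain_load <- function(object, ...) {
  d <- object$bins %>% filter(!is.na(class)) %>%
    mutate(class = factor(class, levels = DOMAIN_CLASSES))
  ggplot(d, aes(x = class, y = count, fill = class)) +
    geom_boxplot(show.legend = FALSE) +
    labs(x = NULL, y = "mutations per window",
         title = "Mutation load by chromatin domain class") +
    theme_minimal()
}

#' @rdname tss_profile
#' @param object A `tss_profile` object.
#' @export
autoplot.tss_profile <- function(object, ...) {
  d <- mutate(object$profile,
              strand_class = if_else(strand_class == "+",
                                     "positive-strand genes",
                                     "negative-strand genes"))
  ggplot(d, aes(x = bin_index * object$bin / 1000, y = load)) +
    geom_line() +
    facet_wrap(~strand_class, ncol = 1) +
    labs(x = "distance from TSS (kb, transcription direction)",
         y = "mutations per gene",
         title = "Mutation profile around transcription start sites") +
    theme_minimal()
}

#' @rdname hotspot_utilization
#' @param object A `hotspot_curves` object.
#' @export
autoplot.hotspot_curves <- function(object, ...) {
  ggplot(object$curves, aes(x = k, y = cum_fraction, colour = group)) +
    geom_step() +
    labs(x = "residues, by decreasing population recurrence",
         y = "cumulative fraction of group mutations", colour = NULL,
         title = "Hotspot utilization") +
    theme_minimal()
}

#' Rainfall plot of inter-mutation distances
#'
#' @param distances Output of [intermutation_distance()].
#' @param colour_col Optional column to colour points by (e.g. `"is_aid"`).
#' @return A ggplot.
#' @export
plot_rainfall <- function(distances, colour_col = NULL) {
  d <- filter(distances, !is.na(distance))
  p <- if (is.null(colour_col)) {
    ggplot(d, aes(x = pos, y = distance))
  } else {
    ggplot(d, aes(x = pos, y = distance, colour = .data[[colour_col]]))
  }
  p + geom_point(size = 0.4, alpha = 0.6) +
    scale_y_log10() +
    facet_wrap(~contig, scales = "free_x") +
    labs(x = "genomic position", y = "distance to previous mutation (bp)",
         title = "Inter-mutation distance") +
    theme_minimal()
}
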