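# ggplot2 front-ends for the main result types.

#' @importFrom ggplot2 ggplot aes geom_line geom_ribbon geom_tile geom_col
#'   geom_point labs theme_minimal scale_fill_viridis_c facet_wrap autoplot
NULL

#' Plot a metaprofile with its bootstrap confidence band
#'
#' @method autoplot metaprofile
#' @param object a `metaprofile` tibble from [metaprofile()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.metaprofile <- function(object, ...) {
  ggplot(object, aes(x = .data$offset, y = .data$mean)) +
    geom_ribbon(aes(ymin = .data$ci_lo, ymax = .data$ci_hi), alpha = 0.25) +
    geom_line() +
    labs(x = "offset from anchor (nt)", y = "mean normalized coverage (CPM/TPM)",
         subtitle = sprintf("n = %d regions, 95%% bootstrap CI", object$n[1])) +
    theme_minimal()
}

#' Plot several metaprofiles (e.g. per regulation class) together
#'
#' @param profiles named list of `metaprofile` tibbles.
#' @return a ggplot.
#' @export
plot_metaprofiles <- function(profiles) {
  df <- bind_rows(purrr::imap(profiles, ~mutate(.x, group = .y)))
  ggplot(df, aes(x = .data$offset, y = .data$mean, color = .data$group,
                 fill = .data$group)) +
    geom_ribbon(aes(ymin = .data$ci_lo, ymax = .data$ci_hi), alpha = 0.2,
                color = NA) +
    geom_line() +
    labs(x = "offset from anchor (nt)",
         y = "mean normalized coverage (CPM/TPM)") +
    theme_minimal()
}

#' Heat map of per-UTR min-max-normalized cross-link signal
#'
#' Rows are UTRs (ordered as supplied), columns positions; the terminal PAS
#' of each UTR is overlaid as a dot.
#'
#' @method autoplot utr_heatmap
#' @param object a `utr_heatmap` from [per_utr_heatmap()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.utr_heatmap <- function(object, ...) {
  m <- object$matrix
  df <- tibble(
    gene = rep(rownames(m), times = ncol(m)),
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    pos = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  ) %>% filter(!is.na(.data$value))
  pas_df <- tibble(row = seq_len(nrow(m)), pos = object$pas) %>%
    filter(!is.na(.data$pos))
  ggplot(df, aes(x = .data$pos, y = .data$row, fill = .data$value)) +
    geom_tile() +
    geom_point(data = pas_df, aes(x = .data$pos, y = .data$row),
               inherit.aes = FALSE, color = "green3", size = 0.6) +
    scale_fill_viridis_c(name = "min-max signal") +
    labs(x = "position in 3'UTR (nt)", y = "3'UTR") +
    theme_minimal()
}

#' Plot motif-group coverage around cross-link sites
#'
#' @param coverage tibble from [motif_coverage_around_crosslinks()], or a
#'   named list of them (one per motif group).
#' @return a ggplot.
#' @export
plot_motif_coverage <- function(coverage) {
  if (!is.data.frame(coverage)) {
    coverage <- bind_rows(purrr::imap(coverage, ~mutate(.x, group = .y)))
  } else if (!"group" %in% names(coverage)) {
    coverage$group <- "group"
  }
  ggplot(coverage, aes(x = .data$offset, y = .data$pct, color = .data$group)) +
    geom_line() +
    labs(x = "offset from cross-link (nt)", y = "% cDNAs covered by group k-mer") +
    theme_minimal()
}

#' Plot nucleotide composition around the PAS
#'
#' @param composition tibble from [nucleotide_composition_around_pas()].
#' @return a ggplot.
#' @export
plot_nucleotide_composition <- function(composition) {
  ggplot(composition, aes(x = .data$offset, y = .data$pct_smoothed,
                          color = .data$base)) +
    geom_line() +
    labs(x = "offset from PAS start (nt)", y = "% of sequences") +
    theme_minimal()
}

#' Plot the two feature-importance measures of a stability model
#'
#' @param model a `stability_model`.
#' @param top_n features shown.
#' @return a ggplot.
#' @export
plot_feature_importance <- function(model, top_n = 15) {
  df <- tidy(model) %>%
    head(top_n) %>%
    tidyr::pivot_longer(c("relative_influence", "permutation_importance"),
                        names_to = "measure", values_to = "value")
  ggplot(df, aes(x = stats::reorder(.data$feature, .data$value), y = .data$value)) +
    geom_col() +
    facet_wrap(~measure, scales = "free_x") +
    ggplot2::coord_flip() +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot training history of the sequence classifier
#'
#' @param model a `seq_classifier`.
#' @return a ggplot.
#' @export
plot_training_history <- function(model) {
  df <- model$history %>%
    tidyr::pivot_longer(c("train_loss", "val_loss"),
                        names_to = "set", values_to = "loss")
  ggplot(df, aes(x = .data$epoch, y = .data$loss, color = .data$set)) +
    geom_line() +
    labs(x = "epoch", y = "cross-entropy loss") +
    theme_minimal()
}
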