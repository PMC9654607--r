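#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot Kaplan-Meier curves
#'
#' Step-function survival curves, one per group if the curve table carries
#' a `group` column (bind several [km_estimate()] results together to
#' overlay signature-high and signature-low).
#'
#' @param object A `uro_km` tibble from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.uro_km <- function(object, ...) {
  d <- as_tibble(object)
  has_group <- "group" %in% names(d)
  if (!has_group) d$group <- "all"
  # prepend the (0, 1) anchor so curves start at full survival
  d <- dplyr::bind_rows(
    dplyr::distinct(d, .data$group) %>%
      mutate(time = 0, survival = 1),
    d
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = .data$time, y = .data$survival, colour = .data$group
  )) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!has_group) p <- p + ggplot2::guides(colour = "none")
  p
}

#' Plot the distribution of signature scores
#'
#' Histogram of per-patient scores, filled by stratification label when a
#' group assignment is supplied — the visual counterpart of the
#' high/low k-means split.
#'
#' @param scores Score tibble from [compute_scores()].
#' @param groups Optional stratification tibble from [kmeans2()].
#' @param bins Histogram bins. Default 30.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, groups = NULL, bins = 30) {
  d <- scores
  if (!is.null(groups)) {
    d <- dplyr::left_join(d, groups[c("patient_id", "label")], by = "patient_id")
  } else {
    d$label <- "all"
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, fill = .data$label)) +
    ggplot2::geom_histogram(bins = bins, position = "identity", alpha = 0.7) +
    ggplot2::labs(x = "Signature score", y = "Patients", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot mutational-signature exposures by stratification group
#'
#' Log-scaled box plots of each exposure column split by signature-high vs
#' signature-low, the layout in which APOBEC (SBS2/SBS13) enrichment shows
#' up against the SBS4/SBS5 controls.
#'
#' @param mutation Mutation tibble.
#' @param groups Stratification tibble from [kmeans2()].
#' @return A ggplot object.
#' @export
plot_exposures <- function(mutation, groups) {
  d <- dplyr::inner_join(mutation, groups[c("patient_id", "label")],
                         by = "patient_id") %>%
    tidyr::pivot_longer(
      dplyr::all_of(c("SBS2", "SBS13", "SBS4", "SBS5")),
      names_to = "signature", values_to = "exposure"
    )
  d$signature <- factor(d$signature, levels = c("SBS2", "SBS13", "SBS4", "SBS5"))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$label, y = .data$exposure, fill = .data$label
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~signature, nrow = 1) +
    ggplot2::labs(x = NULL, y = "Exposure (mutations)", fill = NULL) +
    ggplot2::theme_minimal()
}
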