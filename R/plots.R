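#' Plot elution profiles
#'
#' Line plot of intensity across fractions for selected proteins, faceted
#' by condition (and replicate when present) - the standard co-elution
#' view for judging shared peaks by eye.
#'
#' @param profiles A `cf_profiles` tibble.
#' @param proteins Protein ids to show (default: first 6).
#' @param condition Optional condition filter.
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles, proteins = NULL, condition = NULL) {
  if (!is.null(condition)) {
    profiles <- profiles[profiles$condition %in% condition, ]
  }
  proteins <- proteins %||% utils::head(unique(profiles$protein_id), 6)
  profiles <- profiles[profiles$protein_id %in% proteins, ]
  long <- tidyr::unnest(
    dplyr::mutate(profiles,
                  fraction = list(seq_along(profiles$intensity[[1]]))),
    cols = c("fraction", "intensity")
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$fraction,
                                          y = .data$intensity,
                                          colour = .data$protein_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "SEC fraction", y = "intensity", colour = "protein") +
    ggplot2::theme_minimal()
  if ("replicate" %in% names(long)) {
    p + ggplot2::facet_grid(replicate ~ condition)
  } else {
    p + ggplot2::facet_wrap(~condition)
  }
}

#' @rdname autoplot-cofrac
#' @exportS3Method ggplot2::autoplot
autoplot.cf_roc <- function(object, ...) {
  sel <- tibble::tibble(fpr = object$selected_fpr, tpr = object$selected_tpr)
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(data = sel, colour = "darkgreen", size = 3) +
    ggplot2::annotate("text", x = 0.7, y = 0.1,
                      label = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::labs(x = "false-positive rate", y = "true-positive rate") +
    ggplot2::theme_minimal()
}

#' Autoplot methods for pipeline result objects
#'
#' `autoplot()` on a `cf_roc` draws the ROC curve with the selected
#' operating point; on a `cf_calibration` the standards and the fitted
#' log-linear curve; on a trained `cf_classifier` the loss history.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-cofrac
#' @exportS3Method ggplot2::autoplot
autoplot.cf_calibration <- function(object, ...) {
  std <- object$standards
  ggplot2::ggplot(std, ggplot2::aes(x = .data$apex_fraction,
                                    y = log10(.data$mw_da))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "apex fraction", y = "log10 MW (Da)",
                  title = sprintf("SEC calibration (r2 = %.3f)",
                                  object$fit_r2)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-cofrac
#' @exportS3Method ggplot2::autoplot
autoplot.cf_classifier <- function(object, ...) {
  hist <- tidy(object)
  long <- tidyr::pivot_longer(hist, cols = c("train_loss", "val_loss"),
                              names_to = "set", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy") +
    ggplot2::theme_minimal()
}

#' Degree distribution on log-log axes with the power-law fit
#'
#' @param network A `cf_network`.
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(network) {
  fit <- degree_powerlaw_fit(network)
  deg <- network$degrees$degree
  tab <- table(deg[deg > 0])
  df <- tibble::tibble(degree = as.numeric(names(tab)),
                       frequency = as.numeric(tab))
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$degree),
                                   y = log10(.data$frequency))) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = "log10 degree", y = "log10 frequency",
                  title = sprintf("exponent %.2f (r2 = %.2f)",
                                  fit$exponent, fit$fit_r2)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
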