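# ggplot2 graphics for the main result types.

roc_points <- function(scores, y) {
  ord <- order(scores, decreasing = TRUE)
  y <- as.numeric(y)[ord]
  tibble::tibble(
    fpr = c(0, cumsum(y == 0) / sum(y == 0)),
    tpr = c(0, cumsum(y == 1) / sum(y == 1)))
}

#' ROC curves of all models in a suite
#'
#' @param suite a `model_suite`.
#' @param cohort which cohort to plot.
#' @return a ggplot object.
#' @export
plot_roc <- function(suite, cohort = "external_test") {
  sc <- suite$scores[suite$scores$cohort == cohort, ]
  df <- purrr::map_dfr(unique(sc$model), function(m) {
    d <- sc[sc$model == m, ]
    dplyr::mutate(roc_points(d$score, d$msi), model = m)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$model)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = paste("ROC,", cohort)) +
    ggplot2::theme_minimal()
}

#' Decision curves of an evaluation report
#'
#' @param report an `evaluation_report`.
#' @param cohort which cohort to plot.
#' @return a ggplot object.
#' @export
plot_decision_curve <- function(report, cohort = "external_test") {
  d <- report$decision_curves[report$decision_curves$cohort == cohort, ]
  ref <- d[d$model == d$model[1], ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$threshold, y = .data$net_benefit,
                                  colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = ref, ggplot2::aes(y = .data$treat_all),
                       colour = "grey40", linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40", linetype = 3) +
    ggplot2::coord_cartesian(ylim = c(-0.05, max(d$net_benefit, 0.05))) +
    ggplot2::labs(x = "Threshold probability", y = "Net benefit",
                  title = paste("Decision curves,", cohort)) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves of the predicted MSI and MSS groups
#'
#' @param report an `evaluation_report` built from a clinical table with DFS.
#' @param cohort which cohort to plot.
#' @return a ggplot object.
#' @export
plot_km <- function(report, cohort = "training") {
  km <- report$survival[[cohort]]
  if (is.null(km)) stop("no survival section for cohort ", cohort)
  d <- dplyr::bind_rows(
    km$curves,
    tibble::tibble(group = unique(km$curves$group), time = 0, surv = 1,
                   n_risk = NA, n_event = NA))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$surv,
                                  colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Disease-free survival",
                  title = sprintf("%s (log-rank p = %.3f)", cohort, km$logrank_p)) +
    ggplot2::theme_minimal()
}

#' Display one slice of a subregion label map
#'
#' @param map a `subregion_map`.
#' @param slice slice index along the third axis (default: middle slice).
#' @return a ggplot object.
#' @export
plot_subregion_map <- function(map, slice = NULL) {
  lab <- map$labels
  slice <- slice %||% round(dim(lab)[3] / 2)
  sl <- lab[, , slice]
  df <- tibble::tibble(
    x = rep(seq_len(nrow(sl)), ncol(sl)),
    y = rep(seq_len(ncol(sl)), each = nrow(sl)),
    subregion = factor(as.vector(sl)))
  df <- df[df$subregion != "0", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$subregion)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0("Subregion map, slice ", slice,
                                 " (V = ", map$V, ")")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `autoplot.model_suite` draws the ROC curves; `autoplot.subregion_map`
#' shows the middle slice of the label map.
#'
#' @param object the object to plot.
#' @param ... passed to the underlying plot function.
#' @return a ggplot object.
#' @export
autoplot.model_suite <- function(object, ...) plot_roc(object, ...)

#' @rdname autoplot.model_suite
#' @export
autoplot.subregion_map <- function(object, ...) plot_subregion_map(object, ...)
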