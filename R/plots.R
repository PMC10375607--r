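#' Confusion-matrix heatmap
#'
#' @param object A `metrics_report`.
#' @param normalize Show row-normalized percentages instead of counts.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.metrics_report <- function(object, normalize = TRUE, ...) {
  cm <- object$confusion
  df <- as.data.frame(as.table(cm))
  names(df) <- c("true", "predicted", "count")
  if (normalize) {
    tot <- rowSums(cm)[as.character(df$true)]
    df$value <- ifelse(tot > 0, 100 * df$count / tot, 0)
    lab <- "% of true class"
  } else {
    df$value <- df$count
    lab <- "samples"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted,
                                   y = .data$true,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(normalize, sprintf("%.1f", .data$value),
                     .data$count)), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(levels(df$true))) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 name = lab) +
    ggplot2::labs(title = paste("Confusion matrix -", object$scope),
                  x = "predicted", y = "true")
}

#' Per-lead metric panels
#'
#' One panel per metric, one bar per lead; mirrors the per-lead performance
#' breakdown of the best model.
#'
#' @param object A `lead_metrics` list (from [evaluate_per_lead()]).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.lead_metrics <- function(object, ...) {
  df <- glance(object)
  df <- df[df$scope != "all", ]
  long <- tidyr::pivot_longer(df, c("acc", "sen", "spe", "pre", "f1"),
                              names_to = "metric", values_to = "percent")
  long$scope <- factor(long$scope, levels = ecg_leads())
  ggplot2::ggplot(long, ggplot2::aes(x = .data$scope, y = .data$percent)) +
    ggplot2::geom_col(fill = "#4393c3") +
    ggplot2::facet_wrap(~metric, ncol = 1) +
    ggplot2::coord_cartesian(ylim = c(min(long$percent, na.rm = TRUE) - 2,
                                      100)) +
    ggplot2::labs(x = "lead", y = "macro metric (%)",
                  title = "Per-lead macro metrics")
}

#' Per-class metric boxplot across leads
#'
#' Distribution of each class's metrics over the 12 leads (whiskers at
#' 1.5 IQR), the usual way to spot leads or classes that delineate poorly.
#'
#' @param reports A `lead_metrics` list.
#' @param metric One of `"acc"`, `"sen"`, `"spe"`, `"pre"`, `"f1"`.
#' @return A ggplot object.
#' @export
plot_class_boxplot <- function(reports, metric = "pre") {
  metric <- match.arg(metric, c("acc", "sen", "spe", "pre", "f1"))
  df <- tidy(reports)
  df <- df[df$scope != "all", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class,
                                   y = .data[[metric]])) +
    ggplot2::geom_boxplot(fill = "#d1e5f0") +
    ggplot2::labs(x = "class", y = paste0(toupper(metric), " (%)"),
                  title = paste("Across-lead distribution of",
                                toupper(metric)))
}

#' Ground-truth vs predicted delineation overlay
#'
#' Plots one beat window's signal with shaded ground-truth wave intervals
#' and the predicted intervals as segments underneath.
#'
#' @param beat One-row beat-window tibble.
#' @param model Trained `ecg_model`.
#' @param min_run Smoothing run length for [labels_to_intervals()].
#' @param fs Sampling rate (x axis in seconds).
#' @return A ggplot object.
#' @export
plot_delineation <- function(beat, model, min_run = 10L, fs = 500) {
  sig <- beat$signal[[1L]]
  vl <- beat$valid_length
  df <- tibble::tibble(t = (seq_along(sig) - 1L) / fs, mv = sig)[1:vl, ]
  tru <- labels_to_intervals(beat$labels[[1L]], min_run = 1L)
  pred <- labels_to_intervals(predict_labels(model, beat), min_run)
  pal <- c(P = "#d6604d", QRS = "#4393c3", T = "#f4a582")
  ymin <- min(df$mv); ymax <- max(df$mv)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$mv)) +
    ggplot2::geom_rect(data = tru, inherit.aes = FALSE,
                       ggplot2::aes(xmin = .data$onset / fs,
                                    xmax = .data$offset / fs,
                                    fill = .data$wave_type),
                       ymin = ymin, ymax = ymax, alpha = 0.25) +
    ggplot2::geom_segment(data = pred, inherit.aes = FALSE,
                          ggplot2::aes(x = .data$onset / fs,
                                       xend = .data$offset / fs,
                                       colour = .data$wave_type),
                          y = ymin - 0.05 * (ymax - ymin),
                          yend = ymin - 0.05 * (ymax - ymin),
                          linewidth = 2) +
    ggplot2::geom_line() +
    ggplot2::scale_fill_manual(values = pal, name = "ground truth") +
    ggplot2::scale_colour_manual(values = pal, name = "predicted") +
    ggplot2::labs(x = "time (s)", y = "mV",
                  title = paste0(beat$record_id, " ", beat$lead,
                                 " beat ", beat$beat_index))
}
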