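#' Plot per-subject accuracies of a scenario run
#'
#' Subjects are ordered by default accuracy; points show the default model
#' and the scenario-composed model, with the chance level as a reference
#' line (the transferability gate).
#'
#' @param object A `ctl_scenario`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ctl_scenario <- function(object, ...) {
  df <- object$subjects |>
    mutate(subject_id = factor(.data$subject_id,
                               levels = .data$subject_id[order(.data$default_acc)])) |>
    tidyr::pivot_longer(c("default_acc", "scenario_acc"),
                        names_to = "model", values_to = "accuracy") |>
    mutate(model = ifelse(.data$model == "default_acc", "default", object$scenario))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subject_id, y = .data$accuracy,
                                   colour = .data$model, shape = .data$model)) +
    ggplot2::geom_hline(yintercept = object$config$chance_level,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "target subject (sorted by default accuracy)",
                  y = "leave-trial-out accuracy",
                  colour = NULL, shape = NULL,
                  title = paste0(object$scenario, " scenario, ", object$task)) +
    ggplot2::theme_minimal()
}

#' Plot mean accuracy change against the number of transferred sources
#'
#' One curve per ranking mode, faceted by transferability group, mirroring a
#' source-count sweep: positive values are positive transfer relative to the
#' default model.
#'
#' @param object A `ctl_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ctl_sweep <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$O, y = .data$mean_improvement,
                                   colour = .data$mode)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%+.0f", 100 * v)) +
    ggplot2::labs(x = "number of source subjects (O)",
                  y = "accuracy change vs default (pts)",
                  colour = "source ranking",
                  title = paste0("source-count sweep, ", object$task)) +
    ggplot2::theme_minimal()
}

#' Plot a target-source similarity profile
#'
#' @param object A `ctl_similarity` from [similarity_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ctl_similarity <- function(object, ...) {
  df <- mutate(object,
               ss_id = factor(.data$ss_id, levels = .data$ss_id[order(.data$r)]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ss_id, y = .data$r)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "source subject", y = "Pearson r of ReliefF weight vectors") +
    ggplot2::theme_minimal()
}
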