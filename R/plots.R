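#' Scatter plot of a 2-D codon-embedding projection
#'
#' @param projection A tibble from [project_2d()] (columns `id`, `x`,
#'   `y`; `id` holding codons).
#' @param scheme Colouring scheme passed to [grouping_labels()].
#' @param code A [genetic_code()] object.
#' @return A ggplot object.
#' @export
plot_codon_projection <- function(projection,
                                  scheme = c("wobble", "suffix",
                                             "amino_acid"),
                                  code = genetic_code()) {
  scheme <- match.arg(scheme)
  df <- dplyr::mutate(projection,
                      group = grouping_labels(.data$id, scheme, code))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$id), size = 2,
                       vjust = -1, show.legend = FALSE) +
    ggplot2::labs(colour = scheme, x = "dim 1", y = "dim 2") +
    ggplot2::theme_minimal()
}

#' Training curves for a pretraining run
#'
#' Loss and masked accuracy per step.
#'
#' @param object A `pretrain_result` from [pretrain()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pretrain_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$metrics,
                            c("loss", "masked_accuracy"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(.data$step, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1L) +
    ggplot2::theme_minimal()
}

#' Per-seed R-squared distributions of probe results
#'
#' @param ... `probe_result` objects from [repeated_cv()].
#' @return A ggplot object (one box per model/dataset).
#' @export
plot_probe_results <- function(...) {
  df <- dplyr::bind_rows(lapply(list(...), function(pr) {
    dplyr::mutate(pr$per_seed, model = pr$model, dataset = pr$dataset)
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$model, .data$r2,
                                   fill = .data$model)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~dataset) +
    ggplot2::labs(y = expression(R^2)) +
    ggplot2::theme_minimal()
}

#' Mutation-sensitivity curve
#'
#' @param scan A tibble from [mutation_sensitivity_scan()].
#' @return A ggplot object.
#' @export
plot_sensitivity_curve <- function(scan) {
  ggplot2::ggplot(scan, ggplot2::aes(.data$level, .data$mean_r2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "synonymous mutation level",
                  y = expression(mean ~ R^2)) +
    ggplot2::theme_minimal()
}

#' Learning-rate schedule curve
#'
#' @param total_steps Total steps.
#' @param max_lr,warmup_fraction See [lr_at_step()].
#' @return A ggplot object.
#' @export
plot_lr_schedule <- function(total_steps, max_lr = 2e-4,
                             warmup_fraction = 0.10) {
  steps <- seq(0L, total_steps, length.out = min(500L, total_steps + 1L))
  df <- tibble::tibble(step = steps,
                       lr = lr_at_step(steps, total_steps, max_lr,
                                       warmup_fraction))
  ggplot2::ggplot(df, ggplot2::aes(.data$step, .data$lr)) +
    ggplot2::geom_line() +
    ggplot2::theme_minimal()
}
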