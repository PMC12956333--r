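#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a probe result into per-(seed, fold) rows
#'
#' @param x A `probe_result` from [repeated_cv()].
#' @param ... Unused.
#' @return A tibble with columns `model`, `dataset`, `seed`, `fold`, `r2`.
#' @export
tidy.probe_result <- function(x, ...) {
  dplyr::mutate(x$scores, model = x$model, dataset = x$dataset,
                .before = 1L)
}

#' One-row summary of a probe result
#'
#' @param x A `probe_result`.
#' @param ... Unused.
#' @return A tibble with `model`, `dataset`, `mean_r2`, `n_seeds`,
#'   `folds`.
#' @export
glance.probe_result <- function(x, ...) {
  tibble::tibble(model = x$model, dataset = x$dataset,
                 mean_r2 = x$mean_r2, n_seeds = nrow(x$per_seed),
                 folds = max(x$scores$fold))
}

#' Tidy PERMANOVA group sizes
#'
#' @param x A `permanova_result` from [permanova()].
#' @param ... Unused.
#' @return A tibble with columns `group`, `size`.
#' @export
tidy.permanova_result <- function(x, ...) {
  tibble::tibble(group = x$groups, size = x$group_sizes)
}

#' One-row summary of a PERMANOVA
#'
#' @param x A `permanova_result`.
#' @param ... Unused.
#' @return A tibble with `pseudo_f`, `p_value`, `n_permutations`,
#'   `n_groups`, `n`.
#' @export
glance.permanova_result <- function(x, ...) {
  tibble::tibble(pseudo_f = x$pseudo_f, p_value = x$p_value,
                 n_permutations = x$n_permutations,
                 n_groups = length(x$group_sizes), n = x$n)
}

#' Tidy the training log of a pretraining run
#'
#' @param x A `pretrain_result` from [pretrain()].
#' @param ... Unused.
#' @return The per-step metrics tibble.
#' @export
tidy.pretrain_result <- function(x, ...) x$metrics

#' One-row summary of a pretraining run
#'
#' @param x A `pretrain_result`.
#' @param ... Unused.
#' @return A tibble with final loss/accuracy and run dimensions.
#' @export
glance.pretrain_result <- function(x, ...) {
  last <- x$metrics[nrow(x$metrics), ]
  tibble::tibble(
    steps = nrow(x$metrics), epochs = max(x$metrics$epoch),
    final_loss = last$loss, final_masked_accuracy = last$masked_accuracy,
    constraint_enabled = x$config$constraint_enabled
  )
}
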