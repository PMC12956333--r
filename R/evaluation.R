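#' Scale fitness targets
#'
#' `"minmax"` maps the values affinely onto `[0, 1]`. `"yeo_johnson"`
#' applies the Yeo-Johnson power transform with the maximum-likelihood
#' lambda (via [car::powerTransform()]) and then standardizes to zero
#' mean, unit variance — the treatment used for strongly skewed targets.
#'
#' @param y Numeric vector (`n >= 2`, non-constant).
#' @param method `"minmax"` or `"yeo_johnson"`.
#' @return Scaled numeric vector; for Yeo-Johnson, the lambda is attached
#'   as attribute `lambda`.
#' @examples
#' scale_targets(c(0, 5, 10), "minmax")
#' @export
scale_targets <- function(y, method = c("minmax", "yeo_johnson")) {
  method <- match.arg(method)
  stopifnot(length(y) >= 2L)
  if (max(y) == min(y)) stop("constant target vector", call. = FALSE)
  if (method == "minmax") {
    (y - min(y)) / (max(y) - min(y))
  } else {
    lambda <- car::powerTransform(y, family = "yjPower")$lambda
    z <- car::yjPower(y, lambda)
    out <- (z - mean(z)) / stats::sd(z)
    attr(out, "lambda") <- unname(lambda)
    out
  }
}

#' Fit a regularized linear probe by gradient descent
#'
#' A single affine map from frozen embeddings to the target, fitted by
#' mini-batch Adam on the mean-squared-error loss plus L1 and L2 weight
#' penalties. This is the frozen-representation evaluation head: the
#' encoder is never updated.
#'
#' @param x Numeric matrix of embeddings (rows = samples).
#' @param y Numeric target vector, `length(y) == nrow(x)`.
#' @param l1,l2 Regularization strengths (default 1e-4 each).
#' @param epochs Training epochs (default 100).
#' @param batch_size Mini-batch size (default 16).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed Integer seed for shuffling.
#' @return An object of class `syncodon_probe` with `w`, `b` and the
#'   final training loss.
#' @export
fit_probe <- function(x, y, l1 = 1e-4, l2 = 1e-4, epochs = 100L,
                      batch_size = 16L, lr = 1e-3, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("dimension mismatch", call. = FALSE)
  n <- nrow(x); d <- ncol(x)
  w <- numeric(d); b <- 0
  mw <- vw <- numeric(d); mb <- vb <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      for (chunk in split(perm, ceiling(seq_along(perm) / batch_size))) {
        xb <- x[chunk, , drop = FALSE]
        r <- drop(xb %*% w) + b - y[chunk]
        gw <- 2 * drop(crossprod(xb, r)) / length(chunk) +
          l1 * sign(w) + 2 * l2 * w
        gb <- 2 * mean(r)
        t <- t + 1L
        mw <- b1 * mw + (1 - b1) * gw; vw <- b2 * vw + (1 - b2) * gw^2
        mb <- b1 * mb + (1 - b1) * gb; vb <- b2 * vb + (1 - b2) * gb^2
        w <- w - lr * (mw / (1 - b1^t)) / (sqrt(vw / (1 - b2^t)) + eps)
        b <- b - lr * (mb / (1 - b1^t)) / (sqrt(vb / (1 - b2^t)) + eps)
      }
    }
  })
  final_loss <- mean((drop(x %*% w) + b - y)^2)
  structure(list(w = w, b = b, l1 = l1, l2 = l2, loss = final_loss),
            class = "syncodon_probe")
}

#' @export
predict.syncodon_probe <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$w) + object$b
}

r_squared <- function(y_true, y_pred) {
  ss_res <- sum((y_true - y_pred)^2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  1 - ss_res / ss_tot
}

#' Repeated five-fold cross-validated probing
#'
#' For each seed: shuffle, split into `folds` folds, fit the probe on the
#' remaining folds and score held-out R-squared (`1 - SS_res / SS_tot`,
#' with `SS_tot` around the held-out fold's own mean), rotating through
#' all folds. The per-seed value is the mean of its fold R-squared; the
#' headline value is the mean over seeds. Per-seed values form the pairs
#' for [paired_t_test()] comparisons between models.
#'
#' @param x Embedding matrix.
#' @param y Numeric targets.
#' @param folds Number of CV folds (default 5).
#' @param seeds Integer vector of split seeds (default `1:30`).
#' @param ... Passed to [fit_probe()] (`l1`, `l2`, `epochs`,
#'   `batch_size`, `lr`).
#' @param model_label,dataset_label Labels carried into the result.
#' @return An object of class `probe_result`: tibble `scores` (seed,
#'   fold, r2), tibble `per_seed` (seed, r2), and `mean_r2`.
#' @export
repeated_cv <- function(x, y, folds = 5L, seeds = 1:30, ...,
                        model_label = "model", dataset_label = "dataset") {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < folds) stop("fewer samples than folds", call. = FALSE)
  scores <- purrr::map_dfr(seeds, function(sd) {
    fold_of <- withr::with_seed(sd, {
      sample(rep_len(seq_len(folds), n))
    })
    purrr::map_dfr(seq_len(folds), function(f) {
      test <- fold_of == f
      probe <- fit_probe(x[!test, , drop = FALSE], y[!test], ...,
                         seed = sd * 1000L + f)
      tibble::tibble(
        seed = sd, fold = f,
        r2 = r_squared(y[test], predict(probe, x[test, , drop = FALSE]))
      )
    })
  })
  per_seed <- dplyr::summarise(dplyr::group_by(scores, .data$seed),
                               r2 = mean(.data$r2), .groups = "drop")
  structure(list(model = model_label, dataset = dataset_label,
                 scores = scores, per_seed = per_seed,
                 mean_r2 = mean(per_seed$r2)),
            class = "probe_result")
}

#' @export
print.probe_result <- function(x, ...) {
  cat("<probe_result> ", x$model, " on ", x$dataset, ": mean R^2 = ",
      sprintf("%.4f", x$mean_r2), " over ", nrow(x$per_seed), " seeds x ",
      max(x$scores$fold), " folds\n", sep = "")
  invisible(x)
}

#' Paired two-sided t-test on per-seed scores
#'
#' Computes `t = mean(d) / (sd(d) / sqrt(n))` on the per-pair differences
#' and the two-sided p-value from the Student t distribution with `n - 1`
#' degrees of freedom. Pairs are matched by seed. Zero-variance
#' differences (including identical inputs) are a degenerate-input error.
#'
#' @param a,b Numeric vectors of equal length `n >= 2` (e.g. per-seed
#'   R-squared of two models), or `probe_result` objects.
#' @return A tibble with columns `t`, `df`, `p_value`, `mean_difference`.
#' @examples
#' paired_t_test(c(2, 4, 6, 8), c(1, 2, 3, 4))
#' @export
paired_t_test <- function(a, b) {
  if (inherits(a, "probe_result")) a <- a$per_seed$r2
  if (inherits(b, "probe_result")) b <- b$per_seed$r2
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  s <- stats::sd(d)
  if (s == 0) {
    stop("degenerate input: differences have zero variance", call. = FALSE)
  }
  tstat <- mean(d) / (s / sqrt(n))
  tibble::tibble(
    t = tstat, df = n - 1L,
    p_value = 2 * stats::pt(-abs(tstat), df = n - 1L),
    mean_difference = mean(d)
  )
}

#' Sensitivity of probe performance to synonymous mutation
#'
#' Trains probes on embeddings of *unmutated* training folds and scores
#' them on test folds whose sequences are replaced by synonymous variants
#' at each mutation level, quantifying how much of the learned signal
#' rides on codon choice rather than protein identity. Level 0 reproduces
#' the standard [repeated_cv()] protocol.
#'
#' @param embed_fn Function mapping a character vector of CDS to an
#'   embedding matrix (e.g. a wrapper around [cds_embeddings()]); the
#'   frozen encoder lives in here.
#' @param sequences Character vector of coding sequences.
#' @param y Numeric targets.
#' @param levels Mutation levels (default `seq(0.1, 1, 0.1)`; level 0 is
#'   always prepended as the baseline).
#' @param folds CV folds (default 5).
#' @param seeds Split seeds (default `1:10`).
#' @param mutation_seed Seed for generating the mutated test sequences.
#' @param batch_size Probe mini-batch size (default 64, matching the
#'   larger-dataset protocol).
#' @param ... Further arguments to [fit_probe()].
#' @param code A [genetic_code()] object.
#' @return A tibble with columns `level`, `mean_r2`.
#' @export
mutation_sensitivity_scan <- function(embed_fn, sequences, y,
                                      levels = seq(0.1, 1, 0.1),
                                      folds = 5L, seeds = 1:10,
                                      mutation_seed = 1L, batch_size = 64L,
                                      ..., code = genetic_code()) {
  levels <- sort(unique(c(0, levels)))
  base_emb <- embed_fn(sequences)
  n <- length(sequences)
  purrr::map_dfr(levels, function(lv) {
    emb_test <- if (lv == 0) base_emb else {
      mutated <- withr::with_seed(mutation_seed, {
        vapply(sequences, mutate_synonymously, character(1), level = lv,
               code = code, USE.NAMES = FALSE)
      })
      embed_fn(mutated)
    }
    per_seed <- vapply(seeds, function(sd) {
      fold_of <- withr::with_seed(sd, sample(rep_len(seq_len(folds), n)))
      mean(vapply(seq_len(folds), function(f) {
        test <- fold_of == f
        probe <- fit_probe(base_emb[!test, , drop = FALSE], y[!test],
                           batch_size = batch_size, ...,
                           seed = sd * 1000L + f)
        r_squared(y[test], predict(probe, emb_test[test, , drop = FALSE]))
      }, numeric(1)))
    }, numeric(1))
    tibble::tibble(level = lv, mean_r2 = mean(per_seed))
  })
}
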