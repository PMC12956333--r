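#' Extract the static codon input embeddings
#'
#' Rows of the input embedding table for the 64 codon tokens, in
#' lexicographic codon order, with no contextual forward pass. Because of
#' weight tying these are also the rows the language head projects onto.
#'
#' @param model A [init_model()] (or trained) model.
#' @param tokenizer A [codon_tokenizer()].
#' @return Numeric matrix `64 x hidden_size` with codon rownames.
#' @export
extract_codon_embeddings <- function(model, tokenizer) {
  emb <- model$params$E[tokenizer$codon_ids + 1L, , drop = FALSE]
  rownames(emb) <- names(tokenizer$codon_ids)
  emb
}

#' Grouping labels for codons
#'
#' @param codons Character vector of codons.
#' @param scheme `"wobble"` (third base: 4 groups of 16), `"suffix"`
#'   (positions 2-3: 16 groups of 4) or `"amino_acid"` (synonymous
#'   family: 21 groups under the standard code, stop included).
#' @param code A [genetic_code()] object (for `"amino_acid"`).
#' @return Character vector of group labels.
#' @export
grouping_labels <- function(codons, scheme = c("wobble", "suffix",
                                               "amino_acid"),
                            code = genetic_code()) {
  scheme <- match.arg(scheme)
  codons <- normalize_codon(codons)
  switch(scheme,
    wobble = substr(codons, 3L, 3L),
    suffix = substr(codons, 2L, 3L),
    amino_acid = unname(code$codon_to_aa[codons])
  )
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Tests whether group labels explain the geometry of a point cloud.
#' The pseudo-F statistic is
#' `(SS_between / (g - 1)) / (SS_within / (n - g))`, computed from
#' pairwise squared Euclidean distances via the standard decomposition
#' (`SS_total` is the sum of all pairwise squared distances divided by
#' `n`; `SS_within` sums, per group, the within-group pairwise squared
#' distances divided by the group size). The p-value is
#' `(1 + #permuted F >= observed F) / (1 + n_permutations)` under seeded
#' label permutation, so its smallest attainable value is
#' `1 / (n_permutations + 1)`.
#'
#' @param x Numeric matrix of points (rows = observations), or a `dist`
#'   object / square distance matrix.
#' @param labels Group labels, at least 2 groups with at least 2 members
#'   each; observations in singleton groups are an error (drop them
#'   first).
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return An object of class `permanova_result`: list with `pseudo_f`,
#'   `p_value`, `n_permutations`, `group_sizes`, `n`.
#' @examples
#' set.seed(1)
#' pts <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 3), 10))
#' permanova(pts, rep(c("a", "b"), each = 10))
#' @export
permanova <- function(x, labels, n_permutations = 999L, seed = 1L) {
  if (inherits(x, "dist")) {
    d2 <- as.matrix(x)^2
  } else if (is.matrix(x) && nrow(x) == ncol(x) &&
             max(abs(x - t(x))) < 1e-12 && all(diag(x) == 0)) {
    d2 <- x^2
  } else {
    d2 <- as.matrix(stats::dist(x))^2
  }
  labels <- as.character(labels)
  n <- nrow(d2)
  stopifnot(length(labels) == n)
  sizes <- table(labels)
  g <- length(sizes)
  if (g < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2L)) {
    stop("singleton group(s): ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  ss_total <- sum(d2[upper.tri(d2)]) / n
  f_stat <- function(lab) {
    ss_within <- 0
    for (grp in unique(lab)) {
      idx <- which(lab == grp)
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
    ((ss_total - ss_within) / (g - 1)) / (ss_within / (n - g))
  }
  observed <- f_stat(labels)
  exceed <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(i) {
      f_stat(sample(labels)) >= observed
    }, logical(1)))
  })
  structure(list(
    pseudo_f = observed,
    p_value = (1 + exceed) / (1 + n_permutations),
    n_permutations = as.integer(n_permutations),
    group_sizes = as.integer(sizes),
    groups = names(sizes),
    n = n
  ), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("<permanova> pseudo-F = ", sprintf("%.3f", x$pseudo_f),
      ", p = ", format(x$p_value), " (", x$n_permutations,
      " permutations, ", length(x$group_sizes), " groups, n = ", x$n,
      ")\n", sep = "")
  invisible(x)
}

#' Project points to two dimensions
#'
#' `"pca"` gives the first two principal-component scores (deterministic
#' up to sign). `"tsne"` runs an exact (all-pairs) t-SNE suitable for the
#' small point sets analysed here (the 64 codon embeddings); the
#' perplexity default of 30 matches the conventional setting. The
#' projection is for visualization only — significance testing
#' ([permanova()]) operates in the original space.
#'
#' @param x Numeric matrix (rows = points, `n >= 3`).
#' @param method `"pca"` or `"tsne"`.
#' @param perplexity t-SNE perplexity (must satisfy `perplexity < n`).
#' @param seed Integer seed (t-SNE initialization); same seed, same
#'   coordinates.
#' @param max_iter t-SNE gradient-descent iterations (default 800; with
#'   momentum, adaptive per-coordinate gains and early exaggeration).
#' @return A tibble with columns `id`, `x`, `y`.
#' @export
project_2d <- function(x, method = c("pca", "tsne"), perplexity = 30,
                       seed = 1L, max_iter = 800L) {
  method <- match.arg(method)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  ids <- rownames(x) %||% as.character(seq_len(n))
  if (method == "pca") {
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    sc <- pc$x
    coords <- cbind(sc[, 1L], if (ncol(sc) >= 2L) sc[, 2L] else 0)
  } else {
    if (perplexity >= n) stop("perplexity must be < number of points",
                              call. = FALSE)
    coords <- tsne_exact(x, perplexity, seed, max_iter)
  }
  tibble::tibble(id = ids, x = coords[, 1L], y = coords[, 2L])
}

# Exact t-SNE (no Barnes-Hut): fine for n up to a few hundred points.
# Symmetrized entropy-calibrated affinities, early exaggeration, momentum
# gradient descent.
tsne_exact <- function(x, perplexity, seed, max_iter = 500L) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- 1e-20; hi <- 1e20; beta <- 1
    for (iter in 1:64) {
      p <- exp(-di * beta)
      sump <- sum(p)
      if (sump == 0) { beta <- beta / 2; next }
      p <- p / sump
      h <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (hi == 1e20) beta * 2 else
        (beta + hi) / 2 } else { hi <- beta; beta <- (beta + lo) / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  withr::with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, 0, 1e-4), n, 2)
  })
  vel <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  lr <- 50
  for (iter in seq_len(max_iter)) {
    exag <- if (iter <= 100L) 4 else 1
    momentum <- if (iter <= 250L) 0.5 else 0.8
    dy2 <- as.matrix(stats::dist(Y))^2
    Qnum <- 1 / (1 + dy2)
    diag(Qnum) <- 0
    Q <- pmax(Qnum / sum(Qnum), 1e-12)
    W <- (exag * P - Q) * Qnum
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    gains <- pmax(ifelse(sign(grad) != sign(vel), gains + 0.2,
                         gains * 0.8), 0.01)
    vel <- momentum * vel - lr * gains * grad
    Y <- Y + vel
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y
}

#' Silhouette-based label separation across t-SNE perplexities
#'
#' Re-runs [project_2d()] across a grid of perplexities and records the
#' mean silhouette width of the given labels in each projection — the
#' robustness check that a clustering pattern is not an artifact of one
#' perplexity setting.
#'
#' @param x Numeric matrix of points.
#' @param labels Group labels.
#' @param perplexities Numeric vector of perplexities (default
#'   `c(5, 10, 20, 30)`).
#' @param seed Integer seed.
#' @return A tibble with columns `perplexity`, `silhouette`.
#' @export
perplexity_sweep <- function(x, labels, perplexities = c(5, 10, 20, 30),
                             seed = 1L) {
  purrr::map_dfr(perplexities, function(px) {
    pr <- project_2d(x, "tsne", perplexity = px, seed = seed)
    tibble::tibble(
      perplexity = px,
      silhouette = mean_silhouette(cbind(pr$x, pr$y), labels)
    )
  })
}

#' Mean silhouette width of labelled points
#'
#' @param x Numeric matrix of points.
#' @param labels Group labels (each group needs >= 1 member; silhouette
#'   of singleton groups is 0 by convention).
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
mean_silhouette <- function(x, labels) {
  d <- as.matrix(stats::dist(x))
  labels <- as.character(labels)
  n <- nrow(d)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1L) return(0)
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(gr) {
      mean(d[i, labels == gr])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
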