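#' Training configuration for masked language modeling
#'
#' @param mask_probability Per-codon masking probability (default 0.15).
#' @param max_lr Peak learning rate (default 2e-4).
#' @param warmup_fraction Fraction of steps spent on the linear warmup
#'   (default 0.10), after which the rate follows a cosine decay to 0.
#' @param weight_decay AdamW decoupled weight decay (default 0.01),
#'   applied to weight matrices (not biases or layer-norm parameters).
#' @param dropout Dropout rate during training (default 0.1).
#' @param batch_size Sequences per step (default 32).
#' @param epochs Passes over the corpus (default 10).
#' @param seed Integer seed for masking, dropout and shuffling.
#' @param constraint_enabled Apply the synonymous-constraint matrix to the
#'   logits before softmax and loss (default `TRUE`); `FALSE` gives the
#'   conventional unconstrained masked objective (the no-constraint
#'   ablation).
#' @param token_type_mode One of `"species"`, `"taxon"`, `"none"` —
#'   recorded for provenance; the caller supplies the matching token-type
#'   IDs (all-unknown for `"none"`).
#' @param corruption `"mask"` (default): every selected position is
#'   replaced by the mask token. `"bert"`: the conventional 80/10/10
#'   mask/random/keep corruption, provided for comparison.
#' @param adam_beta1,adam_beta2,adam_eps AdamW moment parameters
#'   (conventional defaults).
#' @return A list of class `train_config`.
#' @export
train_config <- function(mask_probability = 0.15, max_lr = 2e-4,
                         warmup_fraction = 0.10, weight_decay = 0.01,
                         dropout = 0.1, batch_size = 32L, epochs = 10L,
                         seed = 1L, constraint_enabled = TRUE,
                         token_type_mode = c("species", "taxon", "none"),
                         corruption = c("mask", "bert"),
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8) {
  stopifnot(mask_probability > 0, mask_probability < 1,
            warmup_fraction > 0, warmup_fraction < 1)
  structure(list(
    mask_probability = mask_probability, max_lr = max_lr,
    warmup_fraction = warmup_fraction, weight_decay = weight_decay,
    dropout = dropout, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), seed = as.integer(seed),
    constraint_enabled = isTRUE(constraint_enabled),
    token_type_mode = match.arg(token_type_mode),
    corruption = match.arg(corruption),
    adam_beta1 = adam_beta1, adam_beta2 = adam_beta2, adam_eps = adam_eps
  ), class = "train_config")
}

#' Mask codon positions in a tokenized batch
#'
#' Each codon position is independently selected with probability
#' `mask_probability`; special tokens (start/end/mask/pad/unknown) are
#' never selected. Selected positions' input ids are replaced by the mask
#' token (or, under `"bert"` corruption, by the mask token 80 percent of
#' the time, a random codon 10 percent, and left unchanged 10 percent);
#' labels record the original ids at masked positions and `NA` elsewhere.
#' Uses the current RNG state.
#'
#' @param token_ids Integer matrix (batch x positions) of 0-based token
#'   ids with specials in place, or a single vector.
#' @param tokenizer A [codon_tokenizer()].
#' @param mask_probability Selection probability per codon position.
#' @param corruption `"mask"` or `"bert"` (see [train_config()]).
#' @return A list of class `masked_batch`: `input_ids` (matrix), `labels`
#'   (matrix, `NA` at unmasked positions), `n_masked`.
#' @export
mask_batch <- function(token_ids, tokenizer, mask_probability = 0.15,
                       corruption = c("mask", "bert")) {
  corruption <- match.arg(corruption)
  if (is.vector(token_ids)) token_ids <- matrix(token_ids, nrow = 1L)
  n_special <- length(tokenizer$special_tokens)
  is_codon <- token_ids >= n_special
  sel <- is_codon & matrix(stats::runif(length(token_ids)) < mask_probability,
                           nrow(token_ids), ncol(token_ids))
  labels <- matrix(NA_integer_, nrow(token_ids), ncol(token_ids))
  labels[sel] <- token_ids[sel]
  input_ids <- token_ids
  mask_id <- tokenizer$special_tokens[["mask"]]
  if (corruption == "mask") {
    input_ids[sel] <- mask_id
  } else {
    u <- stats::runif(sum(sel))
    repl <- rep(mask_id, sum(sel))
    random <- u >= 0.8 & u < 0.9
    repl[random] <- sample(unname(tokenizer$codon_ids), sum(random),
                           replace = TRUE)
    keep <- u >= 0.9
    repl[keep] <- token_ids[sel][keep]
    input_ids[sel] <- repl
  }
  structure(list(input_ids = input_ids, labels = labels,
                 n_masked = sum(sel)),
            class = "masked_batch")
}

#' Apply the synonymous constraint to logits
#'
#' For each masked position, adds the constraint-matrix row indexed by the
#' *true* codon to that position's logits: synonymous entries are retained
#' unchanged, non-synonymous entries become `-Inf` and receive exactly
#' zero probability after softmax. Rows with `NA` labels (unmasked
#' positions) are returned untouched.
#'
#' @param logits Numeric matrix `positions x vocab_size`.
#' @param labels Integer vector of true token ids (0-based) per row, `NA`
#'   for unmasked rows.
#' @param mask_matrix The constraint matrix from [build_synonym_mask()].
#' @return Constrained logits, same shape as `logits`.
#' @export
constrain_logits <- function(logits, labels, mask_matrix) {
  stopifnot(nrow(logits) == length(labels),
            ncol(logits) == ncol(mask_matrix))
  m <- which(!is.na(labels))
  if (any(labels[m] < 5L)) {
    stop("label is a special token; only codon tokens can be masked",
         call. = FALSE)
  }
  z <- logits
  z[m, ] <- logits[m, , drop = FALSE] +
    mask_matrix[labels[m] + 1L, , drop = FALSE]
  z
}

log_softmax_rows <- function(z) {
  m <- row_max_finite(z)
  z - m - log(rowSums(exp(z - m)))
}

#' Masked language modeling loss
#'
#' The average negative log likelihood of the true tokens over the masked
#' positions: `L = -(1/|M|) * sum over i in M of log softmax(z_i)[x_i]`,
#' with the softmax over the full vocabulary dimension (`-Inf` entries
#' contribute zero mass).
#'
#' @param z Logit matrix `positions x vocab_size` (constrained or raw).
#' @param labels Integer vector of true token ids (0-based), `NA` at
#'   unmasked rows; at least one non-`NA` entry.
#' @return The scalar loss.
#' @export
mlm_loss <- function(z, labels) {
  m <- which(!is.na(labels))
  if (length(m) == 0L) stop("no masked positions (|M| = 0)", call. = FALSE)
  lp <- log_softmax_rows(z[m, , drop = FALSE])
  -mean(lp[cbind(seq_along(m), labels[m] + 1L)])
}

#' Masked prediction accuracy
#'
#' Fraction of masked positions whose highest-scoring token equals the
#' true token; ties are broken in favour of the lowest token id.
#'
#' @inheritParams mlm_loss
#' @return Fraction in `[0, 1]`.
#' @export
masked_accuracy <- function(z, labels) {
  m <- which(!is.na(labels))
  if (length(m) == 0L) stop("no masked positions (|M| = 0)", call. = FALSE)
  pred <- max.col(z[m, , drop = FALSE], ties.method = "first") - 1L
  mean(pred == labels[m])
}

#' Learning rate at a training step
#'
#' Linear warmup from 0 to `max_lr` over the first `warmup_fraction` of
#' steps, then cosine decay back to 0 at `total_steps`. The schedule is
#' continuous, peaks at exactly `max_lr`, and is 0 at both endpoints.
#'
#' @param step Step index (0-based), vectorized.
#' @param total_steps Total number of steps.
#' @param max_lr Peak learning rate.
#' @param warmup_fraction Fraction of steps in the warmup.
#' @return Learning rate(s).
#' @examples
#' lr_at_step(c(0, 100, 550, 1000), 1000)
#' @export
lr_at_step <- function(step, total_steps, max_lr = 2e-4,
                       warmup_fraction = 0.10) {
  stopifnot(all(step >= 0), all(step <= total_steps))
  w <- warmup_fraction * total_steps
  progress <- pmin(pmax((step - w) / (total_steps - w), 0), 1)
  ifelse(step < w,
         max_lr * step / w,
         max_lr * 0.5 * (1 + cos(pi * progress)))
}

# Loss, metrics and parameter gradients for one masked batch.
# Returns list(loss, accuracy, n_masked, grads) with grads mirroring the
# params structure. Gradients at -Inf-constrained entries are exactly 0.
loss_and_grads <- function(model, batch, token_type_ids, mask_matrix = NULL,
                           train = FALSE) {
  cfg <- model$config
  ids <- batch$input_ids
  B <- nrow(ids); L <- ncol(ids)
  pad_id <- 3L # [PAD]
  valid <- ids != pad_id
  token_type_ids <- rep_len(as.integer(token_type_ids), B)
  X0 <- embed_inputs(model, ids, token_type_ids)
  fw <- encoder_forward(model, X0, valid, train = train, keep_cache = TRUE)
  hid <- fw$hidden
  labels_flat <- as.integer(t(batch$labels))
  m <- which(!is.na(labels_flat))
  if (length(m) == 0L) stop("no masked positions (|M| = 0)", call. = FALSE)
  Hm <- hid[m, , drop = FALSE]
  logits <- Hm %*% t(model$params$E) +
    matrix(model$params$b_out, length(m), cfg$vocab_size, byrow = TRUE)
  z <- if (!is.null(mask_matrix)) {
    logits + mask_matrix[labels_flat[m] + 1L, , drop = FALSE]
  } else logits
  lp <- log_softmax_rows(z)
  lab1 <- labels_flat[m] + 1L
  loss <- -mean(lp[cbind(seq_along(m), lab1)])
  acc <- mean(max.col(z, ties.method = "first") == lab1)
  # d loss / d logits: (softmax - onehot) / |M|; exact 0 at -Inf entries
  Pz <- exp(lp)
  Pz[cbind(seq_along(m), lab1)] <- Pz[cbind(seq_along(m), lab1)] - 1
  dlogits <- Pz / length(m)
  grads <- zero_like(model$params)
  grads$E <- crossprod(dlogits, Hm)
  grads$b_out <- colSums(dlogits)
  dHid <- matrix(0, B * L, cfg$hidden_size)
  dHid[m, ] <- dlogits %*% model$params$E
  bwd <- encoder_backward(model, fw$cache, dHid, grads)
  dX0 <- bwd$dX
  grads$layers <- bwd$grads$layers
  grads$P <- bwd$grads$P
  # embedding-table gradients (weight tying: E also gets the input-side term)
  flat_ids <- as.integer(t(ids))
  dE_in <- rowsum(dX0, group = flat_ids)
  grads$E[as.integer(rownames(dE_in)) + 1L, ] <-
    grads$E[as.integer(rownames(dE_in)) + 1L, ] + dE_in
  type_flat <- rep(token_type_ids, each = L)
  dT <- rowsum(dX0, group = type_flat)
  grads$Ttype[as.integer(rownames(dT)) + 1L, ] <-
    grads$Ttype[as.integer(rownames(dT)) + 1L, ] + dT
  list(loss = loss, accuracy = acc, n_masked = length(m), grads = grads)
}

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like)
  else if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
  else numeric(length(p))
}

# Backward pass through the encoder stack. Returns the gradient with
# respect to the input embeddings and the accumulated layer/P gradients.
encoder_backward <- function(model, cache, dX, grads) {
  cfg <- model$config
  H <- cfg$hidden_size
  A <- cfg$num_heads
  dh <- H %/% A
  rs <- cache$rs
  scale <- cache$scale
  valid <- cache$valid
  for (l in rev(seq_len(cfg$num_layers))) {
    cc <- cache$layers[[l]]
    lp <- model$params$layers[[l]]
    gl <- grads$layers[[l]]
    ln2b <- layer_norm_bwd(dX, cc$ln2, lp$ln2_g)
    gl$ln2_g <- gl$ln2_g + ln2b$dg
    gl$ln2_b <- gl$ln2_b + ln2b$db
    dY2 <- ln2b$dY
    dFF <- if (!is.null(cc$drop2)) dY2 * cc$drop2 else dY2
    dX1 <- dY2
    gl$W2 <- gl$W2 + crossprod(cc$G, dFF)
    gl$b2 <- gl$b2 + colSums(dFF)
    dG <- dFF %*% t(lp$W2)
    dU <- dG * (cc$sig * (1 + 1.702 * cc$U * (1 - cc$sig)))
    gl$W1 <- gl$W1 + crossprod(cc$X1, dU)
    gl$b1 <- gl$b1 + colSums(dU)
    dX1 <- dX1 + dU %*% t(lp$W1)
    ln1b <- layer_norm_bwd(dX1, cc$ln1, lp$ln1_g)
    gl$ln1_g <- gl$ln1_g + ln1b$dg
    gl$ln1_b <- gl$ln1_b + ln1b$db
    dY1 <- ln1b$dY
    dAO <- if (!is.null(cc$drop1)) dY1 * cc$drop1 else dY1
    dXres <- dY1
    gl$Wo <- gl$Wo + crossprod(cc$O, dAO)
    gl$bo <- gl$bo + colSums(dAO)
    dO <- dAO %*% t(lp$Wo)
    ab <- attn_backward_cpp(dO, cc$Q, cc$Kc, cc$V, cc$Qr, cc$Kr,
                            cc$attn, rs$Bmat, valid + 0L, A, scale)
    dQ <- ab$dQ
    dKc <- ab$dK
    dV <- ab$dV
    dQr <- ab$dQr
    dKr <- ab$dKr
    X <- cc$X
    gl$Wq <- gl$Wq + crossprod(X, dQ) + crossprod(model$params$P, dQr)
    gl$bq <- gl$bq + colSums(dQ)
    gl$Wk <- gl$Wk + crossprod(X, dKc) + crossprod(model$params$P, dKr)
    gl$bk <- gl$bk + colSums(dKc)
    gl$Wv <- gl$Wv + crossprod(X, dV)
    gl$bv <- gl$bv + colSums(dV)
    grads$P <- grads$P + dQr %*% t(lp$Wq) + dKr %*% t(lp$Wk)
    dX <- dXres + dQ %*% t(lp$Wq) + dKc %*% t(lp$Wk) + dV %*% t(lp$Wv)
    grads$layers[[l]] <- gl
  }
  list(dX = dX, grads = grads)
}

adamw_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adamw_step <- function(params, grads, state, lr, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2; eps <- cfg$adam_eps
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  # weight decay applies to weight matrices and embedding tables only
  walk <- function(p, g, m, v, name) {
    if (is.list(p)) {
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      for (key in keys) {
        res <- walk(p[[key]], g[[key]], m[[key]], v[[key]],
                    if (is.character(key)) key else "")
        p[[key]] <- res$p; m[[key]] <- res$m; v[[key]] <- res$v
      }
      return(list(p = p, m = m, v = v))
    }
    m2 <- b1 * m + (1 - b1) * g
    v2 <- b2 * v + (1 - b2) * g^2
    upd <- (m2 / bc1) / (sqrt(v2 / bc2) + eps)
    if (name %in% c("E", "Ttype", "P") || grepl("^W", name)) {
      upd <- upd + cfg$weight_decay * p
    }
    list(p = p - lr * upd, m = m2, v = v2)
  }
  res <- walk(params, grads, state$m, state$v, "")
  list(params = res$p, state = list(m = res$m, v = res$v, t = state$t))
}

#' Pretrain an encoder by (constrained) masked language modeling
#'
#' The training loop: seeded shuffling into equal-length batches, random
#' codon masking, forward pass, synonym-constrained (or plain) softmax
#' cross-entropy over the masked positions, full backpropagation, and
#' AdamW updates under the warmup-plus-cosine learning-rate schedule.
#' When the constraint is enabled, gradients at non-synonymous logit
#' entries are exactly zero, so parameter updates never move probability
#' mass across amino-acid families.
#'
#' @param model A [init_model()] result.
#' @param tokenizer A [codon_tokenizer()].
#' @param sequences Character vector of coding sequences (the corpus).
#' @param config A [train_config()].
#' @param token_type_ids Integer vector of token-type IDs per sequence
#'   (recycled); default 0.
#' @param mask_matrix Constraint matrix from [build_synonym_mask()];
#'   required when `config$constraint_enabled`.
#' @param verbose Print a line per epoch (default `FALSE`).
#' @return A list of class `pretrain_result`: `model` (trained),
#'   `metrics` (tibble: step, epoch, loss, masked_accuracy, lr, n_masked),
#'   `config`.
#' @export
pretrain <- function(model, tokenizer, sequences, config,
                     token_type_ids = 0L, mask_matrix = NULL,
                     verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (length(sequences) == 0L) stop("empty corpus", call. = FALSE)
  if (config$constraint_enabled && is.null(mask_matrix)) {
    mask_matrix <- build_synonym_mask(tokenizer, genetic_code())
  }
  use_mask <- if (config$constraint_enabled) mask_matrix else NULL
  n <- length(sequences)
  token_type_ids <- rep_len(as.integer(token_type_ids), n)
  ids_list <- lapply(sequences, function(s) {
    encode_cds(tokenizer, s, max_positions = model$config$max_positions)
  })
  lens <- lengths(ids_list)
  state <- adamw_init(model$params)
  metrics <- vector("list", 0L)
  step <- 0L
  batches_per_epoch <- sum(vapply(split(seq_len(n), lens), function(idx) {
    length(split(idx, ceiling(seq_along(idx) / config$batch_size)))
  }, numeric(1)))
  total_steps <- batches_per_epoch * config$epochs
  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      batch_sets <- unlist(lapply(split(perm, lens[perm]), function(idx) {
        split(idx, ceiling(seq_along(idx) / config$batch_size))
      }), recursive = FALSE)
      for (bi in batch_sets) {
        ids <- do.call(rbind, ids_list[bi])
        mb <- mask_batch(ids, tokenizer, config$mask_probability,
                         config$corruption)
        if (mb$n_masked == 0L) next
        lr <- lr_at_step(step, total_steps, config$max_lr,
                         config$warmup_fraction)
        lg <- loss_and_grads(model, mb, token_type_ids[bi], use_mask,
                             train = config$dropout > 0)
        upd <- adamw_step(model$params, lg$grads, state, lr, config)
        model$params <- upd$params
        state <- upd$state
        step <- step + 1L
        metrics[[step]] <- tibble::tibble(
          step = step, epoch = epoch, loss = lg$loss,
          masked_accuracy = lg$accuracy, lr = lr, n_masked = lg$n_masked
        )
      }
      if (verbose) {
        last <- metrics[[step]]
        message(sprintf("epoch %d/%d  loss %.4f  acc %.3f", epoch,
                        config$epochs, last$loss, last$masked_accuracy))
      }
    }
  })
  structure(list(model = model, metrics = dplyr::bind_rows(metrics),
                 config = config),
            class = "pretrain_result")
}

#' Analytic masked-accuracy baseline under the constraint
#'
#' The expected masked accuracy of a guesser that is uniform within each
#' synonymous family: the average of `1 / n_i` over the corpus's codon
#' composition. A constrained model that has learned nothing beyond the
#' family structure attains this value; learned codon-level context shows
#' up as the excess above it.
#'
#' @param sequences Character vector of coding sequences.
#' @param code A [genetic_code()] object.
#' @return The baseline accuracy (scalar in `[0, 1]`).
#' @export
uniform_constraint_baseline <- function(sequences, code = genetic_code()) {
  cods <- unlist(lapply(sequences, split_codons), use.names = FALSE)
  mean(1 / code$degeneracy[cods])
}
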