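#' Encoder configuration
#'
#' Configuration for the bidirectional transformer encoder with
#' disentangled content/position attention and a weight-tied language
#' head. Three named presets are provided: `"desk"` (2 layers, hidden 64,
#' 4 heads — the size exercised throughout the tests and demonstrations),
#' `"ablation"` (hidden 320, intermediate 1280, 6 layers, 5 heads, about
#' 9M parameters) and `"full"` (hidden 768, intermediate 3072, 12 layers,
#' 12 heads, maximum 1024 positions).
#'
#' @param preset One of `"desk"`, `"ablation"`, `"full"`.
#' @param hidden_size,intermediate_size,num_layers,num_heads Architecture
#'   overrides; `hidden_size` must be divisible by `num_heads`.
#' @param max_positions Maximum total token positions including the start
#'   and end tokens.
#' @param vocab_size Vocabulary size (69: 64 codons + 5 specials).
#' @param num_token_types Number of token-type (species-cluster) IDs,
#'   including the reserved unknown ID (501 in the full model).
#' @param dropout Dropout rate used during training.
#' @param relative_position_buckets Maximum relative distance `K`; relative
#'   offsets are clipped to `[-K, K]` and share one embedding table across
#'   layers.
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(preset = c("desk", "ablation", "full"),
                           hidden_size = NULL, intermediate_size = NULL,
                           num_layers = NULL, num_heads = NULL,
                           max_positions = NULL, vocab_size = 69L,
                           num_token_types = 2L, dropout = 0.1,
                           relative_position_buckets = NULL) {
  preset <- match.arg(preset)
  base <- switch(preset,
    desk = list(hidden_size = 64L, intermediate_size = 256L,
                num_layers = 2L, num_heads = 4L, max_positions = 128L,
                relative_position_buckets = 8L),
    ablation = list(hidden_size = 320L, intermediate_size = 1280L,
                    num_layers = 6L, num_heads = 5L, max_positions = 1024L,
                    relative_position_buckets = 256L),
    full = list(hidden_size = 768L, intermediate_size = 3072L,
                num_layers = 12L, num_heads = 12L, max_positions = 1024L,
                relative_position_buckets = 256L)
  )
  cfg <- list(
    hidden_size = hidden_size %||% base$hidden_size,
    intermediate_size = intermediate_size %||% base$intermediate_size,
    num_layers = num_layers %||% base$num_layers,
    num_heads = num_heads %||% base$num_heads,
    max_positions = max_positions %||% base$max_positions,
    vocab_size = as.integer(vocab_size),
    num_token_types = as.integer(num_token_types),
    dropout = dropout,
    relative_position_buckets =
      relative_position_buckets %||% base$relative_position_buckets
  )
  if (cfg$hidden_size %% cfg$num_heads != 0L) {
    stop("hidden_size (", cfg$hidden_size,
         ") must be divisible by num_heads (", cfg$num_heads, ")",
         call. = FALSE)
  }
  structure(cfg, class = "encoder_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initialize an encoder model
#'
#' Parameters are drawn from Normal(0, 0.02) (layer-norm gains 1, biases
#' 0), deterministically for a given seed. The language head owns no
#' separate projection: output scores are inner products with rows of the
#' token embedding table `E` plus a per-token bias (weight tying).
#'
#' @param config An [encoder_config()].
#' @param seed Integer seed.
#' @return An object of class `syncodon_model`: list with `config` and
#'   `params` (named list of arrays; `params$E` is shared by the input
#'   embedding and the output projection).
#' @export
init_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "encoder_config"))
  H <- config$hidden_size
  I <- config$intermediate_size
  K <- config$relative_position_buckets
  rmat <- function(r, c) matrix(stats::rnorm(r * c, 0, 0.02), r, c)
  withr::with_seed(seed, {
    params <- list(
      E = rmat(config$vocab_size, H),
      Ttype = rmat(config$num_token_types, H),
      P = rmat(2L * K + 1L, H),
      b_out = numeric(config$vocab_size),
      layers = lapply(seq_len(config$num_layers), function(l) {
        list(
          Wq = rmat(H, H), bq = numeric(H),
          Wk = rmat(H, H), bk = numeric(H),
          Wv = rmat(H, H), bv = numeric(H),
          Wo = rmat(H, H), bo = numeric(H),
          ln1_g = rep(1, H), ln1_b = numeric(H),
          W1 = rmat(H, I), b1 = numeric(I),
          W2 = rmat(I, H), b2 = numeric(H),
          ln2_g = rep(1, H), ln2_b = numeric(H)
        )
      })
    )
  })
  structure(list(config = config, params = params),
            class = "syncodon_model")
}

#' @export
print.syncodon_model <- function(x, ...) {
  cfg <- x$config
  cat("<syncodon_model> ", cfg$num_layers, " layers, hidden ",
      cfg$hidden_size, ", ", cfg$num_heads, " heads, ",
      format(n_params(x), big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

#' Total number of model parameters
#'
#' @param model A [init_model()] result.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  count <- function(p) {
    if (is.list(p)) sum(vapply(p, count, numeric(1))) else length(p)
  }
  count(model$params)
}

#' Embed token ids (content plus token-type embeddings)
#'
#' Each position's input vector is the sum of its token embedding and the
#' sequence's token-type embedding. No absolute-position embedding is
#' added: positional information enters through the relative-position
#' terms of the attention mechanism.
#'
#' @param model A [init_model()] result.
#' @param token_ids Integer matrix (batch x positions) of 0-based token
#'   ids, or a single integer vector.
#' @param token_type_ids Integer vector of 0-based token-type IDs, one per
#'   sequence (recycled to the batch size). Default 0.
#' @return Numeric matrix of shape `(batch * positions) x hidden` with
#'   attributes `B` and `L`; row `(b-1)*L + i` is sequence `b`, position
#'   `i`.
#' @export
embed_inputs <- function(model, token_ids, token_type_ids = 0L) {
  if (is.vector(token_ids)) token_ids <- matrix(token_ids, nrow = 1L)
  B <- nrow(token_ids)
  L <- ncol(token_ids)
  cfg <- model$config
  if (any(token_ids < 0L) || any(token_ids >= cfg$vocab_size)) {
    stop("token id out of range", call. = FALSE)
  }
  token_type_ids <- rep_len(as.integer(token_type_ids), B)
  if (any(token_type_ids < 0L) || any(token_type_ids >= cfg$num_token_types)) {
    stop("token type id out of range", call. = FALSE)
  }
  flat <- as.integer(t(token_ids)) # row (b-1)*L + i = seq b, pos i
  X <- model$params$E[flat + 1L, , drop = FALSE] +
    model$params$Ttype[rep(token_type_ids, each = L) + 1L, , drop = FALSE]
  attr(X, "B") <- B
  attr(X, "L") <- L
  X
}

relative_buckets <- function(L, K) {
  d <- outer(seq_len(L), seq_len(L), function(i, j) j - i)
  matrix(pmin(pmax(d, -K), K) + K + 1L, L, L)
}

# Memoized bucket-index matrices (one per distinct sequence length).
rel_structures <- local({
  cache <- new.env(parent = emptyenv())
  function(L, K) {
    key <- paste0(L, "_", K)
    if (is.null(cache[[key]])) {
      cache[[key]] <- list(Bmat = relative_buckets(L, K), L = L)
    }
    cache[[key]]
  }
})

layer_norm_fwd <- function(Y, g, b) {
  mu <- rowMeans(Y)
  Yc <- Y - mu
  v <- rowMeans(Yc^2)
  inv <- 1 / sqrt(v + 1e-7)
  xhat <- Yc * inv
  list(out = sweep(xhat * g[col(xhat)], 2L, b, `+`), xhat = xhat, inv = inv)
}

layer_norm_bwd <- function(dout, cache, g) {
  H <- ncol(dout)
  dxhat <- dout * g[col(dout)]
  xhat <- cache$xhat
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * xhat)
  dY <- (dxhat - s1 / H - xhat * s2 / H) * cache$inv
  list(dY = dY, dg = dg, db = db)
}

# sigmoid-approximated GELU (x * sigmoid(1.702 x)); one exp per entry
gelu <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  x * s
}
gelu_grad <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  s * (1 + 1.702 * x * (1 - s))
}

row_max_finite <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  m[!is.finite(m)] <- 0
  m
}

softmax_rows <- function(S) {
  ex <- exp(S - row_max_finite(S))
  ex / rowSums(ex)
}

# Forward pass through all encoder layers. `X` is the (B*L) x H embedding
# matrix from embed_inputs(); `valid` a B x L logical matrix of non-pad
# positions. Returns the final hidden states and, when keep_cache = TRUE,
# everything the backward pass needs.
encoder_forward <- function(model, X, valid, train = FALSE,
                            keep_cache = FALSE) {
  cfg <- model$config
  B <- attr(X, "B"); L <- attr(X, "L")
  stopifnot(!is.null(B), !is.null(L), L <= cfg$max_positions)
  H <- cfg$hidden_size
  A <- cfg$num_heads
  dh <- H %/% A
  K <- cfg$relative_position_buckets
  rs <- rel_structures(L, K)
  scale <- 1 / sqrt(3 * dh)
  keep_p <- if (train) 1 - cfg$dropout else 1
  caches <- vector("list", cfg$num_layers)
  rows_of <- function(b) ((b - 1L) * L + 1L):(b * L)
  for (l in seq_len(cfg$num_layers)) {
    lp <- model$params$layers[[l]]
    Q <- X %*% lp$Wq + lp$bq[col(X)]
    Kc <- X %*% lp$Wk + lp$bk[col(X)]
    V <- X %*% lp$Wv + lp$bv[col(X)]
    Qr <- model$params$P %*% lp$Wq
    Kr <- model$params$P %*% lp$Wk
    att <- attn_forward_cpp(Q, Kc, V, Qr, Kr, rs$Bmat, valid + 0L, A,
                            scale)
    O <- att$O
    AO <- O %*% lp$Wo + lp$bo[col(O)]
    drop1 <- NULL
    if (train && cfg$dropout > 0) {
      drop1 <- matrix((stats::runif(length(AO)) < keep_p) / keep_p,
                      nrow(AO), ncol(AO))
      AO <- AO * drop1
    }
    ln1 <- layer_norm_fwd(X + AO, lp$ln1_g, lp$ln1_b)
    X1 <- ln1$out
    U <- sweep(X1 %*% lp$W1, 2L, lp$b1, `+`)
    sig <- 1 / (1 + exp(-1.702 * U))
    G <- U * sig
    FF <- G %*% lp$W2 + lp$b2[col(X1)]
    drop2 <- NULL
    if (train && cfg$dropout > 0) {
      drop2 <- matrix((stats::runif(length(FF)) < keep_p) / keep_p,
                      nrow(FF), ncol(FF))
      FF <- FF * drop2
    }
    ln2 <- layer_norm_fwd(X1 + FF, lp$ln2_g, lp$ln2_b)
    if (keep_cache) {
      caches[[l]] <- list(X = X, Q = Q, Kc = Kc, V = V, Qr = Qr, Kr = Kr,
                          attn = att$P, O = O, drop1 = drop1, ln1 = ln1,
                          X1 = X1, U = U, sig = sig, G = G, drop2 = drop2,
                          ln2 = ln2)
    }
    X <- ln2$out
    attr(X, "B") <- B
    attr(X, "L") <- L
  }
  list(hidden = X,
       cache = if (keep_cache) list(layers = caches, rs = rs,
                                    valid = valid, scale = scale))
}

#' Run the encoder over embedded inputs
#'
#' Applies the stack of disentangled-attention transformer layers. Each
#' layer combines content-to-content, content-to-position and
#' position-to-content attention terms over clipped relative distances;
#' padding positions receive no attention mass. In evaluation mode
#' (default) dropout is disabled and the output is deterministic.
#'
#' @param model A [init_model()] result.
#' @param inputs Embedding matrix from [embed_inputs()].
#' @param valid Logical matrix (batch x positions): `TRUE` for real
#'   (non-pad) positions. Default: all valid.
#' @param train Apply dropout (training mode)? Default `FALSE`.
#' @return Final hidden states, same shape and attributes as `inputs`.
#' @export
forward_hidden <- function(model, inputs, valid = NULL, train = FALSE) {
  B <- attr(inputs, "B"); L <- attr(inputs, "L")
  if (is.null(valid)) valid <- matrix(TRUE, B, L)
  encoder_forward(model, inputs, valid, train = train)$hidden
}

#' Language-model logits from final hidden states
#'
#' Scores every vocabulary token at every position as the inner product of
#' the hidden state with the token's row of the shared embedding table,
#' plus a per-token bias — the weight-tied language head.
#'
#' @param model A [init_model()] result.
#' @param hidden Hidden-state matrix from [forward_hidden()].
#' @return Numeric matrix `(positions) x vocab_size`.
#' @export
lm_logits <- function(model, hidden) {
  out <- sweep(hidden %*% t(model$params$E), 2L, model$params$b_out, `+`)
  attr(out, "B") <- attr(hidden, "B")
  attr(out, "L") <- attr(hidden, "L")
  out
}

#' Mean-pool hidden states over valid positions
#'
#' Arithmetic mean of the hidden vectors over non-pad positions, one
#' pooled vector per sequence; the frozen-embedding representation used by
#' the linear probes.
#'
#' @param hidden Hidden-state matrix from [forward_hidden()] (attributes
#'   `B`, `L`).
#' @param valid Logical matrix (batch x positions); default all valid.
#' @return Numeric matrix `batch x hidden`.
#' @export
mean_pool <- function(hidden, valid = NULL) {
  B <- attr(hidden, "B"); L <- attr(hidden, "L")
  if (is.null(valid)) valid <- matrix(TRUE, B, L)
  out <- matrix(0, B, ncol(hidden))
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    v <- valid[b, ]
    if (!any(v)) stop("sequence ", b, " has no valid positions",
                      call. = FALSE)
    out[b, ] <- colMeans(hidden[rows[v], , drop = FALSE])
  }
  out
}

#' Mean-pooled encoder embeddings for coding sequences
#'
#' Tokenizes, embeds and encodes a set of CDS and returns one mean-pooled
#' vector per sequence. Sequences are grouped by token length into
#' equal-length batches internally.
#'
#' @param model A [init_model()] (or trained) model.
#' @param tokenizer A [codon_tokenizer()].
#' @param sequences Character vector of coding sequences.
#' @param token_type_ids Integer vector of token-type IDs (one per
#'   sequence, recycled); default 0.
#' @param batch_size Sequences per forward batch (default 64).
#' @return Numeric matrix `length(sequences) x hidden_size`.
#' @export
cds_embeddings <- function(model, tokenizer, sequences,
                           token_type_ids = 0L, batch_size = 64L) {
  n <- length(sequences)
  token_type_ids <- rep_len(as.integer(token_type_ids), n)
  ids_list <- lapply(sequences, function(s) {
    encode_cds(tokenizer, s, max_positions = model$config$max_positions)
  })
  lens <- lengths(ids_list)
  out <- matrix(NA_real_, n, model$config$hidden_size)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    for (chunk in split(idx, ceiling(seq_along(idx) / batch_size))) {
      ids <- do.call(rbind, ids_list[chunk])
      X <- embed_inputs(model, ids, token_type_ids[chunk])
      Hm <- forward_hidden(model, X)
      out[chunk, ] <- mean_pool(Hm)
    }
  }
  out
}
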