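test_that("initialization is seed-deterministic with preset shapes", {
  cfg <- encoder_config("desk")
  m1 <- init_model(cfg, seed = 11)
  m2 <- init_model(cfg, seed = 11)
  expect_identical(m1$params, m2$params)
  m3 <- init_model(cfg, seed = 12)
  expect_false(identical(m1$params$E, m3$params$E))
  expect_equal(dim(m1$params$E), c(69L, 64L))
  expect_error(encoder_config("desk", hidden_size = 7L, num_heads = 2L),
               "divisible")
})

test_that("ablation preset lands near its 9 million parameter budget", {
  cfg <- encoder_config("ablation", num_token_types = 501L)
  expect_equal(cfg$hidden_size, 320L)
  expect_equal(cfg$intermediate_size, 1280L)
  expect_equal(cfg$num_layers, 6L)
  expect_equal(cfg$num_heads, 5L)
  n <- n_params(init_model(cfg, seed = 1))
  expect_gt(n, 9e6 * 0.8)
  expect_lt(n, 9e6 * 1.2)
})

test_that("input embedding adds token and token-type rows", {
  mod <- tiny_model()
  ids <- encode_cds(the_tok, "ATGGCTTAA")
  x0 <- embed_inputs(mod, ids, 0L)
  x1 <- embed_inputs(mod, ids, 1L)
  # differ by one constant vector per position
  diffs <- x1 - x0
  expect_true(all(abs(sweep(diffs, 2L, diffs[1, ])) < 1e-12))
  expect_equal(unname(diffs[1, ]),
               unname(mod$params$Ttype[2, ] - mod$params$Ttype[1, ]))
  # zero token-type row makes the output the token embedding alone
  mod0 <- mod
  mod0$params$Ttype[1, ] <- 0
  expect_equal(unname(embed_inputs(mod0, ids, 0L)[2, ]),
               unname(mod0$params$E[ids[2] + 1L, ]))
  expect_error(embed_inputs(mod, c(0L, 200L)), "out of range")
  expect_error(embed_inputs(mod, ids, 99L), "out of range")
})

test_that("evaluation-mode forward pass is deterministic", {
  mod <- tiny_model()
  ids <- rbind(encode_cds(the_tok, random_cds(8)))
  X <- embed_inputs(mod, ids)
  h1 <- forward_hidden(mod, X)
  h2 <- forward_hidden(mod, X)
  expect_identical(h1, h2)
})

test_that("padding positions do not perturb non-pad outputs", {
  mod <- tiny_model()
  cds <- withr::with_seed(2, random_cds(6))
  ids <- encode_cds(the_tok, cds)
  pad <- the_tok$special_tokens[["pad"]]
  ids_padded <- c(ids, rep(pad, 4L))
  h <- forward_hidden(mod, embed_inputs(mod, ids),
                      valid = matrix(TRUE, 1, length(ids)))
  hp <- forward_hidden(mod, embed_inputs(mod, ids_padded),
                       valid = matrix(c(rep(TRUE, length(ids)),
                                        rep(FALSE, 4L)), 1))
  expect_equal(h[seq_along(ids), ], hp[seq_along(ids), ],
               tolerance = 1e-10)
  # pooled representation is pad-invariant too
  expect_equal(
    mean_pool(h, matrix(TRUE, 1, length(ids))),
    mean_pool(hp, matrix(c(rep(TRUE, length(ids)), rep(FALSE, 4L)), 1)),
    tolerance = 1e-10
  )
})

test_that("relative positions make equal content give equal hidden states", {
  # two identical sequences in one batch: all relative offsets agree, so
  # hidden states must match position-wise (no absolute-position leak)
  mod <- tiny_model()
  ids <- encode_cds(the_tok, withr::with_seed(5, random_cds(7)))
  X <- embed_inputs(mod, rbind(ids, ids))
  h <- forward_hidden(mod, X)
  L <- length(ids)
  expect_equal(h[1:L, ], h[(L + 1):(2 * L), ], tolerance = 1e-12)
})

test_that("the language head is weight-tied to the input embedding", {
  mod <- tiny_model()
  ids <- encode_cds(the_tok, "ATGGCTTAA")
  v <- ids[2] # token id of ATG
  X <- embed_inputs(mod, ids)
  h <- forward_hidden(mod, X)
  lg <- lm_logits(mod, h)
  expect_equal(dim(lg), c(length(ids), 69L))
  # perturbing E[v] changes both the input embedding and logits column v
  # (a non-constant perturbation: layer-norm zero-centres hidden rows, so
  # adding a constant vector to an E row leaves its logit column fixed)
  mod2 <- mod
  mod2$params$E[v + 1L, 1L] <- mod2$params$E[v + 1L, 1L] + 0.5
  expect_false(isTRUE(all.equal(embed_inputs(mod2, ids)[2, ],
                                X[2, ])))
  lg2 <- lm_logits(mod2, h)
  expect_false(isTRUE(all.equal(lg2[, v + 1L], lg[, v + 1L])))
  expect_equal(lg2[, -(v + 1L)], lg[, -(v + 1L)]) # other columns fixed
  # logits are inner products with E rows plus the bias
  expect_equal(unname(lg[1, ]),
               unname(drop(mod$params$E %*% h[1, ]) + mod$params$b_out))
})

test_that("orthonormal embeddings score their own token highest", {
  mod <- tiny_model()
  # plant an orthonormal embedding block and feed h = E[v]
  mod$params$E <- diag(1, 69, mod$config$hidden_size)
  mod$params$b_out[] <- 0
  h <- mod$params$E[10, , drop = FALSE]
  attr(h, "B") <- 1L; attr(h, "L") <- 1L
  lg <- lm_logits(mod, h)
  expect_equal(which.max(lg[1, ]), 10L)
})

test_that("mean pooling averages valid positions only", {
  mod <- tiny_model()
  h <- matrix(rnorm(5 * 16), 5, 16)
  attr(h, "B") <- 1L; attr(h, "L") <- 5L
  expect_equal(drop(mean_pool(h)), colMeans(h))
  v <- matrix(c(TRUE, FALSE, FALSE, FALSE, FALSE), 1)
  expect_equal(drop(mean_pool(h, v)), h[1, ])
  expect_error(mean_pool(h, matrix(FALSE, 1, 5)), "no valid")
  # constant hidden states pool to the constant
  hc <- matrix(2, 4, 16); attr(hc, "B") <- 1L; attr(hc, "L") <- 4L
  expect_equal(drop(mean_pool(hc)), rep(2, 16))
})

test_that("analytic gradients match numerical gradients", {
  cfg <- encoder_config("desk", hidden_size = 8L, intermediate_size = 16L,
                        num_layers = 2L, num_heads = 2L,
                        relative_position_buckets = 3L,
                        num_token_types = 3L, dropout = 0)
  mod <- init_model(cfg, seed = 7)
  ids <- do.call(rbind, lapply(c("ATGCTGAAATCTTAA", "ATGGCGCGTTGGTAA"),
                               function(s) encode_cds(the_tok, s)))
  batch <- withr::with_seed(5, mask_batch(ids, the_tok, 0.5))
  lg <- syncodon:::loss_and_grads(mod, batch, c(0L, 1L), the_mask)
  get_path <- function(p, path) { for (k in path) p <- p[[k]]; p }
  set_path <- function(p, path, val) {
    if (length(path) == 1L) { p[[path[[1]]]] <- val; return(p) }
    p[[path[[1]]]] <- set_path(p[[path[[1]]]], path[-1], val)
    p
  }
  eps <- 1e-5
  paths <- list(list("E"), list("P"), list("Ttype"),
                list("layers", 1, "Wq"), list("layers", 1, "Wk"),
                list("layers", 2, "Wo"), list("layers", 1, "W1"),
                list("layers", 2, "ln1_g"))
  withr::with_seed(31, {
    for (pth in paths) {
      arr <- get_path(mod$params, pth)
      g_an <- get_path(lg$grads, pth)
      for (i in sample(length(arr), 3)) {
        m2 <- mod
        a <- arr; a[i] <- a[i] + eps
        m2$params <- set_path(m2$params, pth, a)
        up <- syncodon:::loss_and_grads(m2, batch, c(0L, 1L),
                                        the_mask)$loss
        a[i] <- arr[i] - eps
        m2$params <- set_path(m2$params, pth, a)
        dn <- syncodon:::loss_and_grads(m2, batch, c(0L, 1L),
                                        the_mask)$loss
        g_num <- (up - dn) / (2 * eps)
        expect_lt(abs(g_num - g_an[i]),
                  1e-4 * max(1, abs(g_num) + abs(g_an[i])))
      }
    }
  })
})

test_that("cds_embeddings handles mixed lengths and batching", {
  mod <- tiny_model()
  seqs <- withr::with_seed(6, c(random_cds(5), random_cds(9),
                                random_cds(5)))
  emb <- cds_embeddings(mod, the_tok, seqs, batch_size = 2L)
  expect_equal(dim(emb), c(3L, 16L))
  # singleton call agrees with batched call
  single <- cds_embeddings(mod, the_tok, seqs[2])
  expect_equal(emb[2, ], single[1, ], tolerance = 1e-12)
})
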