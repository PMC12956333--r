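test_that("masking selects codon positions only, at the requested rate", {
  ids <- do.call(rbind, lapply(1:20, function(i) {
    encode_cds(the_tok, withr::with_seed(i, random_cds(20)))
  }))
  mb0 <- withr::with_seed(1, mask_batch(ids, the_tok, 1e-12))
  expect_equal(mb0$n_masked, 0L)
  mb1 <- withr::with_seed(1, mask_batch(ids, the_tok, 1 - 1e-12))
  expect_equal(mb1$n_masked, sum(ids >= 5L)) # every codon position
  # specials untouched
  specials <- ids < 5L
  expect_identical(mb1$input_ids[specials], ids[specials])
  expect_true(all(mb1$input_ids[!specials] ==
                    the_tok$special_tokens[["mask"]]))
  expect_true(all(is.na(mb1$labels[specials])))
  # empirical rate concentrates (binomial) at moderate scale
  mb <- withr::with_seed(2, mask_batch(ids, the_tok, 0.15))
  rate <- mb$n_masked / sum(ids >= 5L)
  expect_lt(abs(rate - 0.15), 0.05)
})

test_that("bert-style corruption keeps the selection rate and labels", {
  ids <- do.call(rbind, lapply(1:30, function(i) {
    encode_cds(the_tok, withr::with_seed(100 + i, random_cds(30)))
  }))
  mb <- withr::with_seed(3, mask_batch(ids, the_tok, 0.5, "bert"))
  sel <- !is.na(mb$labels)
  expect_identical(mb$labels[sel], ids[sel])
  # roughly 10% of selected positions keep their original codon
  kept <- mean(mb$input_ids[sel] == ids[sel])
  expect_lt(abs(kept - 0.1), 0.06)
  masked <- mean(mb$input_ids[sel] == the_tok$special_tokens[["mask"]])
  expect_lt(abs(masked - 0.8), 0.08)
})

test_that("constrained softmax puts zero mass outside the family", {
  withr::with_seed(7, {
    for (rep in 1:50) {
      lab <- sample(unname(the_tok$codon_ids), 1)
      logits <- matrix(rnorm(69, sd = 3), 1, 69)
      z <- constrain_logits(logits, lab, the_mask)
      p <- exp(z - max(z))
      p <- p / sum(p)
      fam <- synonymous_set(the_tok$vocab[lab + 1L], the_code)
      outside <- setdiff(the_tok$vocab, fam)
      expect_identical(sum(p[1, match(outside, the_tok$vocab)]), 0)
      # synonymous entries keep the raw logits unchanged
      ins <- match(fam, the_tok$vocab)
      expect_equal(z[1, ins], logits[1, ins])
    }
  })
  expect_error(constrain_logits(matrix(0, 1, 69), 2L, the_mask),
               "special")
})

test_that("constrained loss has the closed-form values", {
  # uniform logits, one masked leucine codon -> ln 6
  z <- constrain_logits(matrix(0, 1, 69), the_tok$codon_ids[["CTG"]],
                        the_mask)
  expect_equal(mlm_loss(z, the_tok$codon_ids[["CTG"]]), log(6))
  # two-fold family -> ln 2
  z2 <- constrain_logits(matrix(0, 1, 69), the_tok$codon_ids[["AAA"]],
                         the_mask)
  expect_equal(mlm_loss(z2, the_tok$codon_ids[["AAA"]]), log(2))
  # singleton family: loss exactly 0 whatever the logits
  withr::with_seed(1, {
    raw <- matrix(rnorm(69, sd = 5), 1, 69)
  })
  z3 <- constrain_logits(raw, the_tok$codon_ids[["ATG"]], the_mask)
  expect_identical(mlm_loss(z3, the_tok$codon_ids[["ATG"]]), 0)
  # batch loss is the |M|-average of per-position losses
  labs <- c(the_tok$codon_ids[["CTG"]], the_tok$codon_ids[["AAA"]])
  zb <- constrain_logits(matrix(0, 2, 69), labs, the_mask)
  expect_equal(mlm_loss(zb, labs), (log(6) + log(2)) / 2)
  expect_error(mlm_loss(zb, c(NA, NA)), "no masked")
})

test_that("constraint never increases the loss for identical logits", {
  withr::with_seed(12, {
    for (rep in 1:25) {
      lab <- sample(unname(the_tok$codon_ids), 4)
      raw <- matrix(rnorm(4 * 69), 4, 69)
      zc <- constrain_logits(raw, lab, the_mask)
      expect_lte(mlm_loss(zc, lab), mlm_loss(raw, lab) + 1e-12)
    }
  })
})

test_that("masked accuracy: ties, one-hot, and constraint dominance", {
  lab <- the_tok$codon_ids[["GCT"]]
  onehot <- matrix(-10, 1, 69)
  onehot[1, lab + 1L] <- 10
  expect_equal(masked_accuracy(onehot, lab), 1)
  # exact ties break to the lowest token id
  fam_ids <- sort(the_tok$codon_ids[synonymous_set("GCT")])
  z <- constrain_logits(matrix(0, 1, 69), fam_ids[1], the_mask)
  expect_equal(masked_accuracy(z, fam_ids[1]), 1) # truth has lowest id
  z2 <- constrain_logits(matrix(0, 1, 69), fam_ids[2], the_mask)
  expect_equal(masked_accuracy(z2, fam_ids[2]), 0)
  # with jittered logits on 2-fold families, accuracy ~ 0.5
  two_fold <- names(the_code$degeneracy)[the_code$degeneracy == 2]
  withr::with_seed(9, {
    labs <- the_tok$codon_ids[sample(two_fold, 2000, replace = TRUE)]
    raw <- matrix(rnorm(2000 * 69, sd = 0.3), 2000, 69)
    zc <- constrain_logits(raw, labs, the_mask)
    expect_lt(abs(masked_accuracy(zc, labs) - 0.5), 0.05)
    # enabling the constraint can only help on random logits
    expect_gte(masked_accuracy(zc, labs), masked_accuracy(raw, labs))
  })
})

test_that("learning-rate schedule matches warmup plus cosine decay", {
  total <- 1000
  expect_equal(lr_at_step(0, total), 0)
  expect_equal(lr_at_step(100, total), 2e-4) # end of 10% warmup
  expect_equal(lr_at_step(550, total), 1e-4) # decay midpoint
  expect_equal(lr_at_step(total, total), 0)
  # continuous, bounded by max_lr, single peak
  lr <- lr_at_step(0:total, total)
  expect_equal(max(lr), 2e-4)
  expect_true(all(abs(diff(lr)) < 2e-4 / 50))
})

test_that("gradients vanish exactly at constrained-out logit entries", {
  cfg <- encoder_config("desk", hidden_size = 16L,
                        intermediate_size = 32L, num_layers = 1L,
                        num_heads = 2L, relative_position_buckets = 4L,
                        num_token_types = 2L, dropout = 0)
  mod <- init_model(cfg, seed = 3)
  ids <- rbind(encode_cds(the_tok, "ATGCTGAAACTGTAA"))
  batch <- withr::with_seed(8, mask_batch(ids, the_tok, 0.9))
  lab <- batch$labels[!is.na(batch$labels)]
  lg <- syncodon:::loss_and_grads(mod, batch, 0L, the_mask)
  # rows of dE for codons non-synonymous with every masked label must be 0:
  # their logit entries are -Inf at every masked position
  masked_fams <- unique(unlist(lapply(lab, function(l) {
    synonymous_set(the_tok$vocab[l + 1L], the_code)
  })))
  # a codon absent from the input and from every masked family gets no
  # gradient at all (neither embedding nor head)
  inert <- setdiff(names(the_tok$codon_ids), masked_fams)
  inert <- inert[!(the_tok$codon_ids[inert] %in% as.vector(ids))]
  expect_gt(length(inert), 0L)
  for (cod in inert) {
    expect_identical(max(abs(lg$grads$E[the_tok$codon_ids[[cod]] + 1L, ])),
                     0)
    expect_identical(unname(lg$grads$b_out[the_tok$codon_ids[[cod]] + 1L]),
                     0)
  }
})

test_that("initial constrained loss matches the corpus ln-degeneracy", {
  # at initialization logits are nearly uniform, so the constrained loss
  # approaches the masked-codon average of ln n_i
  seqs <- withr::with_seed(14, replicate(30, random_cds(25)))
  ids <- do.call(rbind, lapply(seqs, function(s) encode_cds(the_tok, s)))
  mod <- tiny_model(seed = 2)
  batch <- withr::with_seed(15, mask_batch(ids, the_tok, 0.15))
  lg <- syncodon:::loss_and_grads(mod, batch, 0L, the_mask)
  lab <- batch$labels[!is.na(batch$labels)]
  expected <- mean(log(the_code$degeneracy[the_tok$vocab[lab + 1L]]))
  expect_lt(abs(lg$loss - expected) / expected, 0.05)
})

test_that("a short training run reduces the constrained loss", {
  corpus <- make_demo_corpus(60, protein_length = 12L, seed = 33)
  cfg <- encoder_config("desk", hidden_size = 32L,
                        intermediate_size = 64L, num_layers = 1L,
                        num_heads = 2L, relative_position_buckets = 4L,
                        num_token_types = 2L)
  tc <- train_config(epochs = 8L, batch_size = 20L, seed = 5,
                     mask_probability = 0.3)
  res <- pretrain(init_model(cfg, seed = 1), the_tok, corpus$sequence, tc)
  expect_s3_class(res$metrics, "tbl_df")
  first <- mean(res$metrics$loss[1:3])
  last <- mean(utils::tail(res$metrics$loss, 3))
  expect_lt(last, first)
  # identical config and seed reproduce the run exactly
  res2 <- pretrain(init_model(cfg, seed = 1), the_tok, corpus$sequence,
                   tc)
  expect_identical(res$metrics, res2$metrics)
  expect_identical(res$model$params$E, res2$model$params$E)
  expect_error(pretrain(init_model(cfg, seed = 1), the_tok, character(0),
                        tc),
               "empty corpus")
})

test_that("uniform-constraint baseline averages reciprocal degeneracy", {
  expect_equal(uniform_constraint_baseline("ATGTGG"), 1)
  expect_equal(uniform_constraint_baseline("CTGCTA"), 1 / 6)
  expect_equal(uniform_constraint_baseline(c("ATG", "AAA")),
               mean(c(1, 1 / 2)))
})
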