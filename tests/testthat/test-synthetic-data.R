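test_that("species profiles are reproducible and taxon-structured", {
  p1 <- make_species_profiles(6, 2, seed = 5)
  p2 <- make_species_profiles(6, 2, seed = 5)
  expect_identical(p1, p2)
  expect_length(p1, 6L)
  expect_equal(p1[[1]]$taxon_group, "taxon_01")
  # per-family probabilities sum to 1
  for (probs in p1[[1]]$family_probs) {
    expect_equal(sum(probs), 1, tolerance = 1e-12)
  }
  expect_error(make_species_profiles(2, 5), "n_species >= n_taxa")
})

test_that("high concentration collapses species onto the taxon mean", {
  hi <- make_species_profiles(10, 1, dirichlet_concentration = 1e6,
                              seed = 3)
  fam <- names(hi[[1]]$family_probs)[1]
  probs <- vapply(hi, function(p) p$family_probs[[fam]], numeric(
    length(hi[[1]]$family_probs[[fam]])))
  expect_lt(max(apply(probs, 1L, stats::sd)), 1e-2)
})

test_that("sampled CDS encode the requested protein and validate", {
  prof <- make_species_profiles(1, 1, seed = 2)[[1]]
  withr::with_seed(11, {
    for (i in 1:20) {
      cds <- sample_cds(prof, 15)
      expect_equal(validate_cds(cds), "pass")
      expect_equal(substr(cds, 1, 3), "ATG")
      expect_equal(translate_codon(substr(cds, nchar(cds) - 2,
                                          nchar(cds))), "*")
      expect_equal(nchar(cds), 16 * 3)
    }
    # supplied protein is encoded faithfully
    cds <- sample_cds(prof, protein = "MKVLA")
    cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    expect_equal(paste0(translate_codon(cods), collapse = ""), "MKVLA*")
  })
})

test_that("sampled codon frequencies match the profile (LLN)", {
  prof <- make_species_profiles(1, 1, seed = 8)[[1]]
  seqs <- withr::with_seed(9, replicate(60, sample_cds(prof, 80)))
  counts <- codon_counts(seqs)
  leu <- synonymous_set("CTG")
  emp <- counts[leu] / sum(counts[leu])
  expect_lt(max(abs(emp - prof$family_probs[["L"]][leu])), 0.05)
})

test_that("an identity wobble transition locks consecutive wobble bases", {
  ident <- diag(4)
  dimnames(ident) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  prof <- make_species_profiles(1, 1, seed = 4,
                                wobble_transition = ident)[[1]]
  # glycine run: GG[ACGT] family permits every wobble base, so the chain
  # must stay on the wobble base of the first sampled glycine codon
  cds <- withr::with_seed(5, sample_cds(prof, protein = strrep("G", 30)))
  cods <- substring(cds, 4, nchar(cds) - 3)
  cods <- substring(cods, seq(1, nchar(cods), 3), seq(3, nchar(cods), 3))
  expect_equal(length(unique(substr(cods, 3, 3))), 1L)
})

test_that("variant libraries encode one protein with GC3-driven fitness", {
  lib <- make_variant_library(25, 60, beta = 4, noise_sd = 0, seed = 21)
  expect_equal(nrow(lib$data), 60L)
  prots <- vapply(lib$data$sequence, function(s) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    paste0(translate_codon(cods), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  expect_length(unique(prots), 1L)
  # noiseless: fitness is exactly affine in GC3; a linear fit attains R2 = 1
  fit <- stats::lm(fitness ~ gc3, data = lib$data)
  r2 <- 1 - sum(stats::resid(fit)^2) /
    sum((lib$data$fitness - mean(lib$data$fitness))^2)
  expect_gt(r2, 1 - 1e-12)
  expect_equal(unname(stats::coef(fit)[2]), 4, tolerance = 1e-9)
  # beta = 0: fitness is pure noise, uncorrelated with GC3
  lib0 <- make_variant_library(25, 200, beta = 0, noise_sd = 0.3,
                               seed = 22)
  expect_lt(stats::cor(lib0$data$gc3, lib0$data$fitness)^2, 0.05)
  expect_error(make_variant_library(10, 1), "n_variants >= 2")
})

test_that("synonymous mutation respects level, identity and translation", {
  cds <- "ATGCTGAAATCTTGGTAA"
  expect_identical(withr::with_seed(1, mutate_synonymously(cds, 0)), cds)
  # singleton-only sequences never change
  only_singletons <- "ATGTGGTGGATG"
  expect_identical(withr::with_seed(2,
    mutate_synonymously(only_singletons, 1)), only_singletons)
  # level 1: every degenerate codon differs, translation preserved
  mut <- withr::with_seed(3, mutate_synonymously(cds, 1))
  orig <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  new <- substring(mut, seq(1, nchar(mut), 3), seq(3, nchar(mut), 3))
  deg <- the_code$degeneracy[orig] >= 2
  expect_true(all(orig[deg] != new[deg]))
  expect_true(all(orig[!deg] == new[!deg]))
  expect_equal(translate_codon(new), translate_codon(orig))
  expect_error(mutate_synonymously("ATGGC", 0.5), "invalid CDS")
})

test_that("the mutated fraction equals round(level * D) / D exactly", {
  withr::with_seed(17, {
    for (i in 1:30) {
      cds <- random_cds(sample(5:30, 1))
      orig <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
      D <- sum(the_code$degeneracy[orig] >= 2)
      level <- stats::runif(1)
      mut <- mutate_synonymously(cds, level)
      new <- substring(mut, seq(1, nchar(mut), 3), seq(3, nchar(mut), 3))
      expect_equal(sum(orig != new), round(level * D))
    }
  })
})

test_that("translation is invariant under fuzzed synonymous mutation", {
  withr::with_seed(23, {
    for (i in 1:200) {
      cds <- random_cds(sample(3:25, 1))
      mut <- mutate_synonymously(cds, stats::runif(1))
      expect_equal(validate_cds(mut), "pass")
      o <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
      n <- substring(mut, seq(1, nchar(mut), 3), seq(3, nchar(mut), 3))
      expect_equal(translate_codon(n), translate_codon(o))
    }
  })
})

test_that("demo corpus plants recoverable wobble and residue structure", {
  corpus <- make_demo_corpus(150, protein_length = 20L, seed = 31)
  expect_equal(nrow(corpus), 150L)
  expect_true(all(validate_cds(corpus$sequence) == "pass"))
  expect_identical(corpus,
                   make_demo_corpus(150, protein_length = 20L, seed = 31))
  # consecutive wobble bases follow the cyclic shift more often than chance
  shift <- c(A = "C", C = "G", G = "T", T = "A")
  cons <- unlist(lapply(corpus$sequence, function(s) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    w <- substr(cods, 3, 3)
    w[-1] == shift[w[-length(w)]]
  }))
  expect_gt(mean(cons), 0.4) # chance level would be 0.25
})
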