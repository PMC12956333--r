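#' Synthetic species codon-usage profiles
#'
#' Generates species-specific codon-usage profiles with recoverable
#' taxon-level structure: each taxon group draws a Dirichlet mean per
#' synonymous family, and each species draws its per-family codon
#' probabilities from a Dirichlet centred on its taxon's mean with the
#' given concentration. As the concentration grows, species profiles
#' converge to the taxon mean, so RSCU clustering can recover the taxa.
#'
#' @param n_species Number of species (split as evenly as possible across
#'   taxa).
#' @param n_taxa Number of taxon groups.
#' @param dirichlet_concentration Concentration of the species-level
#'   Dirichlet around the taxon mean (default 200: clearly clusterable,
#'   visibly noisy).
#' @param seed Integer seed; generation is bitwise-reproducible.
#' @param wobble_transition Optional 4x4 row-stochastic matrix (rows and
#'   columns A, C, G, T): first-order dependence of a codon's wobble base
#'   on the previous codon's wobble base, shared by all species.
#' @param code A [genetic_code()] object.
#' @return A list of `species_profile` objects: each has `species`,
#'   `taxon_group`, `family_probs` (named list of per-family probability
#'   vectors over codons, families of size >= 2 including the stop family),
#'   and `wobble_transition` (or `NULL`).
#' @export
make_species_profiles <- function(n_species, n_taxa,
                                  dirichlet_concentration = 200,
                                  seed = 1L, wobble_transition = NULL,
                                  code = genetic_code()) {
  stopifnot(n_species >= n_taxa, n_taxa >= 1)
  if (!is.null(wobble_transition)) {
    stopifnot(all(dim(wobble_transition) == c(4L, 4L)),
              all(abs(rowSums(wobble_transition) - 1) < 1e-8))
  }
  fams <- code$families[vapply(code$families, length, integer(1)) >= 2L]
  taxa <- sprintf("taxon_%02d", seq_len(n_taxa))
  taxon_of <- rep(taxa, length.out = n_species)
  withr::with_seed(seed, {
    taxon_means <- lapply(taxa, function(tx) {
      lapply(fams, function(fam) {
        stats::setNames(rdirichlet1(rep(1, length(fam))), fam)
      })
    })
    names(taxon_means) <- taxa
    lapply(seq_len(n_species), function(i) {
      tx <- taxon_of[i]
      probs <- lapply(taxon_means[[tx]], function(m) {
        stats::setNames(rdirichlet1(dirichlet_concentration * m), names(m))
      })
      structure(
        list(species = sprintf("species_%03d", i), taxon_group = tx,
             family_probs = probs, wobble_transition = wobble_transition),
        class = "species_profile"
      )
    })
  })
}

rdirichlet1 <- function(alpha) {
  # one Dirichlet draw via normalized gammas; guard exact-zero draws
  g <- stats::rgamma(length(alpha), shape = pmax(alpha, 1e-8), rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Sample a coding sequence from a species profile
#'
#' Draws a protein uniformly (first residue methionine) unless one is
#' supplied, then draws each codon from the profile's per-family
#' probabilities, optionally re-weighted by the wobble-transition matrix
#' given the previous codon's wobble base. The CDS starts with ATG and
#' ends with a stop codon drawn from the profile's stop-family
#' distribution, and always passes [validate_cds()]. Uses the current RNG
#' state; seed at the call site for reproducibility.
#'
#' @param profile A `species_profile` from [make_species_profiles()].
#' @param protein_length Number of residues (including the initial
#'   methionine when the protein is drawn).
#' @param protein Optional character string of 1-letter amino-acid symbols
#'   to encode instead of a random protein.
#' @param code A [genetic_code()] object.
#' @return A DNA string of `(residues + 1) * 3` characters.
#' @export
sample_cds <- function(profile, protein_length, protein = NULL,
                       code = genetic_code()) {
  aa_letters <- setdiff(unique(unname(code$codon_to_aa)), "*")
  if (is.null(protein)) {
    stopifnot(protein_length >= 1)
    protein <- c("M", sample(aa_letters, protein_length - 1L,
                             replace = TRUE))
  } else {
    protein <- strsplit(toupper(protein), "")[[1]]
    stopifnot(all(protein %in% aa_letters))
  }
  residues <- c(protein, "*")
  prev_wobble <- NULL
  codons <- vapply(residues, function(aa) {
    fam <- code$families[[aa]]
    if (length(fam) == 1L) {
      codon <- fam
    } else {
      p <- profile$family_probs[[aa]][fam]
      if (!is.null(profile$wobble_transition) && !is.null(prev_wobble)) {
        p <- p * profile$wobble_transition[prev_wobble, substr(fam, 3L, 3L)]
      }
      codon <- if (sum(p) == 0) sample(fam, 1L) else
        sample(fam, 1L, prob = p)
    }
    prev_wobble <<- substr(codon, 3L, 3L)
    codon
  }, character(1))
  paste0(codons, collapse = "")
}

#' Sample a multi-species synthetic corpus
#'
#' @param profiles Profiles from [make_species_profiles()].
#' @param n_per_species CDS per species.
#' @param protein_length Residues per CDS (see [sample_cds()]).
#' @param seed Integer seed.
#' @param code A [genetic_code()] object.
#' @return A tibble of CDS records (`id`, `species`, `taxon_group`,
#'   `sequence`, `codon_count`).
#' @export
sample_corpus <- function(profiles, n_per_species, protein_length,
                          seed = 1L, code = genetic_code()) {
  withr::with_seed(seed, {
    rows <- purrr::map(profiles, function(pr) {
      tibble::tibble(
        id = sprintf("%s_cds_%04d", pr$species, seq_len(n_per_species)),
        species = pr$species,
        taxon_group = pr$taxon_group,
        sequence = vapply(seq_len(n_per_species), function(i) {
          sample_cds(pr, protein_length, code = code)
        }, character(1))
      )
    })
  })
  as_cds_records(dplyr::bind_rows(rows))
}

#' Synonymous-variant library with codon-determined fitness
#'
#' Generates one random protein and `n_variants` synonymous coding
#' sequences for it, with fitness `y = beta * GC3 + noise`: a declared
#' codon-level signal (the fraction of G/C wobble bases) plus Gaussian
#' noise, so the label depends on the CDS only through codon choice while
#' the protein is held constant. Variants are sampled with diverse GC3 by
#' drawing a per-variant G/C-wobble preference.
#'
#' @param protein_length Number of residues (including the initial
#'   methionine).
#' @param n_variants Number of synonymous variants (>= 2).
#' @param beta Coefficient of the GC3 signal (default 4).
#' @param noise_sd Standard deviation of the Gaussian noise (default 0.1).
#' @param seed Integer seed.
#' @param code A [genetic_code()] object.
#' @return A list of class `variant_library` with `protein` (string),
#'   `data` (tibble: `id`, `sequence`, `gc3`, `fitness`), `beta`,
#'   `noise_sd`.
#' @export
make_variant_library <- function(protein_length, n_variants, beta = 4,
                                 noise_sd = 0.1, seed = 1L,
                                 code = genetic_code()) {
  stopifnot(n_variants >= 2)
  aa_letters <- setdiff(unique(unname(code$codon_to_aa)), "*")
  withr::with_seed(seed, {
    protein <- paste0(c("M", sample(aa_letters, protein_length - 1L,
                                    replace = TRUE)), collapse = "")
    residues <- c(strsplit(protein, "")[[1]], "*")
    seqs <- vapply(seq_len(n_variants), function(i) {
      gc_pref <- stats::runif(1, 0.05, 0.95)
      codons <- vapply(residues, function(aa) {
        fam <- code$families[[aa]]
        if (length(fam) == 1L) return(fam)
        w_gc <- substr(fam, 3L, 3L) %in% c("G", "C")
        p <- ifelse(w_gc, gc_pref, 1 - gc_pref)
        sample(fam, 1L, prob = p)
      }, character(1))
      paste0(codons, collapse = "")
    }, character(1))
    g <- gc3(seqs)
    fitness <- beta * g + stats::rnorm(n_variants, 0, noise_sd)
  })
  structure(
    list(
      protein = protein,
      data = tibble::tibble(
        id = sprintf("variant_%05d", seq_len(n_variants)),
        sequence = seqs, gc3 = g, fitness = fitness
      ),
      beta = beta, noise_sd = noise_sd
    ),
    class = "variant_library"
  )
}

#' Introduce silent mutations at a given level
#'
#' Replaces a fraction `level` of the synonymously degenerate codon
#' positions (families of size >= 2; ATG and TGG cannot change) with a
#' uniformly chosen *different* synonymous codon, so the translation is
#' unchanged and, at level 1, every degenerate codon differs from the
#' original. The number of mutated positions is `round(level * D)` where
#' `D` is the count of degenerate positions, selected uniformly without
#' replacement. Uses the current RNG state.
#'
#' @param cds A valid coding sequence.
#' @param level Mutation level in `[0, 1]`.
#' @param code A [genetic_code()] object.
#' @return The mutated CDS string.
#' @examples
#' set.seed(1)
#' mutate_synonymously("ATGCTGAAATAA", 1)
#' @export
mutate_synonymously <- function(cds, level, code = genetic_code()) {
  stopifnot(level >= 0, level <= 1)
  if (validate_cds(cds, code) != "pass") {
    stop("invalid CDS: ", validate_cds(cds, code), call. = FALSE)
  }
  codons <- split_codons(cds)
  degenerate <- which(code$degeneracy[codons] >= 2L)
  n_mut <- round(level * length(degenerate))
  if (n_mut == 0L) return(toupper(cds))
  at <- degenerate[sample.int(length(degenerate), n_mut)]
  codons[at] <- vapply(codons[at], function(cod) {
    alt <- setdiff(code$families[[code$family_of[[cod]]]], cod)
    if (length(alt) == 1L) alt else sample(alt, 1L)
  }, character(1))
  paste0(codons, collapse = "")
}

#' Demonstration corpus with planted codon-level and protein-level structure
#'
#' Builds the corpus used by the desk-scale training demonstration. Two
#' independent, learnable signals are planted: (i) a first-order
#' amino-acid Markov chain — each residue prefers three successor residues
#' (weight 8 against 1), giving the *unconstrained* masked objective a
#' protein-level signal; and (ii) a first-order wobble-base transition —
#' the wobble base of each codon follows the previous codon's wobble base
#' cyclically (A to C to G to T to A) with probability 0.75 — giving the
#' *synonym-constrained* objective a purely codon-level signal. Within a
#' family, codon choice follows the wobble transition; across positions,
#' residues follow the amino-acid chain.
#'
#' @param n Number of CDS.
#' @param protein_length Residues per CDS (including the initial
#'   methionine; the CDS gains one stop codon).
#' @param seed Integer seed.
#' @param wobble_peak Probability mass on the favoured next wobble base
#'   (default 0.75).
#' @param aa_weight Preference weight for the three favoured successor
#'   residues (default 8, against 1 for the others).
#' @param code A [genetic_code()] object.
#' @return A tibble of CDS records.
#' @export
make_demo_corpus <- function(n, protein_length = 40L, seed = 1L,
                             wobble_peak = 0.75, aa_weight = 8,
                             code = genetic_code()) {
  bases <- c("A", "C", "G", "T")
  wt <- matrix((1 - wobble_peak) / 3, 4L, 4L,
               dimnames = list(bases, bases))
  for (i in 1:4) wt[i, (i %% 4L) + 1L] <- wobble_peak
  aa_letters <- sort(setdiff(unique(unname(code$codon_to_aa)), "*"))
  n_aa <- length(aa_letters)
  aa_t <- matrix(1, n_aa, n_aa, dimnames = list(aa_letters, aa_letters))
  for (i in seq_len(n_aa)) {
    aa_t[i, ((i + 0:2) %% n_aa) + 1L] <- aa_weight
  }
  aa_t <- aa_t / rowSums(aa_t)
  profile <- structure(
    list(species = "demo", taxon_group = "demo",
         family_probs = lapply(
           code$families[vapply(code$families, length, integer(1)) >= 2L],
           function(fam) stats::setNames(rep(1 / length(fam), length(fam)),
                                         fam)),
         wobble_transition = wt),
    class = "species_profile"
  )
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      protein <- character(protein_length)
      protein[1] <- "M"
      for (p in seq_len(protein_length - 1L)) {
        protein[p + 1L] <- sample(aa_letters, 1L, prob = aa_t[protein[p], ])
      }
      sample_cds(profile, protein_length,
                 protein = paste0(protein, collapse = ""), code = code)
    }, character(1))
  })
  as_cds_records(tibble::tibble(
    id = sprintf("demo_%05d", seq_len(n)),
    species = "demo", taxon_group = "demo", sequence = seqs
  ))
}
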