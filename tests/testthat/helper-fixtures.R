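# Shared fixtures: one tokenizer/code/mask per session, plus small
# generators used across test files.

the_code <- genetic_code()
the_tok <- codon_tokenizer()
the_mask <- build_synonym_mask(the_tok, the_code)

NON_STOP_CODONS <- names(the_code$codon_to_aa)[the_code$codon_to_aa != "*"]
STOP_CODONS <- names(the_code$codon_to_aa)[the_code$codon_to_aa == "*"]

# A random valid CDS: ATG + random non-stop codons + one stop codon.
random_cds <- function(n_codons) {
  paste0(c("ATG",
           sample(NON_STOP_CODONS, n_codons - 2L, replace = TRUE),
           sample(STOP_CODONS, 1L)),
         collapse = "")
}

# A toy record tibble for curation tests.
toy_records <- function(seqs, species = "sp1", taxon = "grp1",
                        ids = NULL) {
  tibble::tibble(
    id = ids %||% sprintf("r%03d", seq_along(seqs)),
    species = rep_len(species, length(seqs)),
    taxon_group = rep_len(taxon, length(seqs)),
    sequence = seqs
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny encoder used when a forward pass is needed but size is irrelevant.
tiny_model <- function(seed = 1L, ...) {
  cfg <- encoder_config("desk", hidden_size = 16L,
                        intermediate_size = 32L, num_layers = 2L,
                        num_heads = 2L, relative_position_buckets = 4L,
                        num_token_types = 3L, dropout = 0, ...)
  init_model(cfg, seed = seed)
}
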