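#' Validate coding sequences
#'
#' Applies the three curation rules: only canonical nucleotides (A/C/G/T),
#' length divisible by three, and no internal stop codon (a stop at the
#' final codon index is allowed). Failures are return values, not errors.
#'
#' @param sequence Character vector of candidate coding sequences
#'   (case-insensitive).
#' @param code A [genetic_code()] object (for the stop codons).
#' @return Character vector, one of `"pass"`, `"alphabet"`, `"length"`,
#'   `"internal_stop"` per sequence. Rules are checked in that order.
#' @examples
#' validate_cds(c("ATGGCTTAA", "ATGTAAGCTTAA", "ATGGC", "ATGNCT"))
#' @export
validate_cds <- function(sequence, code = genetic_code()) {
  stops <- names(code$codon_to_aa)[code$codon_to_aa == "*"]
  vapply(toupper(sequence), function(s) {
    if (nchar(s) == 0L || grepl("[^ACGT]", s)) return("alphabet")
    if (nchar(s) %% 3L != 0L) return("length")
    cods <- split_codons(s)
    if (length(cods) > 1L && any(cods[-length(cods)] %in% stops)) {
      return("internal_stop")
    }
    "pass"
  }, character(1), USE.NAMES = FALSE)
}

as_cds_records <- function(records) {
  records <- tibble::as_tibble(records)
  needed <- c("id", "species", "taxon_group", "sequence")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0L) {
    stop("records must have columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  records$sequence <- toupper(records$sequence)
  records$codon_count <- nchar(records$sequence) %/% 3L
  records
}

#' Remove exact duplicate sequences within each species
#'
#' For each (species, exact sequence) pair exactly one record is retained —
#' the first occurrence in input order. Identical sequences in different
#' species are all kept: the rule is scoped within species.
#'
#' @param records A data frame with columns `id`, `species`, `taxon_group`,
#'   `sequence`.
#' @return A tibble of retained records (plus a `codon_count` column).
#' @export
dedupe_within_species <- function(records) {
  records <- as_cds_records(records)
  records[!duplicated(records[c("species", "sequence")]), ]
}

#' Stratify a corpus so no taxon group exceeds a reference group's codons
#'
#' Caps every taxon group's total codon count at the reference group's
#' total by randomly removing whole records (seeded, uniform, without
#' replacement) from over-cap groups until their total is at or below the
#' cap. The reference group and groups already under the cap are unchanged.
#' Records are never truncated.
#'
#' @param records A data frame of CDS records (see
#'   [dedupe_within_species()]).
#' @param reference_group The taxon group whose codon total is the cap
#'   (e.g. mammalian vertebrates).
#' @param seed Integer seed for the record subsampling.
#' @return A tibble of retained records.
#' @export
stratify_by_codons <- function(records, reference_group, seed = 1L) {
  records <- as_cds_records(records)
  if (!reference_group %in% records$taxon_group) {
    stop("reference group '", reference_group, "' not present",
         call. = FALSE)
  }
  totals <- tapply(records$codon_count, records$taxon_group, sum)
  cap <- totals[[reference_group]]
  keep <- rep(TRUE, nrow(records))
  withr::with_seed(seed, {
    for (grp in names(totals)[totals > cap]) {
      idx <- which(records$taxon_group == grp)
      idx <- sample(idx) # random removal order
      running <- cumsum(records$codon_count[idx])
      # drop from the end of the shuffled order until the group fits
      n_keep <- findInterval(cap, running)
      keep[idx[seq_along(idx) > n_keep]] <- FALSE
    }
  })
  records[keep, ]
}

#' Split records into training and test sets
#'
#' Seeded random partition; the train size is `round(n * train_fraction)`
#' (round-half-even). The partition is disjoint and exhaustive.
#'
#' @param records A data frame of CDS records.
#' @param train_fraction Fraction of records assigned to training
#'   (default 0.98).
#' @param seed Integer seed for the shuffle.
#' @return A list with tibbles `train` and `test`.
#' @export
split_train_test <- function(records, train_fraction = 0.98, seed = 1L) {
  records <- as_cds_records(records)
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 records to split", call. = FALSE)
  n_train <- round(n * train_fraction)
  perm <- withr::with_seed(seed, sample.int(n))
  list(
    train = records[sort(perm[seq_len(n_train)]), ],
    test = records[sort(perm[seq_len(n - n_train) + n_train]), ]
  )
}

#' Curate a CDS corpus end to end
#'
#' Runs the curation pipeline: validation, per-species exact-duplicate
#' removal, optional taxon stratification against a reference group, and a
#' train/test split, returning the retained records together with a
#' curation report. Similarity clustering (e.g. MMSeqs2 at 90 percent
#' nucleotide identity / 80 percent coverage, `mmseqs easy-cluster seqs.fasta
#' res tmp --min-seq-id 0.9 -c 0.8`) is an upstream, external step: pass its
#' representatives in as `records`.
#'
#' @param records A data frame with columns `id`, `species`, `taxon_group`,
#'   `sequence`.
#' @param reference_group Optional taxon group capping codon totals; `NULL`
#'   skips stratification.
#' @param train_fraction Fraction of records for training (default 0.98).
#' @param seed Integer seed used for stratification and splitting.
#' @param code A [genetic_code()] for validation.
#' @return A list with elements `train`, `test` (tibbles) and `report` (a
#'   list of per-rule rejection counts, retained count, and per-group codon
#'   totals before/after stratification). `retained + sum(rejected)` equals
#'   the input count.
#' @export
curate_cds <- function(records, reference_group = NULL,
                       train_fraction = 0.98, seed = 1L,
                       code = genetic_code()) {
  records <- as_cds_records(records)
  n_in <- nrow(records)
  verdict <- validate_cds(records$sequence, code)
  rejected <- c(
    alphabet = sum(verdict == "alphabet"),
    length = sum(verdict == "length"),
    internal_stop = sum(verdict == "internal_stop")
  )
  records <- records[verdict == "pass", ]
  n_valid <- nrow(records)
  records <- dedupe_within_species(records)
  rejected["duplicate"] <- n_valid - nrow(records)
  totals_before <- as.list(tapply(records$codon_count, records$taxon_group,
                                  sum))
  if (!is.null(reference_group)) {
    records <- stratify_by_codons(records, reference_group, seed = seed)
  }
  rejected["stratified"] <- n_in - sum(rejected) - nrow(records)
  totals_after <- as.list(tapply(records$codon_count, records$taxon_group,
                                 sum))
  split <- split_train_test(records, train_fraction, seed = seed)
  report <- list(
    input = n_in,
    rejected = as.list(rejected),
    retained = nrow(records),
    codon_totals_before = totals_before,
    codon_totals_after = totals_after
  )
  c(split, list(report = report))
}
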