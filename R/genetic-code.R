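#' The genetic code and its synonymous-codon families
#'
#' Builds a genetic-code object from an NCBI translation table: the
#' codon-to-amino-acid map over the 64 DNA codons, the partition of codons
#' into synonymous families, and the per-codon degeneracy (family size).
#' Stop codons are treated as one synonymous family (symbol `"*"`), so under
#' the standard code the family-size multiset is one 1, one 1 (Met, Trp),
#' nine 2s, one 3 (Ile), one 3 (stops), five 4s and three 6s, summing to 64.
#'
#' @param table_id NCBI genetic-code table identifier as a string
#'   (default `"1"`, the standard code). Passed to
#'   [Biostrings::getGeneticCode()].
#' @param split_boxes If `TRUE`, families are additionally split by codon
#'   prefix (first two bases), so e.g. the six serine codons separate into
#'   the `TC*` box and the `AG*` pair. The default (`FALSE`) uses full
#'   amino-acid families.
#' @return An object of class `genetic_code`: a list with elements
#'   `codon_to_aa` (named character of length 64), `families` (named list of
#'   character vectors keyed by family label), `family_of` (named character:
#'   codon to family label), and `degeneracy` (named integer of length 64).
#' @examples
#' code <- genetic_code()
#' code$codon_to_aa[["ATG"]]
#' sort(code$families[["S"]])
#' @export
genetic_code <- function(table_id = "1", split_boxes = FALSE) {
  map <- Biostrings::getGeneticCode(table_id)
  map <- map[order(names(map))]
  stopifnot(length(map) == 64L)
  fam_label <- unname(map)
  if (split_boxes) {
    fam_label <- paste0(fam_label, ":", substr(names(map), 1L, 2L))
    # collapse boxes that are alone in their amino acid back to the aa label
  }
  families <- split(names(map), fam_label)
  family_of <- stats::setNames(fam_label, names(map))
  degeneracy <- stats::setNames(
    vapply(family_of, function(f) length(families[[f]]), integer(1)),
    names(map)
  )
  structure(
    list(
      table_id = table_id,
      split_boxes = split_boxes,
      codon_to_aa = map,
      families = families,
      family_of = family_of,
      degeneracy = degeneracy
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code> NCBI table ", x$table_id,
      if (x$split_boxes) " (split boxes)", "\n", sep = "")
  cat("  64 codons, ", length(x$families), " synonymous families\n", sep = "")
  invisible(x)
}

ALL_CODONS <- sort(apply(expand.grid(c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T")), 1L, paste0,
                         collapse = ""))

normalize_codon <- function(codon) {
  codon <- toupper(codon)
  bad <- nchar(codon) != 3L | grepl("[^ACGT]", codon)
  if (any(bad)) {
    stop("invalid codon: ", paste(unique(codon[bad]), collapse = ", "),
         " (need 3 characters over A/C/G/T)", call. = FALSE)
  }
  codon
}

#' Translate a codon to its amino-acid symbol
#'
#' @param codon Character vector of 3-letter DNA codons (case-insensitive).
#' @param code A [genetic_code()] object.
#' @return Character vector of 1-letter amino-acid symbols; stop codons give
#'   `"*"`.
#' @examples
#' translate_codon(c("ATG", "TGG", "TAA"))
#' @export
translate_codon <- function(codon, code = genetic_code()) {
  unname(code$codon_to_aa[normalize_codon(codon)])
}

#' Synonymous family of a codon
#'
#' Returns the full set of codons encoding the same amino acid (or stop) as
#' `codon`, always including `codon` itself.
#'
#' @inheritParams translate_codon
#' @return Character vector of codons.
#' @examples
#' synonymous_set("AGT") # the six serine codons
#' synonymous_set("ATG") # singleton
#' @export
synonymous_set <- function(codon, code = genetic_code()) {
  codon <- normalize_codon(codon)
  stopifnot(length(codon) == 1L)
  code$families[[code$family_of[[codon]]]]
}

#' Positional codon features: wobble base and suffix dinucleotide
#'
#' The wobble base is the third nucleotide of the codon (where most
#' synonymous variation occurs); the suffix dinucleotide is positions 2-3.
#'
#' @inheritParams translate_codon
#' @return A tibble with columns `codon`, `wobble`, `suffix`.
#' @examples
#' codon_features("AGT")
#' @export
codon_features <- function(codon) {
  codon <- normalize_codon(codon)
  tibble::tibble(
    codon = codon,
    wobble = substr(codon, 3L, 3L),
    suffix = substr(codon, 2L, 3L)
  )
}

#' Fraction of codons with a G or C wobble base
#'
#' GC3 of a coding sequence: the fraction of its codons whose third base is
#' G or C.
#'
#' @param cds Character vector of coding sequences (length divisible by 3).
#' @return Numeric vector of GC3 values in `[0, 1]`.
#' @export
gc3 <- function(cds) {
  vapply(cds, function(s) {
    cods <- split_codons(s)
    mean(substr(cods, 3L, 3L) %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

split_codons <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3", call. = FALSE)
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Write a genetic code as a two-column TSV
#'
#' @param code A [genetic_code()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genetic_code_tsv <- function(code, path) {
  utils::write.table(
    data.frame(codon = names(code$codon_to_aa),
               amino_acid = unname(code$codon_to_aa)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
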