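#' Codon counts for a set of CDS records
#'
#' Counts every codon occurrence across the given records (typically all
#' records of one species). Counts sum to the total number of codons.
#'
#' @param records A data frame of CDS records, or a character vector of
#'   sequences.
#' @return Named integer vector of length 64 (all codons, lexicographic).
#' @export
codon_counts <- function(records) {
  seqs <- if (is.data.frame(records)) records$sequence else records
  if (length(seqs) == 0L) stop("no records to count", call. = FALSE)
  cods <- unlist(lapply(seqs, split_codons), use.names = FALSE)
  counts <- table(factor(cods, levels = ALL_CODONS))
  stats::setNames(as.integer(counts), ALL_CODONS)
}

#' Relative synonymous codon usage (RSCU) vector
#'
#' For codon `j` in a synonymous family of size `n_i` with family total
#' `T_i`, `RSCU = n_i * X_ij / T_i`: the observed count divided by the
#' count expected under uniform use of the family. Families with zero
#' counts get the neutral value 1 for every member. Single-codon families
#' and the stop family are excluded, leaving 59 values under the standard
#' code.
#'
#' @param counts Named numeric vector of 64 codon counts (as from
#'   [codon_counts()]).
#' @param code A [genetic_code()] object.
#' @return Named numeric vector of RSCU values (length 59 under the
#'   standard code) with attribute `total_codons`.
#' @examples
#' counts <- codon_counts("ATGCTGCTG")
#' rscu_vector(counts)[["CTG"]] # all leucines on CTG: RSCU = 6
#' @export
rscu_vector <- function(counts, code = genetic_code()) {
  stopifnot(setequal(names(counts), ALL_CODONS))
  if (any(counts < 0)) stop("negative codon counts", call. = FALSE)
  counts <- counts[ALL_CODONS]
  keep_fams <- code$families[
    vapply(code$families, length, integer(1)) >= 2L &
      names(code$families) != "*"
  ]
  out <- unlist(lapply(keep_fams, function(fam) {
    x <- counts[fam]
    total <- sum(x)
    if (total == 0) rep(1, length(fam)) else length(fam) * x / total
  }), use.names = FALSE)
  names(out) <- unlist(keep_fams, use.names = FALSE)
  out <- out[order(names(out))]
  attr(out, "total_codons") <- sum(counts)
  out
}

#' Per-species RSCU table
#'
#' Computes one RSCU vector per species from a record table.
#'
#' @param records A data frame of CDS records with `species` and
#'   `taxon_group` columns.
#' @param code A [genetic_code()] object.
#' @return A tibble with columns `species`, `taxon_group`, `total_codons`,
#'   and one column per RSCU codon (59 under the standard code).
#' @export
rscu_table <- function(records, code = genetic_code()) {
  records <- as_cds_records(records)
  dplyr::group_by(records, .data$species, .data$taxon_group) |>
    dplyr::group_modify(function(df, key) {
      v <- rscu_vector(codon_counts(df), code)
      tibble::as_tibble_row(c(list(total_codons = attr(v, "total_codons")),
                              as.list(v)))
    }) |>
    dplyr::ungroup()
}

#' Allocate cluster token-type IDs across taxa
#'
#' Divides a budget of cluster IDs among taxon groups proportionally to
#' their CDS counts using the largest-remainder method, with every taxon
#' guaranteed at least one ID. Allocations always sum to the budget and
#' are invariant to rescaling all counts by a constant.
#'
#' @param cds_counts Named numeric vector: CDS count per taxon group.
#' @param total_cluster_ids Number of cluster IDs to allocate (default 500;
#'   one further ID is conventionally reserved as "unknown", giving the 501
#'   token-type IDs of the full model).
#' @return Named integer vector of per-taxon cluster counts `k`.
#' @examples
#' allocate_type_ids(c(A = 900, B = 100), 500)
#' @export
allocate_type_ids <- function(cds_counts, total_cluster_ids = 500L) {
  stopifnot(all(cds_counts > 0))
  n_taxa <- length(cds_counts)
  if (n_taxa > total_cluster_ids) {
    stop("more taxa (", n_taxa, ") than cluster ids (", total_cluster_ids,
         ")", call. = FALSE)
  }
  quota <- cds_counts / sum(cds_counts) * total_cluster_ids
  k <- floor(quota)
  remainder <- total_cluster_ids - sum(k)
  if (remainder > 0) {
    top <- order(quota - k, decreasing = TRUE)[seq_len(remainder)]
    k[top] <- k[top] + 1
  }
  # floor rule: every taxon gets at least one id, taken from the largest
  while (any(k == 0)) {
    k[which.max(k)] <- k[which.max(k)] - 1
    k[which(k == 0)[1]] <- 1
  }
  stats::setNames(as.integer(k), names(cds_counts))
}

#' Cluster species by RSCU into token-type IDs
#'
#' Within each taxon group, species are clustered by k-means on their RSCU
#' vectors (Euclidean distance on the raw values — RSCU is already
#' family-normalized — with 10 random restarts). Cluster labels are turned
#' into globally unique token-type IDs, dense `0..total_ids-1`, with the
#' last ID reserved as "unknown" for species unseen at lookup time.
#'
#' @param rscu A tibble from [rscu_table()].
#' @param k_per_taxon Named integer vector of cluster counts per taxon
#'   (e.g. from [allocate_type_ids()]). A taxon with fewer species than its
#'   `k` is reduced to its species count (with a message).
#' @param seed Integer seed for the k-means restarts.
#' @return An object of class `species_type_model`: list with
#'   `assignments` (tibble: species, taxon_group, type_id), `centroids`
#'   (named list of per-taxon centroid matrices), `unknown_id`,
#'   `total_ids`.
#' @export
cluster_species <- function(rscu, k_per_taxon, seed = 1L) {
  if (nrow(rscu) == 0L) stop("empty RSCU table", call. = FALSE)
  taxa <- sort(unique(rscu$taxon_group))
  stopifnot(all(taxa %in% names(k_per_taxon)))
  feature_cols <- setdiff(names(rscu),
                          c("species", "taxon_group", "total_codons"))
  next_id <- 0L
  assignments <- list()
  centroids <- list()
  withr::with_seed(seed, {
    for (tx in taxa) {
      sub <- rscu[rscu$taxon_group == tx, ]
      x <- as.matrix(sub[feature_cols])
      k <- k_per_taxon[[tx]]
      row_key <- apply(x, 1L, paste, collapse = "\r")
      n_distinct <- length(unique(row_key))
      if (k > n_distinct) {
        message("taxon ", tx, ": k reduced from ", k, " to ", n_distinct)
        k <- n_distinct
      }
      if (k == 1L) {
        cl <- rep(1L, nrow(x))
        centers <- matrix(colMeans(x), 1L,
                          dimnames = list(NULL, feature_cols))
      } else if (k == n_distinct) {
        # one cluster per distinct profile: the exact k-means optimum
        cl <- match(row_key, unique(row_key))
        centers <- x[!duplicated(row_key), , drop = FALSE]
        rownames(centers) <- NULL
      } else {
        km <- stats::kmeans(x, centers = k, nstart = 10L, iter.max = 100L)
        cl <- km$cluster
        centers <- km$centers
      }
      assignments[[tx]] <- tibble::tibble(
        species = sub$species,
        taxon_group = tx,
        type_id = next_id + cl - 1L
      )
      rownames(centers) <- as.character(next_id + seq_len(nrow(centers)) - 1L)
      centroids[[tx]] <- centers
      next_id <- next_id + k
    }
  })
  structure(
    list(
      assignments = dplyr::bind_rows(assignments),
      centroids = centroids,
      unknown_id = next_id,
      total_ids = next_id + 1L
    ),
    class = "species_type_model"
  )
}

#' @export
print.species_type_model <- function(x, ...) {
  cat("<species_type_model> ", nrow(x$assignments), " species, ",
      x$total_ids, " token-type ids (unknown id = ", x$unknown_id, ")\n",
      sep = "")
  invisible(x)
}

#' Look up the token-type ID for species
#'
#' Species not seen during clustering receive the reserved unknown ID, so
#' the model can be used without species-specific context.
#'
#' @param model A [cluster_species()] result.
#' @param species Character vector of species names.
#' @return Integer vector of token-type IDs.
#' @export
species_type_id <- function(model, species) {
  idx <- match(species, model$assignments$species)
  ifelse(is.na(idx), model$unknown_id, model$assignments$type_id[idx])
}

#' Project token-type embeddings to two dimensions by PCA
#'
#' @param embeddings Numeric matrix, one row per token-type ID.
#' @return A tibble with columns `id`, `PC1`, `PC2` and attribute
#'   `variance_explained`.
#' @export
project_type_embeddings <- function(embeddings) {
  if (nrow(embeddings) < 3L) stop("need at least 3 rows", call. = FALSE)
  pc <- stats::prcomp(embeddings, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  if (ncol(scores) < 2L) scores <- cbind(scores, 0)
  out <- tibble::tibble(
    id = if (!is.null(rownames(embeddings))) rownames(embeddings)
         else as.character(seq_len(nrow(embeddings)) - 1L),
    PC1 = scores[, 1L],
    PC2 = scores[, 2L]
  )
  attr(out, "variance_explained") <- pc$sdev^2 / sum(pc$sdev^2)
  out
}
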