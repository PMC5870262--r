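# Core containers: the genotype dataset (SNP x individual matrix plus
# metadata and a binary phenotype) and the cluster map (ordered partition
# of SNP indices) that drives meta-node splits.

#' Construct a case-control genotype dataset
#'
#' The universal input of the package: an `n_snps x n_individuals`
#' genotype matrix coded as minor-allele counts 0/1/2 (`NA` = missing),
#' SNP metadata, and a binary case/control phenotype.  SNPs are sorted by
#' (chromosome, position) on construction.
#'
#' @param snps `data.frame` with columns `snp_id` (unique strings),
#'   `chromosome` (string labels) and `position_bp` (integer, 1-based).
#' @param genotypes Integer matrix, one row per SNP, one column per
#'   individual, entries in `{0, 1, 2, NA}`.
#' @param phenotype Character vector of `"case"` / `"control"`, one per
#'   individual.
#' @param individual_ids Optional individual identifiers (default
#'   `ind1..indp`).
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(snps, genotypes, phenotype,
                             individual_ids = NULL) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  required <- c("snp_id", "chromosome", "position_bp")
  if (!all(required %in% names(snps)))
    stop("snps must have columns snp_id, chromosome, position_bp")
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) != nrow(snps))
    stop("genotype matrix rows (", nrow(genotypes), ") != number of SNPs (",
         nrow(snps), ")")
  if (ncol(genotypes) != length(phenotype))
    stop("genotype matrix columns (", ncol(genotypes),
         ") != phenotype length (", length(phenotype), ")")
  if (anyDuplicated(snps$snp_id)) stop("duplicated snp_id in dataset")
  if (any(snps$position_bp < 1)) stop("position_bp must be >= 1")
  bad <- !(genotypes %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("genotype entries must be 0, 1, 2 or NA")
  phenotype <- as.character(phenotype)
  if (!all(phenotype %in% c("case", "control")))
    stop("phenotype must be binary 'case'/'control'")
  if (is.null(individual_ids))
    individual_ids <- paste0("ind", seq_along(phenotype))
  individual_ids <- as.character(individual_ids)
  if (length(individual_ids) != length(phenotype))
    stop("individual_ids length mismatch")
  ord <- order(snps$chromosome, snps$position_bp)
  snps <- snps[ord, , drop = FALSE]
  rownames(snps) <- NULL
  genotypes <- genotypes[ord, , drop = FALSE]
  dimnames(genotypes) <- NULL
  structure(list(snps = snps, genotypes = genotypes,
                 phenotype = phenotype, individual_ids = individual_ids),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$snps), "SNPs x",
      length(x$phenotype), "individuals (",
      sum(x$phenotype == "case"), "cases /",
      sum(x$phenotype == "control"), "controls )\n")
  miss <- mean(is.na(x$genotypes))
  cat("  chromosomes:", paste(unique(x$snps$chromosome), collapse = ", "),
      sprintf("| missingness: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of SNPs / individuals in a dataset
#' @param ds A `genotype_dataset`.
#' @return An integer count.
#' @export
n_snps <- function(ds) nrow(ds$snps)

#' @rdname n_snps
#' @export
n_individuals <- function(ds) length(ds$phenotype)

is_case <- function(ds) ds$phenotype == "case"

#' Construct a cluster map
#'
#' An ordered partition of the SNP indices `1..n_snps` into non-empty,
#' pairwise-disjoint clusters.  Contiguous blocks give the classical
#' block map; FLTM layer-1 child sets give the LD map of the hybrid
#' approach.
#'
#' @param clusters List of integer vectors of 1-based SNP indices.
#' @param n_snps Total number of SNPs the map must cover.
#' @param provenance `"contiguous_blocks"` or `"fltm_layer1"`.
#' @return An object of class `cluster_map`.
#' @export
cluster_map <- function(clusters, n_snps,
                        provenance = c("contiguous_blocks", "fltm_layer1")) {
  provenance <- match.arg(provenance)
  clusters <- unname(lapply(clusters, function(x) as.integer(unname(x))))
  if (any(vapply(clusters, length, 1L) == 0L)) stop("empty cluster not allowed")
  all_idx <- sort(as.integer(unname(unlist(clusters))))
  if (anyDuplicated(all_idx))
    stop("overlapping clusters: a SNP index appears more than once")
  if (!identical(all_idx, seq_len(n_snps)))
    stop("clusters must partition 1..", n_snps,
         " (missing or out-of-range SNP index)")
  structure(list(clusters = clusters, n_snps = as.integer(n_snps),
                 provenance = provenance),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  sizes <- vapply(x$clusters, length, 1L)
  cat("cluster_map (", x$provenance, "): ", length(x$clusters),
      " clusters over ", x$n_snps, " SNPs; sizes ",
      min(sizes), "-", max(sizes),
      " (median ", stats::median(sizes), ")\n", sep = "")
  invisible(x)
}
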