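# Readers/writers for genotype datasets (matrix TSV and PLINK text),
# cluster maps, and ranking tables.
#
# Matrix TSV dialect:
#   line 1: snp_id <TAB> chromosome <TAB> position <TAB> ind ids...
#   line 2: #phenotype <TAB> . <TAB> . <TAB> case|control ...
#   data  : one row per SNP, genotype codes 0/1/2, -1 = missing.

MISSING_TOKEN <- "-1"

#' Read a genotype dataset
#'
#' @param path For `matrix_tsv`, path to the TSV file.  For `plink_text`,
#'   the path to the `.ped` file or the common prefix of the `.ped`/`.map`
#'   pair.
#' @param format `"matrix_tsv"` or `"plink_text"`.
#' @return A [genotype_dataset()].
#' @export
read_dataset <- function(path, format = c("matrix_tsv", "plink_text")) {
  format <- match.arg(format)
  switch(format,
         matrix_tsv = read_matrix_tsv(path),
         plink_text = read_plink_text(path))
}

#' Write a genotype dataset
#'
#' @param ds A [genotype_dataset()].
#' @inheritParams read_dataset
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(ds, path, format = c("matrix_tsv", "plink_text")) {
  format <- match.arg(format)
  stopifnot(inherits(ds, "genotype_dataset"))
  if (n_individuals(ds) == 0L) stop("refusing to write a dataset with no individuals")
  switch(format,
         matrix_tsv = write_matrix_tsv(ds, path),
         plink_text = write_plink_text(ds, path))
  invisible(path)
}

read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 3L) stop("matrix TSV needs a header, a phenotype row and >=1 SNP row")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 4L || header[1L] != "snp_id")
    stop("line 1: malformed header (expected snp_id\\tchromosome\\tposition\\tids...)")
  ind_ids <- header[-(1:3)]
  ph_row <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  if (ph_row[1L] != "#phenotype" || length(ph_row) != length(header))
    stop("line 2: malformed phenotype row")
  phenotype <- ph_row[-(1:3)]
  if (!all(phenotype %in% c("case", "control")))
    stop("line 2: phenotype not binary case/control")
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  p <- length(ind_ids)
  snp_id <- character(length(body)); chrom <- character(length(body))
  pos <- integer(length(body))
  geno <- matrix(NA_integer_, length(body), p)
  for (i in seq_along(body)) {
    f <- body[[i]]
    line_no <- i + 2L
    if (length(f) != p + 3L)
      stop("line ", line_no, ": expected ", p + 3L, " fields, found ", length(f))
    snp_id[i] <- f[1L]; chrom[i] <- f[2L]
    pos_i <- suppressWarnings(as.integer(f[3L]))
    if (is.na(pos_i) || pos_i < 1L) stop("line ", line_no, ": invalid position '", f[3L], "'")
    pos[i] <- pos_i
    g <- f[-(1:3)]
    bad <- !(g %in% c("0", "1", "2", MISSING_TOKEN))
    if (any(bad))
      stop("line ", line_no, ": invalid genotype code '", g[which(bad)[1L]], "'")
    gi <- as.integer(g)
    gi[gi == -1L] <- NA_integer_
    geno[i, ] <- gi
  }
  if (anyDuplicated(snp_id))
    stop("duplicated snp_id: ", snp_id[anyDuplicated(snp_id)])
  genotype_dataset(data.frame(snp_id = snp_id, chromosome = chrom,
                              position_bp = pos, stringsAsFactors = FALSE),
                   geno, phenotype, ind_ids)
}

write_matrix_tsv <- function(ds, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("snp_id", "chromosome", "position", ds$individual_ids),
                   collapse = "\t"), con)
  writeLines(paste(c("#phenotype", ".", ".", ds$phenotype), collapse = "\t"), con)
  g <- ds$genotypes
  g[is.na(g)] <- -1L
  rows <- paste(ds$snps$snp_id, ds$snps$chromosome, ds$snps$position_bp,
                apply(g, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(rows, con)
}

plink_paths <- function(path) {
  prefix <- sub("\\.(ped|map)$", "", path)
  list(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map"))
}

read_plink_text <- function(path) {
  pp <- plink_paths(path)
  if (!file.exists(pp$ped)) stop("file not found: ", pp$ped)
  if (!file.exists(pp$map)) stop("file not found: ", pp$map)
  map <- read.table(pp$map, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 4L) stop("malformed .map: expected 4 columns")
  names(map)[1:4] <- c("chromosome", "snp_id", "cm", "position_bp")
  n <- nrow(map)
  ped_lines <- readLines(pp$ped)
  fields <- strsplit(trimws(ped_lines), "[ \t]+")
  p <- length(fields)
  phenotype <- character(p); ind_ids <- character(p)
  a1 <- matrix("", n, p); a2 <- matrix("", n, p)
  for (j in seq_len(p)) {
    f <- fields[[j]]
    if (length(f) != 6L + 2L * n)
      stop("line ", j, ": .ped row has ", length(f), " fields, expected ", 6L + 2L * n)
    ind_ids[j] <- f[2L]
    phenotype[j] <- switch(f[6L], "2" = "case", "1" = "control",
                           stop("line ", j, ": phenotype not binary (1/2): '", f[6L], "'"))
    al <- f[-(1:6)]
    a1[, j] <- al[seq(1L, by = 2L, length.out = n)]
    a2[, j] <- al[seq(2L, by = 2L, length.out = n)]
  }
  geno <- matrix(NA_integer_, n, p)
  for (i in seq_len(n)) {
    obs <- a1[i, ] != "0" & a2[i, ] != "0"
    alleles <- sort(unique(c(a1[i, obs], a2[i, obs])))
    if (length(alleles) > 2L)
      stop("SNP ", map$snp_id[i], ": more than two alleles observed")
    if (length(alleles) == 0L) next  # all missing; QC will reject later
    counts <- vapply(alleles,
                     function(a) sum(a1[i, obs] == a) + sum(a2[i, obs] == a), 1L)
    # minor allele = least frequent; ties by lexicographic order
    minor <- alleles[order(counts, alleles)][1L]
    geno[i, obs] <- (a1[i, obs] == minor) + (a2[i, obs] == minor)
  }
  if (anyDuplicated(map$snp_id)) stop("duplicated snp_id in .map")
  genotype_dataset(map[, c("snp_id", "chromosome", "position_bp")],
                   geno, phenotype, ind_ids)
}

write_plink_text <- function(ds, path) {
  pp <- plink_paths(path)
  map <- data.frame(ds$snps$chromosome, ds$snps$snp_id, 0L, ds$snps$position_bp)
  write.table(map, pp$map, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  # genotype g = count of allele "A" (written as the minor allele)
  g <- ds$genotypes
  first <- c("B", "A", "A")  # index by g + 1
  second <- c("B", "B", "A")
  p <- n_individuals(ds)
  con <- file(pp$ped, open = "wt")
  on.exit(close(con))
  for (j in seq_len(p)) {
    gj <- g[, j]
    aj1 <- ifelse(is.na(gj), "0", first[gj + 1L])
    aj2 <- ifelse(is.na(gj), "0", second[gj + 1L])
    writeLines(paste(c("FAM", ds$individual_ids[j], "0", "0", "0",
                       if (ds$phenotype[j] == "case") "2" else "1",
                       as.vector(rbind(aj1, aj2))), collapse = " "), con)
  }
}

#' Read / write a cluster map
#'
#' Cluster-map TSV: header `cluster_index  snp_index  snp_id`, 1-based
#' indices.  On read the partition invariant (every SNP index exactly
#' once) is enforced.
#'
#' @param path File path.
#' @param n_snps Expected number of SNPs; defaults to the maximum index
#'   present.
#' @param provenance Stored provenance for the map read back.
#' @return A [cluster_map()] (for the reader).
#' @export
read_cluster_map <- function(path, n_snps = NULL,
                             provenance = c("contiguous_blocks", "fltm_layer1")) {
  provenance <- match.arg(provenance)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("cluster_index", "snp_index") %in% names(tab)))
    stop("cluster map must have columns cluster_index, snp_index")
  if (is.null(n_snps)) n_snps <- max(tab$snp_index)
  clusters <- split(as.integer(tab$snp_index), tab$cluster_index)
  clusters <- clusters[order(as.integer(names(clusters)))]
  names(clusters) <- NULL
  cluster_map(clusters, n_snps = n_snps, provenance = provenance)
}

#' @rdname read_cluster_map
#' @param map A [cluster_map()] to serialize.
#' @param snp_ids Optional SNP identifiers (length `n_snps`) written in
#'   the `snp_id` column; defaults to `snp<index>`.
#' @export
write_cluster_map <- function(map, path, snp_ids = NULL) {
  stopifnot(inherits(map, "cluster_map"))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(map$n_snps))
  rows <- do.call(rbind, lapply(seq_along(map$clusters), function(ci) {
    data.frame(cluster_index = ci, snp_index = map$clusters[[ci]])
  }))
  rows$snp_id <- snp_ids[rows$snp_index]
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-SNP score table (importance or association ranking)
#'
#' @param snp_id,score,rank Parallel vectors.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_ranking <- function(snp_id, score, rank, path) {
  write.table(data.frame(snp_id = snp_id, score = score, rank = rank),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
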