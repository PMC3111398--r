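#' @name genotype_io
#' @title Reading and writing genotype tables, HLA typings and trained models
#'
#' @description
#' Two text dialects are read for SNP genotypes: a tab-delimited matrix
#' (samples x SNPs allele counts with a companion `.snps` metadata file) and
#' the PLINK-style `ped`/`map` pair. Genotype calls count copies of
#' `allele_b` (the second listed allele); the counted allele is recorded per
#' SNP so that cross-platform inputs can be orientation-harmonized
#' explicitly rather than silently. Trained haplotype models round-trip
#' through a versioned, human-readable text format.
NULL

#' Construct a genotype table
#'
#' @param calls integer matrix, samples x SNPs, entries in `{0,1,2,NA}`
#'   counting copies of each SNP's `allele_b`.
#' @param snps data frame with columns `snp_id`, `chrom`, `position`,
#'   `allele_a`, `allele_b`; one row per column of `calls`.
#' @param sample_ids character vector, one per row of `calls`; defaults to
#'   `rownames(calls)`.
#' @param sort_by_position reorder SNPs by genomic position (default).
#' @return An object of class `genotype_table` with elements `calls` and
#'   `snps`.
#' @export
genotype_table <- function(calls, snps, sample_ids = rownames(calls),
                           sort_by_position = TRUE) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "position", "allele_a", "allele_b")
  if (!all(need %in% names(snps)))
    stop_hla("snps must have columns: ", paste(need, collapse = ", "))
  snps$snp_id <- as.character(snps$snp_id)
  snps$chrom <- as.character(snps$chrom)
  snps$position <- as.integer(snps$position)
  snps$allele_a <- as.character(snps$allele_a)
  snps$allele_b <- as.character(snps$allele_b)
  if (ncol(calls) != nrow(snps))
    stop_hla("calls has ", ncol(calls), " columns but snps has ",
             nrow(snps), " rows")
  if (anyDuplicated(snps$snp_id))
    stop_hla("duplicate snp_id: ",
             paste(unique(snps$snp_id[duplicated(snps$snp_id)]), collapse = ", "))
  if (any(snps$position <= 0, na.rm = TRUE))
    stop_hla("SNP positions must be positive (1-based)")
  bad_al <- snps$allele_a == snps$allele_b
  if (any(bad_al))
    stop_hla("allele_a equals allele_b for: ",
             paste(snps$snp_id[bad_al], collapse = ", "))
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%04d", seq_len(nrow(calls)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(calls))
    stop_hla("sample_ids length does not match calls rows")
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2))
    stop_hla("genotype calls must be 0, 1, 2 or NA")
  if (sort_by_position) {
    ord <- order(snps$position, snps$snp_id)
    snps <- snps[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
  }
  rownames(snps) <- NULL
  dimnames(calls) <- list(sample_ids, snps$snp_id)
  structure(list(calls = calls, snps = snps), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table: ", nrow(x$calls), " samples x ", ncol(x$calls),
      " SNPs (", sum(is.na(x$calls)), " missing calls)\n", sep = "")
  invisible(x)
}

#' Number of samples / SNPs in a table
#' @param gt a `genotype_table`.
#' @export
n_samples <- function(gt) nrow(gt$calls)

#' @rdname n_samples
#' @export
n_snps <- function(gt) ncol(gt$calls)

#' Subset a genotype table
#'
#' @param gt a `genotype_table`.
#' @param samples,snps character vectors of sample ids / snp ids (or `NULL`).
#' @export
subset_genotypes <- function(gt, samples = NULL, snps = NULL) {
  calls <- gt$calls
  meta <- gt$snps
  if (!is.null(samples)) {
    miss <- setdiff(samples, rownames(calls))
    if (length(miss)) stop_hla("unknown sample ids: ", paste(miss, collapse = ", "))
    calls <- calls[samples, , drop = FALSE]
  }
  if (!is.null(snps)) {
    miss <- setdiff(snps, meta$snp_id)
    if (length(miss)) stop_hla("unknown snp ids: ", paste(miss, collapse = ", "))
    keep <- meta$snp_id %in% snps
    calls <- calls[, keep, drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  }
  genotype_table(calls, meta, rownames(calls))
}

.missing_tokens <- c("NA", ".", "", "-9")

#' Read a SNP genotype table
#'
#' @param path path to the genotype file. For `dialect = "matrix-tsv"` a
#'   companion SNP metadata file (default `<path>.snps`) supplies snp_id,
#'   chrom, position and alleles. For `dialect = "ped-map"`, `path` is the
#'   `.ped` file and the `.map` is found by extension swap unless
#'   `map_path` is given.
#' @param dialect `"matrix-tsv"` or `"ped-map"`.
#' @param snp_path,map_path optional companion-file overrides.
#' @return A `genotype_table`; SNPs sorted by position, unknown genotype
#'   tokens mapped to missing.
#' @export
read_genotypes <- function(path, dialect = c("matrix-tsv", "ped-map"),
                           snp_path = NULL, map_path = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_hla("no such file: ", path)
  if (dialect == "matrix-tsv") {
    .read_matrix_tsv(path, snp_path %||% paste0(path, ".snps"))
  } else {
    .read_ped_map(path, map_path %||% sub("\\.ped$", ".map", path))
  }
}

.read_matrix_tsv <- function(path, snp_path) {
  if (!file.exists(snp_path))
    stop_hla("companion SNP metadata file not found: ", snp_path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop_hla("empty genotype file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (header[1] != "sample_id")
    stop_hla("matrix-tsv header must start with 'sample_id'")
  snp_ids <- header[-1]
  width <- length(header)
  n <- length(fields) - 1L
  calls <- matrix(NA_integer_, n, length(snp_ids))
  sample_ids <- character(n)
  for (i in seq_len(n)) {
    row <- fields[[i + 1L]]
    if (length(row) != width)
      stop_hla("line ", i + 1L, " of ", path, " has ", length(row),
               " fields, expected ", width)
    sample_ids[i] <- row[1]
    tok <- row[-1]
    ok <- tok %in% c("0", "1", "2")
    calls[i, ok] <- as.integer(tok[ok])
  }
  meta <- utils::read.delim(snp_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  need <- c("snp_id", "chrom", "position", "allele_a", "allele_b")
  if (!all(need %in% names(meta)))
    stop_hla("SNP metadata must have columns: ", paste(need, collapse = ", "))
  miss <- setdiff(snp_ids, meta$snp_id)
  if (length(miss))
    stop_hla("SNPs missing from metadata: ", paste(miss, collapse = ", "))
  meta <- meta[match(snp_ids, meta$snp_id), , drop = FALSE]
  genotype_table(calls, meta, sample_ids)
}

.read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(map_path)) stop_hla("no such map file: ", map_path)
  map <- utils::read.table(map_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(map) == 4L) {
    names(map) <- c("chrom", "snp_id", "cm", "position")
  } else if (ncol(map) == 3L) {
    names(map) <- c("chrom", "snp_id", "position")
  } else stop_hla("map file must have 3 or 4 columns")
  if (anyDuplicated(map$snp_id))
    stop_hla("duplicate snp_id in map: ",
             paste(unique(map$snp_id[duplicated(map$snp_id)]), collapse = ", "))
  S <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "[ \t]+")
  width <- 6L + 2L * S
  n <- length(fields)
  a1 <- matrix(NA_character_, n, S)
  a2 <- matrix(NA_character_, n, S)
  sample_ids <- character(n)
  for (i in seq_len(n)) {
    row <- fields[[i]]
    if (length(row) != width)
      stop_hla("line ", i, " of ", ped_path, " has ", length(row),
               " fields, expected ", width)
    sample_ids[i] <- row[2]
    gcols <- row[-(1:6)]
    a1[i, ] <- gcols[seq(1, 2 * S, by = 2)]
    a2[i, ] <- gcols[seq(2, 2 * S, by = 2)]
  }
  a1[a1 == "0"] <- NA_character_
  a2[a2 == "0"] <- NA_character_
  # per-SNP allele coding: allele_a/allele_b alphabetical over observed alleles
  allele_a <- character(S); allele_b <- character(S)
  calls <- matrix(NA_integer_, n, S)
  for (s in seq_len(S)) {
    obs <- sort(unique(stats::na.omit(c(a1[, s], a2[, s]))))
    if (length(obs) > 2L)
      stop_hla("SNP ", map$snp_id[s], " has >2 alleles in ped file")
    if (length(obs) == 0L) obs <- c("N", "X")      # all missing
    if (length(obs) == 1L) obs <- c(obs, if (obs == "N") "X" else "N")
    allele_a[s] <- obs[1]; allele_b[s] <- obs[2]
    ok <- !is.na(a1[, s]) & !is.na(a2[, s])
    calls[ok, s] <- (a1[ok, s] == obs[2]) + (a2[ok, s] == obs[2])
  }
  meta <- data.frame(snp_id = map$snp_id, chrom = map$chrom,
                     position = as.integer(map$position),
                     allele_a = allele_a, allele_b = allele_b,
                     stringsAsFactors = FALSE)
  genotype_table(calls, meta, sample_ids)
}

#' Write a genotype table in the matrix-tsv dialect
#'
#' @param gt a `genotype_table`.
#' @param path output path; the SNP metadata is written next to it as
#'   `<path>.snps`.
#' @export
write_genotypes <- function(gt, path) {
  calls <- gt$calls
  m <- matrix(as.character(calls), nrow(calls), ncol(calls))
  m[is.na(calls)] <- "NA"
  lines <- c(paste(c("sample_id", gt$snps$snp_id), collapse = "\t"),
             vapply(seq_len(nrow(calls)), function(i)
               paste(c(rownames(calls)[i], m[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
  utils::write.table(gt$snps, paste0(path, ".snps"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct / read a posterior-probability genotype table
#'
#' Imputation software emits, per sample and SNP, a probability triple
#' (p0, p1, p2) over the allele-count genotype. Stored as an
#' n x S x 3 array.
#'
#' @param p numeric array `samples x SNPs x 3`; each triple must sum to 1
#'   within 1e-6.
#' @param snps SNP metadata as for [genotype_table()].
#' @param sample_ids character vector of sample ids.
#' @return An object of class `posterior_table`.
#' @export
posterior_table <- function(p, snps, sample_ids = dimnames(p)[[1]]) {
  if (length(dim(p)) != 3L || dim(p)[3] != 3L)
    stop_hla("p must be a samples x SNPs x 3 array")
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (dim(p)[2] != nrow(snps))
    stop_hla("p has ", dim(p)[2], " SNPs but metadata has ", nrow(snps))
  if (any(p < -1e-9 | p > 1 + 1e-9, na.rm = TRUE))
    stop_hla("posterior probabilities must lie in [0, 1]")
  sums <- p[, , 1] + p[, , 2] + p[, , 3]
  if (any(abs(sums - 1) > 1e-6, na.rm = TRUE))
    stop_hla("posterior triples must sum to 1 within 1e-6")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(dim(p)[1]))
  dimnames(p) <- list(sample_ids, snps$snp_id, c("p0", "p1", "p2"))
  structure(list(p = p, snps = snps), class = "posterior_table")
}

#' @export
print.posterior_table <- function(x, ...) {
  cat("posterior_table: ", dim(x$p)[1], " samples x ", dim(x$p)[2],
      " SNPs (probability triples)\n", sep = "")
  invisible(x)
}

#' Read an HLA typing table
#'
#' Tab-separated columns `sample_id`, `locus`, `allele1`, `allele2`;
#' alleles like `"A*0201"` or `"A*02"`, ambiguity alternatives joined by
#' `"/"`, missing as `NA`.
#'
#' @param path file path.
#' @return Data frame with those four character columns, at most one row
#'   per (sample, locus).
#' @export
read_hla_typing <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  need <- c("sample_id", "locus", "allele1", "allele2")
  if (!all(need %in% names(df)))
    stop_hla("HLA typing table must have columns: ", paste(need, collapse = ", "))
  hla_typing(df)
}

#' @rdname read_hla_typing
#' @param df a data frame with the four typing columns (validated).
#' @export
hla_typing <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  key <- paste(df$sample_id, df$locus)
  if (anyDuplicated(key))
    stop_hla("more than one typing row for: ",
             paste(unique(key[duplicated(key)]), collapse = "; "))
  bad <- !df$locus %in% .hla_loci
  if (any(bad)) stop_hla("unknown locus: ", paste(unique(df$locus[bad]), collapse = ", "))
  df[c("sample_id", "locus", "allele1", "allele2")]
}

#' @rdname read_hla_typing
#' @param typing a typing data frame.
#' @export
write_hla_typing <- function(typing, path) {
  utils::write.table(typing, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.model_format_version <- 1L

#' Serialize a fitted haplotype model
#'
#' A versioned, human-readable key-value text format: header fields, the
#' ordered SNP list, then one `hla_allele,snp_allele_string,frequency` row
#' per retained joint haplotype. Haplotypes with zero frequency (or below
#' the model's pruning threshold) are dropped on write. Frequencies
#' round-trip to within 1e-12.
#'
#' @param model a `haplotype_model`.
#' @param path output file.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "haplotype_model"))
  h <- model$haplo
  keep <- h$freq >= max(model$prune_eps, .Machine$double.xmin)
  h <- h[keep, , drop = FALSE]
  h$freq <- h$freq / sum(h$freq)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#HLAMODEL v", .model_format_version),
    paste("locus", model$locus),
    paste("resolution", model$resolution),
    paste("n_train", model$n_train),
    paste("prune_eps", format(model$prune_eps, digits = 17)),
    paste("snps", nrow(model$snps))), con)
  if (nrow(model$snps)) {
    writeLines(paste(model$snps$snp_id, model$snps$chrom,
                     model$snps$position, model$snps$allele_a,
                     model$snps$allele_b, sep = "\t"), con)
  }
  writeLines(paste("haplotypes", nrow(h)), con)
  writeLines(paste(h$hla, h$snp, format(h$freq, digits = 17, scientific = TRUE),
                   sep = ","), con)
  writeLines("end", con)
  invisible(path)
}

#' @rdname write_model
#' @return `read_model` returns the deserialized `haplotype_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop_hla("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines) || !grepl("^#HLAMODEL v", lines[1]))
    stop_hla("not a haplotype model file: ", path)
  ver <- as.integer(sub("^#HLAMODEL v", "", lines[1]))
  if (is.na(ver) || ver != .model_format_version)
    stop_hla("unsupported model format version: ", lines[1])
  if (lines[length(lines)] != "end")
    stop_hla("truncated or corrupt model file: ", path)
  kv <- function(i, key) {
    parts <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    if (parts[1] != key) stop_hla("corrupt model file: expected '", key,
                                  "' on line ", i)
    parts[2]
  }
  locus <- kv(2, "locus")
  resolution <- kv(3, "resolution")
  n_train <- as.integer(kv(4, "n_train"))
  prune_eps <- as.numeric(kv(5, "prune_eps"))
  n_snp <- as.integer(kv(6, "snps"))
  at <- 7L
  if (n_snp > 0) {
    rows <- strsplit(lines[at:(at + n_snp - 1L)], "\t", fixed = TRUE)
    if (any(lengths(rows) != 5L)) stop_hla("corrupt SNP row in model file")
    snps <- data.frame(
      snp_id = vapply(rows, `[`, "", 1),
      chrom = vapply(rows, `[`, "", 2),
      position = as.integer(vapply(rows, `[`, "", 3)),
      allele_a = vapply(rows, `[`, "", 4),
      allele_b = vapply(rows, `[`, "", 5),
      stringsAsFactors = FALSE)
    at <- at + n_snp
  } else {
    snps <- data.frame(snp_id = character(), chrom = character(),
                       position = integer(), allele_a = character(),
                       allele_b = character(), stringsAsFactors = FALSE)
  }
  n_hap <- as.integer(sub("^haplotypes ", "", lines[at]))
  if (is.na(n_hap)) stop_hla("corrupt model file: missing haplotype count")
  at <- at + 1L
  if (at + n_hap - 1L > length(lines) - 1L)
    stop_hla("truncated model file: fewer haplotype rows than declared")
  rows <- strsplit(lines[at:(at + n_hap - 1L)], ",", fixed = TRUE)
  if (any(lengths(rows) != 3L)) stop_hla("corrupt haplotype row in model file")
  haplo <- data.frame(
    hla = vapply(rows, `[`, "", 1),
    snp = vapply(rows, `[`, "", 2),
    freq = as.numeric(vapply(rows, `[`, "", 3)),
    stringsAsFactors = FALSE)
  haplo$snp[is.na(haplo$snp)] <- ""
  haplotype_model(locus = locus, resolution = resolution, snps = snps,
                  haplo = haplo, n_train = n_train, prune_eps = prune_eps)
}
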