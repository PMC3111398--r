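# Fixture builders shared across the test files. Everything is generated in
# code; nothing is read from disk except where a test writes its own
# temporary file first.

snp_meta <- function(ids, pos = seq_along(ids) * 1000L + 29900000L,
                     a = "A", b = "G") {
  data.frame(snp_id = ids, chrom = "6", position = pos,
             allele_a = a, allele_b = b, stringsAsFactors = FALSE)
}

# the worked 3-haplotype model: {(A01,a):0.5, (A02,a):0.3, (A02,b):0.2}
toy_model3 <- function() {
  haplotype_model(
    "A", "high", snp_meta("rs1"),
    data.frame(hla = c("01:01", "02:01", "02:01"), snp = c("a", "a", "b"),
               freq = c(0.5, 0.3, 0.2), stringsAsFactors = FALSE),
    n_train = 10L, prune_eps = 1e-6)
}

toy_typing <- function(sample_ids, a1, a2, locus = "A") {
  hla_typing(data.frame(sample_id = sample_ids, locus = locus,
                        allele1 = a1, allele2 = a2, stringsAsFactors = FALSE))
}

toy_genotypes <- function(calls, ids = sprintf("rs%d", seq_len(ncol(calls))),
                          sample_ids = sprintf("s%d", seq_len(nrow(calls)))) {
  genotype_table(calls, snp_meta(ids), sample_ids)
}

# deterministic-tagging training data: `d` SNPs jointly encode the allele
# index in binary, plus `noise` SNPs independent of the allele.
tagging_cohort <- function(n, n_alleles = 4L, d = 2L, noise = 0L, seed = 1L,
                           gene = c(29910247L, 29913661L)) {
  stopifnot(2^d >= n_alleles)
  freqs <- rep(1 / n_alleles, n_alleles)
  names(freqs) <- sprintf("%02d:01", seq_len(n_alleles))
  codes <- matrix(vapply(seq_len(n_alleles) - 1L,
                         function(x) as.integer(intToBits(x))[seq_len(d)],
                         integer(d)),
                  nrow = n_alleles, ncol = d, byrow = TRUE)
  set.seed(seed)
  gene_pos <- as.integer(seq(gene[1] + 100L, gene[2] - 100L, length.out = d))
  noise_pos <- if (noise > 0)
    as.integer(gene[2] + 50000L + seq_len(noise) * 1000L) else integer(0)
  meta <- snp_meta(c(sprintf("tag%d", seq_len(d)),
                     if (noise > 0) sprintf("noise%d", seq_len(noise))),
                   pos = c(gene_pos, noise_pos))
  a1 <- sample.int(n_alleles, n, replace = TRUE, prob = freqs)
  a2 <- sample.int(n_alleles, n, replace = TRUE, prob = freqs)
  hap <- function(ai) cbind(codes[ai, , drop = FALSE],
                            matrix(rbinom(length(ai) * noise, 1, 0.5),
                                   length(ai), noise))
  calls <- hap(a1) + hap(a2)
  storage.mode(calls) <- "integer"
  gt <- genotype_table(calls, meta, sprintf("s%04d", seq_len(n)))
  typ <- toy_typing(sprintf("s%04d", seq_len(n)),
                    names(freqs)[a1], names(freqs)[a2])
  list(genotypes = gt, typing = typ, freqs = freqs)
}

# the 5-SNP QC toy panel: snpB fails MAF (monomorphic), snpD fails
# missingness (3/10 missing); the other three pass everything.
qc_toy_panel <- function() {
  calls <- cbind(
    snpA = c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 1L, 0L, 1L),
    snpB = rep(0L, 10L),
    snpC = c(0L, 0L, 1L, 1L, 0L, 1L, 0L, 1L, 1L, 0L),
    snpD = c(0L, 1L, NA, NA, NA, 1L, 0L, 1L, 0L, 1L),
    snpE = c(2L, 1L, 1L, 0L, 2L, 1L, 0L, 1L, 2L, 1L))
  genotype_table(calls, snp_meta(colnames(calls)),
                 sprintf("s%02d", 1:10))
}
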