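#' @name synthetic_mhc
#' @title Synthetic multi-population MHC cohorts
#'
#' @description
#' A seedable generator of phased (HLA allele, SNP haplotype) truth and the
#' unphased observables derived from it, emulating the one property SNP-based
#' HLA prediction rests on: linkage disequilibrium between an HLA allele and
#' the SNP haplotypes it rides on. LD is modelled at the haplotype-pool
#' level rather than by coalescent simulation: each HLA allele carries one
#' or more core SNP haplotypes ("tags"), pool haplotypes are noisy copies of
#' the cores, and sampled chromosomes may recombine with a random pool
#' haplotype. With zero noise and one tag per allele the HLA allele is a
#' deterministic function of the SNP haplotype (perfect tagging); raising
#' `haplotype_noise` towards 0.5 destroys the association. Populations with
#' disjoint HLA alleles and independent cores give the cohort-level
#' Hardy-Weinberg violation that multi-ethnic training experiments require.
#'
#' Observable genotypes are the allele-count sums of the two truth
#' haplotypes, with uniform missingness; optionally each genotype is
#' emitted as an imputation-style posterior triple peaked at the truth with
#' configurable sharpness.
NULL

#' Specify one source population
#'
#' @param name population label.
#' @param n_snps number of SNPs in the panel.
#' @param hla_freqs named vector of HLA allele-key frequencies (sums to 1),
#'   or `NULL` to draw `n_hla_alleles` frequencies from a symmetric
#'   Dirichlet with concentration `hla_conc`.
#' @param n_hla_alleles,hla_conc used when `hla_freqs` is `NULL`.
#' @param allele_prefix first field stem used to synthesize allele names
#'   when `hla_freqs` is `NULL` (alleles `"<p+i>:01"`).
#' @param tags_per_allele core SNP haplotypes per HLA allele.
#' @param haplotype_noise per-SNP probability that a pool haplotype deviates
#'   from its core (0 = perfect tagging, 0.5 = no information).
#' @param recomb_rate per-adjacent-SNP crossover probability between a
#'   sampled haplotype and a random pool haplotype.
#' @param pool_draws noisy pool haplotypes drawn per core (ignored at zero
#'   noise, where the pool is exactly the cores).
#' @param span two positions bounding the SNP panel; defaults to 100 kb
#'   either side of the gene.
#' @param gene two positions bounding the HLA gene (defaults to the HLA-A
#'   coordinates on chromosome 6).
#' @param locus HLA locus label for the simulated gene.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(name, n_snps = 8L, hla_freqs = NULL,
                            n_hla_alleles = 4L, hla_conc = 1,
                            allele_prefix = 1L, tags_per_allele = 1L,
                            haplotype_noise = 0, recomb_rate = 0,
                            pool_draws = 20L,
                            gene = c(29910247L, 29913661L),
                            span = NULL, locus = "A") {
  span <- span %||% c(gene[1] - 100000L, gene[2] + 100000L)
  if (!is.null(hla_freqs)) {
    if (abs(sum(hla_freqs) - 1) > 1e-8)
      stop_hla("hla_freqs must sum to 1")
    if (is.null(names(hla_freqs))) stop_hla("hla_freqs must be named")
  }
  if (haplotype_noise < 0 || haplotype_noise > 1 ||
      recomb_rate < 0 || recomb_rate > 1)
    stop_hla("probabilities must lie in [0, 1]")
  structure(list(name = name, n_snps = as.integer(n_snps),
                 hla_freqs = hla_freqs,
                 n_hla_alleles = as.integer(n_hla_alleles),
                 hla_conc = hla_conc, allele_prefix = as.integer(allele_prefix),
                 tags_per_allele = as.integer(tags_per_allele),
                 haplotype_noise = haplotype_noise,
                 recomb_rate = recomb_rate, pool_draws = as.integer(pool_draws),
                 gene = as.integer(gene), span = as.integer(span),
                 locus = locus),
            class = "population_spec")
}

#' Build a population's joint-haplotype pool
#'
#' Draws HLA allele frequencies (unless given), per-allele core SNP
#' haplotypes (distinct across alleles and tags), and — at positive noise —
#' `pool_draws` noisy copies per core. Returns the normalized frequency
#' table over joint haplotypes plus the SNP panel.
#'
#' @param spec a `population_spec`.
#' @param seed integer seed.
#' @param snps optional pre-built SNP metadata to reuse (shared panels).
#' @return A list of class `haplotype_pool` with elements `haplo`
#'   (`hla`, `snp`, `freq`), `snps` and `spec`.
#' @export
build_haplotype_pool <- function(spec, seed, snps = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed(seed, {
    if (is.null(snps)) snps <- .draw_snp_panel(spec)
    S <- nrow(snps)
    freqs <- spec$hla_freqs
    if (is.null(freqs)) {
      f <- rdirichlet1(rep(spec$hla_conc, spec$n_hla_alleles))
      names(f) <- sprintf("%02d:01",
                          spec$allele_prefix + seq_len(spec$n_hla_alleles) - 1L)
      freqs <- f
    }
    alleles <- names(freqs)
    ncore <- length(alleles) * spec$tags_per_allele
    if (2^S < ncore * 2)
      stop_hla("n_snps too small to give ", ncore, " distinct core haplotypes")
    # distinct cores across all (allele, tag) combinations; at zero noise
    # additionally require distinct unordered pair sums so the HLA genotype
    # is identifiable from the unphased SNP genotype (perfect tagging)
    repeat {
      cores <- matrix(stats::rbinom(ncore * S, 1, 0.5), ncore, S)
      keys <- apply(cores, 1, paste, collapse = "")
      if (anyDuplicated(keys)) next
      if (spec$haplotype_noise <= 0) {
        ij <- which(upper.tri(diag(ncore), diag = TRUE), arr.ind = TRUE)
        sums <- apply(ij, 1, function(p)
          paste(cores[p[1], ] + cores[p[2], ], collapse = ""))
        if (anyDuplicated(sums)) next
      }
      break
    }
    rows <- list()
    ci <- 0L
    for (ai in seq_along(alleles)) {
      for (t in seq_len(spec$tags_per_allele)) {
        ci <- ci + 1L
        base_f <- freqs[ai] / spec$tags_per_allele
        if (spec$haplotype_noise <= 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            hla = alleles[ai],
            snp = paste(c("a", "b")[cores[ci, ] + 1L], collapse = ""),
            freq = base_f, stringsAsFactors = FALSE)
        } else {
          for (d in seq_len(spec$pool_draws)) {
            flip <- stats::rbinom(S, 1, spec$haplotype_noise)
            hap <- (cores[ci, ] + flip) %% 2L
            rows[[length(rows) + 1L]] <- data.frame(
              hla = alleles[ai],
              snp = paste(c("a", "b")[hap + 1L], collapse = ""),
              freq = base_f / spec$pool_draws, stringsAsFactors = FALSE)
          }
        }
      }
    }
    haplo <- do.call(rbind, rows)
    agg <- stats::aggregate(freq ~ hla + snp, data = haplo, FUN = sum)
    agg <- agg[order(agg$hla, agg$snp), , drop = FALSE]
    agg$freq <- agg$freq / sum(agg$freq)
    rownames(agg) <- NULL
    structure(list(haplo = agg, snps = snps, spec = spec),
              class = "haplotype_pool")
  })
}

.draw_snp_panel <- function(spec) {
  pos <- sort(sample(seq(spec$span[1], spec$span[2]), spec$n_snps))
  data.frame(snp_id = sprintf("rs%07d", seq_len(spec$n_snps) * 13L + pos %% 7L),
             chrom = "6", position = pos,
             allele_a = "A", allele_b = "G", stringsAsFactors = FALSE)
}

#' Specify a (possibly multi-population) cohort
#'
#' @param populations list of `list(spec = population_spec, n = count)`.
#' @param shared_snp_panel reuse the first population's SNP panel for all
#'   (required to combine populations into one table).
#' @param missing_rate uniform per-cell missingness of the observable
#'   genotypes.
#' @param posterior_mode also emit imputation-style posterior triples.
#' @param posterior_conc sharpness of the simulated posteriors (Dirichlet
#'   concentration added to the true genotype's component; larger = more
#'   confident).
#' @param seed mandatory integer seed.
#' @param pool_seed seed for building the haplotype pools; defaults to
#'   `seed`. Give two cohort specs the same `pool_seed` (and population
#'   specs) to draw independent cohorts from the same population.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(populations, shared_snp_panel = TRUE,
                        missing_rate = 0, posterior_mode = FALSE,
                        posterior_conc = 50, seed, pool_seed = seed) {
  if (missing(seed)) stop_hla("cohort_spec requires a seed")
  for (p in populations) {
    if (!inherits(p$spec, "population_spec") || is.null(p$n) || p$n < 0)
      stop_hla("each population entry needs a population_spec and n >= 0")
  }
  structure(list(populations = populations,
                 shared_snp_panel = isTRUE(shared_snp_panel),
                 missing_rate = missing_rate,
                 posterior_mode = isTRUE(posterior_mode),
                 posterior_conc = posterior_conc, seed = as.integer(seed),
                 pool_seed = as.integer(pool_seed)),
            class = "cohort_spec")
}

#' Sample a cohort from its specification
#'
#' Per sample: a population by its count share, two haplotypes drawn
#' independently from that population's pool (Hardy-Weinberg within
#' population), optional recombination with a random pool haplotype, then
#' the derived unphased observables. Fully reproducible from the seed.
#'
#' @param cs a `cohort_spec`.
#' @return A list of class `sim_cohort`: `truth` (sample, population, the
#'   two phased joint haplotypes), `genotypes` (`genotype_table`),
#'   `posteriors` (`posterior_table` or `NULL`), `typing` (HLA typing
#'   table), `pools` (per-population `haplotype_pool`s), `locus`.
#' @export
sample_cohort <- function(cs) {
  stopifnot(inherits(cs, "cohort_spec"))
  pools <- list()
  snps <- NULL
  for (i in seq_along(cs$populations)) {
    sp <- cs$populations[[i]]$spec
    pools[[sp$name]] <- build_haplotype_pool(
      sp, seed = (cs$pool_seed %||% cs$seed) + 1000L * i,
      snps = if (cs$shared_snp_panel && !is.null(snps)) snps else NULL)
    if (is.null(snps)) snps <- pools[[sp$name]]$snps
  }
  locus <- cs$populations[[1]]$spec$locus
  with_seed(cs$seed, {
    rows <- list(); hap1 <- list(); hap2 <- list()
    sid <- 0L
    for (i in seq_along(cs$populations)) {
      sp <- cs$populations[[i]]$spec
      n <- cs$populations[[i]]$n
      if (n == 0) next
      pool <- pools[[sp$name]]
      H <- nrow(pool$haplo)
      for (k in seq_len(n)) {
        sid <- sid + 1L
        i1 <- sample.int(H, 1, prob = pool$haplo$freq)
        i2 <- sample.int(H, 1, prob = pool$haplo$freq)
        h1 <- .recombine(pool, i1, sp)
        h2 <- .recombine(pool, i2, sp)
        rows[[sid]] <- data.frame(
          sample_id = sprintf("sim%05d", sid), population = sp$name,
          hla1 = h1$hla, hla2 = h2$hla, hap1 = h1$snp, hap2 = h2$snp,
          stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, rows)
    n <- nrow(truth)
    S <- nrow(snps)
    c1 <- snp_code_matrix(truth$hap1)
    c2 <- snp_code_matrix(truth$hap2)
    calls <- c1 + c2
    storage.mode(calls) <- "integer"
    true_calls <- calls
    if (cs$missing_rate > 0) {
      mask <- matrix(stats::runif(n * S) < cs$missing_rate, n, S)
      calls[mask] <- NA_integer_
    }
    gt <- genotype_table(calls, snps, truth$sample_id,
                         sort_by_position = FALSE)
    post <- NULL
    if (cs$posterior_mode) {
      p <- array(NA_real_, c(n, S, 3))
      base <- 0.5
      g <- stats::rgamma(n * S * 3, shape = base, rate = 1)
      dim(g) <- c(n, S, 3)
      bump <- stats::rgamma(n * S, shape = cs$posterior_conc, rate = 1)
      for (k in 0:2) {
        sel <- true_calls == k
        gk <- g[, , k + 1]
        gk[sel] <- gk[sel] + bump[sel]
        g[, , k + 1] <- gk
      }
      tot <- g[, , 1] + g[, , 2] + g[, , 3]
      for (k in 1:3) p[, , k] <- g[, , k] / tot
      post <- posterior_table(p, snps, truth$sample_id)
    }
    typing <- hla_typing(data.frame(
      sample_id = truth$sample_id, locus = locus,
      allele1 = truth$hla1, allele2 = truth$hla2, stringsAsFactors = FALSE))
    structure(list(truth = truth, genotypes = gt, posteriors = post,
                   typing = typing, pools = pools, locus = locus,
                   spec = cs),
              class = "sim_cohort")
  })
}

# crossover of pool haplotype i with an independently drawn partner;
# the HLA allele follows the template covering the gene midpoint.
.recombine <- function(pool, i, sp) {
  hla <- pool$haplo$hla[i]
  snp <- pool$haplo$snp[i]
  if (sp$recomb_rate <= 0) return(list(hla = hla, snp = snp))
  S <- nchar(snp)
  j <- sample.int(nrow(pool$haplo), 1, prob = pool$haplo$freq)
  # loci in order: SNPs plus the HLA gene at its midpoint position
  gene_mid <- mean(sp$gene)
  pos <- c(pool$snps$position, gene_mid)
  ord <- order(pos)
  L <- length(pos)
  cur <- rep(1L, L)
  state <- 1L
  for (k in seq_len(L)) {
    if (k > 1L && stats::runif(1) < sp$recomb_rate) state <- 3L - state
    cur[ord[k]] <- state
  }
  s1 <- strsplit(snp, "")[[1]]
  s2 <- strsplit(pool$haplo$snp[j], "")[[1]]
  out <- ifelse(cur[seq_len(S)] == 1L, s1, s2)
  list(hla = if (cur[L] == 1L) hla else pool$haplo$hla[j],
       snp = paste(out, collapse = ""))
}

#' @export
print.sim_cohort <- function(x, ...) {
  tab <- table(x$truth$population)
  cat("sim_cohort: ", nrow(x$truth), " samples (",
      paste(names(tab), tab, sep = "=", collapse = ", "), "), ",
      nrow(x$genotypes$snps), " SNPs, locus HLA-", x$locus,
      if (!is.null(x$posteriors)) ", with posteriors", "\n", sep = "")
  invisible(x)
}

#' Subset a simulated cohort by sample id
#' @param cohort a `sim_cohort`.
#' @param sample_ids samples to keep.
#' @export
subset_cohort <- function(cohort, sample_ids) {
  keep <- cohort$truth$sample_id %in% sample_ids
  out <- cohort
  out$truth <- cohort$truth[keep, , drop = FALSE]
  out$genotypes <- subset_genotypes(cohort$genotypes, samples = sample_ids)
  if (!is.null(cohort$posteriors)) {
    p <- cohort$posteriors$p[sample_ids, , , drop = FALSE]
    out$posteriors <- posterior_table(p, cohort$posteriors$snps, sample_ids)
  }
  out$typing <- cohort$typing[cohort$typing$sample_id %in% sample_ids, ,
                              drop = FALSE]
  out
}
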