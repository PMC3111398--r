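# Independent oracles: plain-loop implementations used to cross-check the
# package, deliberately sharing no code with it.

# Likelihood of unphased training data under an explicit joint-haplotype
# frequency table, by brute-force enumeration of ordered haplotype pairs.
# haps: data.frame(hla, snp); freq: numeric; geno: n x S matrix (NA ok);
# truth1/truth2: character vectors of allele keys (unambiguous truth).
brute_loglik <- function(haps, freq, geno, truth1, truth2) {
  H <- nrow(haps)
  S <- ncol(geno)
  code <- matrix(0L, H, S)
  if (S > 0) {
    for (h in seq_len(H))
      code[h, ] <- as.integer(strsplit(haps$snp[h], "")[[1]] == "b")
  }
  ll <- 0
  for (i in seq_len(nrow(geno))) {
    lik <- 0
    for (h1 in seq_len(H)) for (h2 in seq_len(H)) {
      ok_hla <- (haps$hla[h1] == truth1[i] && haps$hla[h2] == truth2[i]) ||
        (haps$hla[h1] == truth2[i] && haps$hla[h2] == truth1[i])
      if (!ok_hla) next
      ok <- TRUE
      for (s in seq_len(S)) {
        g <- geno[i, s]
        if (!is.na(g) && code[h1, s] + code[h2, s] != g) { ok <- FALSE; break }
      }
      if (ok) lik <- lik + freq[h1] * freq[h2]
    }
    ll <- ll + log(max(lik, 1e-300))
  }
  ll
}

# haplotypes that appear in at least one sample's compatible pair carry all
# the likelihood mass at the optimum; the grid search runs over that support.
brute_support <- function(haps, geno, truth1, truth2) {
  H <- nrow(haps)
  S <- ncol(geno)
  code <- matrix(0L, H, S)
  if (S > 0) {
    for (h in seq_len(H))
      code[h, ] <- as.integer(strsplit(haps$snp[h], "")[[1]] == "b")
  }
  used <- logical(H)
  for (i in seq_len(nrow(geno))) {
    for (h1 in seq_len(H)) for (h2 in seq_len(H)) {
      ok_hla <- (haps$hla[h1] == truth1[i] && haps$hla[h2] == truth2[i]) ||
        (haps$hla[h1] == truth2[i] && haps$hla[h2] == truth1[i])
      if (!ok_hla) next
      ok <- TRUE
      for (s in seq_len(S)) {
        g <- geno[i, s]
        if (!is.na(g) && code[h1, s] + code[h2, s] != g) { ok <- FALSE; break }
      }
      if (ok) { used[h1] <- TRUE; used[h2] <- TRUE }
    }
  }
  used
}

# all compositions of `total` into k non-negative parts (k <= 4 here)
simplex_grid <- function(k, step = 0.01) {
  total <- round(1 / step)
  if (k == 1) return(matrix(1, 1, 1))
  if (k == 2) {
    i <- 0:total
    return(cbind(i, total - i) * step)
  }
  if (k == 3) {
    g <- expand.grid(i = 0:total, j = 0:total)
    g <- g[g$i + g$j <= total, ]
    return(cbind(g$i, g$j, total - g$i - g$j) * step)
  }
  if (k == 4) {
    g <- expand.grid(i = 0:total, j = 0:total, k = 0:total)
    g <- g[g$i + g$j + g$k <= total, ]
    return(cbind(g$i, g$j, g$k, total - g$i - g$j - g$k) * step)
  }
  stop("grid oracle limited to 4 support haplotypes")
}

# best log-likelihood over the frequency simplex grid, restricted to the
# support; vectorized over grid rows.
grid_search_loglik <- function(haps, geno, truth1, truth2, step = 0.01) {
  used <- brute_support(haps, geno, truth1, truth2)
  sub <- haps[used, , drop = FALSE]
  H <- nrow(sub)
  stopifnot(H >= 1, H <= 4)
  S <- ncol(geno)
  code <- matrix(0L, H, S)
  if (S > 0) {
    for (h in seq_len(H))
      code[h, ] <- as.integer(strsplit(sub$snp[h], "")[[1]] == "b")
  }
  # per-sample compatible ordered pairs over the support
  pairlists <- vector("list", nrow(geno))
  for (i in seq_len(nrow(geno))) {
    prs <- list()
    for (h1 in seq_len(H)) for (h2 in seq_len(H)) {
      ok_hla <- (sub$hla[h1] == truth1[i] && sub$hla[h2] == truth2[i]) ||
        (sub$hla[h1] == truth2[i] && sub$hla[h2] == truth1[i])
      if (!ok_hla) next
      ok <- TRUE
      for (s in seq_len(S)) {
        g <- geno[i, s]
        if (!is.na(g) && code[h1, s] + code[h2, s] != g) { ok <- FALSE; break }
      }
      if (ok) prs[[length(prs) + 1L]] <- c(h1, h2)
    }
    pairlists[[i]] <- do.call(rbind, prs)
  }
  FG <- simplex_grid(H, step)
  ll <- numeric(nrow(FG))
  for (i in seq_len(nrow(geno))) {
    pr <- pairlists[[i]]
    lik <- numeric(nrow(FG))
    if (!is.null(pr))
      for (m in seq_len(nrow(pr)))
        lik <- lik + FG[, pr[m, 1]] * FG[, pr[m, 2]]
    ll <- ll + log(pmax(lik, 1e-300))
  }
  max(ll)
}

# random small EM-oracle instance with grid-feasible support (<= 4
# haplotypes): one polymorphic SNP with two HLA alleles, optionally plus a
# monomorphic second SNP, or three alleles with a monomorphic SNP only.
random_em_instance <- function(seed) {
  set.seed(seed)
  variant <- sample(1:3, 1)
  n <- sample(6:20, 1)
  if (variant == 3L) {          # 3 alleles, 1 monomorphic SNP: support 3
    alleles <- c("01:01", "02:01", "03:01")
    a1 <- sample(alleles, n, replace = TRUE)
    a2 <- sample(alleles, n, replace = TRUE)
    geno <- matrix(0L, n, 1)
    meta <- snp_meta("m1")
  } else {                      # 2 alleles, 1 informative SNP (support <= 4)
    alleles <- c("01:01", "02:01")
    a1 <- sample(alleles, n, replace = TRUE, prob = c(0.6, 0.4))
    a2 <- sample(alleles, n, replace = TRUE, prob = c(0.6, 0.4))
    p_assoc <- runif(1, 0.5, 1)
    hap_code <- function(al) ifelse(runif(n) < p_assoc, al == "02:01",
                                    al != "02:01")
    g1 <- as.integer(hap_code(a1)) + as.integer(hap_code(a2))
    if (variant == 2L) {        # add a monomorphic SNP; support unchanged
      geno <- cbind(g1, 0L)
      meta <- snp_meta(c("p1", "m1"))
    } else {
      geno <- matrix(g1, n, 1)
      meta <- snp_meta("p1")
    }
  }
  storage.mode(geno) <- "integer"
  sample_ids <- sprintf("s%03d", seq_len(n))
  list(genotypes = genotype_table(geno, meta, sample_ids),
       typing = toy_typing(sample_ids, a1, a2),
       geno = geno, truth1 = a1, truth2 = a2, meta = meta)
}

# full candidate haplotype table (all alleles x all SNP patterns) for an
# instance — the space the oracle searches over.
full_hap_space <- function(alleles, S) {
  pats <- ""
  for (s in seq_len(S))
    pats <- as.vector(outer(pats, c("a", "b"), paste0))
  expand.grid(hla = alleles, snp = pats, stringsAsFactors = FALSE)
}

# chance-corrected agreement from an explicit contingency table
kappa_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- factor(x[ok], levels = 0:2)
  y <- factor(y[ok], levels = 0:2)
  tab <- table(x, y) / sum(ok)
  pa <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (pe >= 1) return(if (pa == 1) 1 else 0)
  (pa - pe) / (1 - pe)
}
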