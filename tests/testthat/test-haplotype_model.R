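test_that("compatible pair enumeration matches hand enumeration", {
  # degenerate one-haplotype model: a single pair of weight 1
  m1 <- haplotype_model("A", "high", snp_meta("rs1"),
                        data.frame(hla = "01:01", snp = "a", freq = 1),
                        1, 1e-6)
  pr <- enumerate_compatible_pairs(m1, 0L)
  expect_identical(nrow(pr), 1L)
  expect_equal(pr$weight, 1)

  # two haplotypes, het genotype: both orders, total weight 2 * 0.6 * 0.4
  m2 <- haplotype_model("A", "high", snp_meta("rs1"),
                        data.frame(hla = c("01:01", "02:01"),
                                   snp = c("a", "b"), freq = c(0.6, 0.4)),
                        2, 1e-6)
  pr2 <- enumerate_compatible_pairs(m2, 1L)
  expect_identical(nrow(pr2), 2L)
  expect_equal(sum(pr2$weight), 0.48)

  # a missing genotype imposes no constraint: weights sum over all pairs
  pr3 <- enumerate_compatible_pairs(m2, NA_integer_)
  expect_identical(nrow(pr3), 4L)
  expect_equal(sum(pr3$weight), 1)

  # optional HLA constraint filters pairs
  pr4 <- enumerate_compatible_pairs(m2, NA_integer_, c("01:01", "01:01"))
  expect_identical(nrow(pr4), 1L)
  expect_equal(pr4$weight, 0.36)
})

test_that("the worked three-haplotype posterior is exact", {
  m <- toy_model3()
  p <- posterior_hla(m, 0L)
  expect_equal(unname(p["01:01/02:01"]), 0.46875)
  expect_equal(unname(p["01:01/01:01"]), 0.390625)
  expect_equal(unname(p["02:01/02:01"]), 0.140625)
  expect_equal(sum(p), 1)
  expect_false(attr(p, "fallback"))
})

test_that("with all SNPs missing the posterior is the HWE prior over HLA pairs", {
  m <- toy_model3()
  p <- posterior_hla(m, NA_integer_)
  marg <- hla_marginals(m)             # 01:01 -> 0.5, 02:01 -> 0.5
  expect_equal(unname(p["01:01/01:01"]), unname(marg["01:01"]^2))
  expect_equal(unname(p["01:01/02:01"]),
               unname(2 * marg["01:01"] * marg["02:01"]))
  expect_equal(sum(p), 1)
})

test_that("a zero-likelihood sample falls back to the prior, flagged", {
  # model has no haplotype with 'b', so genotype 2 is inexplicable
  m <- haplotype_model("A", "high", snp_meta("rs1"),
                       data.frame(hla = c("01:01", "02:01"),
                                  snp = c("a", "a"), freq = c(0.7, 0.3)),
                       2, 1e-6)
  p <- posterior_hla(m, 2L)
  expect_true(attr(p, "fallback"))
  expect_equal(unname(p["01:01/01:01"]), 0.49)
  expect_equal(sum(p), 1)
})

test_that("conditional likelihood: exactness, ambiguity credit, additivity", {
  m <- toy_model3()
  gt1 <- toy_genotypes(matrix(0L, 1, 1), ids = "rs1", sample_ids = "s1")
  typ1 <- toy_typing("s1", "01:01", "02:01")
  expect_equal(conditional_nll(m, gt1, typ1), -log(0.46875), tolerance = 1e-12)

  # two identical samples give exactly twice the value
  gt2 <- toy_genotypes(matrix(0L, 2, 1), ids = "rs1",
                       sample_ids = c("s1", "s2"))
  typ2 <- toy_typing(c("s1", "s2"), "01:01", "02:01")
  expect_equal(conditional_nll(m, gt2, typ2), -2 * log(0.46875),
               tolerance = 1e-12)

  # ambiguous truth sums posterior mass over the alternatives
  typ_amb <- toy_typing("s1", "01:01/02:01", "02:01")
  expect_equal(conditional_nll(m, gt1, typ_amb),
               -log(0.46875 + 0.140625), tolerance = 1e-12)

  # deterministic model with correct truth: nll = 0
  md <- haplotype_model("A", "high", snp_meta("rs1"),
                        data.frame(hla = "01:01", snp = "a", freq = 1),
                        1, 1e-6)
  expect_equal(conditional_nll(md, gt1, toy_typing("s1", "01:01", "01:01")), 0)
})

test_that("a single-haplotype population fits to frequency one at loglik zero", {
  gt <- toy_genotypes(matrix(0L, 8, 1), ids = "rs1",
                      sample_ids = sprintf("s%d", 1:8))
  typ <- toy_typing(sprintf("s%d", 1:8), "01:01", "01:01")
  fit <- fit_em(gt, typ, "A", "high", seed = 1)
  expect_identical(nrow(fit$model$haplo), 1L)
  expect_equal(fit$model$haplo$freq, 1)
  expect_equal(fit$diagnostics$loglik[length(fit$diagnostics$loglik)], 0)
})

test_that("the all-double-heterozygote saddle is escaped to the symmetric optimum", {
  n <- 10
  gt <- toy_genotypes(matrix(1L, n, 1), ids = "rs1",
                      sample_ids = sprintf("s%d", 1:n))
  typ <- toy_typing(sprintf("s%d", 1:n), "01:01", "02:01")
  fit <- fit_em(gt, typ, "A", "high", seed = 7)
  ll <- fit$diagnostics$loglik[length(fit$diagnostics$loglik)]
  # optimum: two haplotypes at 0.5 each, per-sample likelihood 2*(0.5*0.5)
  expect_equal(ll / n, log(0.5), tolerance = 1e-4)
  big <- fit$model$haplo[fit$model$haplo$freq > 0.05, ]
  expect_identical(nrow(big), 2L)
  expect_setequal(big$hla, c("01:01", "02:01"))
})

test_that("EM log-likelihood is monotone and frequencies normalized on random fits", {
  set.seed(19)
  for (rep in 1:8) {
    co <- tagging_cohort(n = 60, n_alleles = sample(2:4, 1), d = 2,
                         noise = sample(0:2, 1), seed = rep)
    fit <- fit_em(co$genotypes, co$typing, "A", "high", seed = rep)
    for (tr in fit$diagnostics$stages)
      expect_true(all(diff(tr) >= -1e-10))
    expect_equal(sum(fit$model$haplo$freq), 1, tolerance = 1e-8)
    g <- co$genotypes$calls[sample(nrow(co$genotypes$calls), 1), ]
    expect_equal(sum(posterior_hla(fit$model, g)), 1, tolerance = 1e-8)
  }
})

test_that("fitted frequencies are invariant to sample order", {
  co <- tagging_cohort(n = 80, n_alleles = 3, d = 2, noise = 1, seed = 4)
  fit1 <- fit_em(co$genotypes, co$typing, "A", "high", seed = 2)
  perm <- sample(rownames(co$genotypes$calls))
  fit2 <- fit_em(subset_genotypes(co$genotypes, samples = perm),
                 co$typing, "A", "high", seed = 2)
  h1 <- fit1$model$haplo[order(fit1$model$haplo$hla, fit1$model$haplo$snp), ]
  h2 <- fit2$model$haplo[order(fit2$model$haplo$hla, fit2$model$haplo$snp), ]
  expect_identical(h1$hla, h2$hla)
  expect_identical(h1$snp, h2$snp)
  expect_equal(h1$freq, h2$freq, tolerance = 1e-8)
})

test_that("EM attains the simplex-grid optimum on small instances", {
  for (seed in c(101, 202, 303)) {
    inst <- random_em_instance(seed)
    fit <- fit_em(inst$genotypes, inst$typing, "A", "high", seed = seed,
                  prune_eps = 1e-7)
    ll_em <- brute_loglik(fit$model$haplo, fit$model$haplo$freq,
                          inst$geno, inst$truth1, inst$truth2)
    space <- full_hap_space(unique(c(inst$truth1, inst$truth2)),
                            ncol(inst$geno))
    ll_grid <- grid_search_loglik(space, inst$geno, inst$truth1, inst$truth2)
    expect_gte(ll_em, ll_grid - 1e-3)
  }
})

test_that("extending an HLA-only model by one SNP equals a cold-start fit", {
  co <- tagging_cohort(n = 50, n_alleles = 2, d = 1, noise = 0, seed = 9)
  base <- fit_em(co$genotypes, co$typing, "A", "high",
                 snp_ids = character(0), seed = 1)$model
  ext <- extend_model(base, co$genotypes$snps[1, ], co$genotypes, co$typing,
                      seed = 1)
  cold <- fit_em(co$genotypes, co$typing, "A", "high",
                 snp_ids = co$genotypes$snps$snp_id[1], seed = 1)$model
  e <- ext$haplo[order(ext$haplo$hla, ext$haplo$snp), ]
  c2 <- cold$haplo[order(cold$haplo$hla, cold$haplo$snp), ]
  expect_identical(e$hla, c2$hla)
  expect_equal(e$freq, c2$freq, tolerance = 1e-6)
})

test_that("extending with a monomorphic SNP changes nothing", {
  co <- tagging_cohort(n = 40, n_alleles = 2, d = 1, noise = 0, seed = 3)
  fit <- fit_em(co$genotypes, co$typing, "A", "high", seed = 1)
  mono <- data.frame(snp_id = "mono1", chrom = "6",
                     position = max(co$genotypes$snps$position) + 500L,
                     allele_a = "A", allele_b = "G", stringsAsFactors = FALSE)
  gt2 <- genotype_table(cbind(co$genotypes$calls, mono1 = 0L),
                        rbind(co$genotypes$snps, mono),
                        rownames(co$genotypes$calls))
  ext <- extend_model(fit$model, mono, gt2, co$typing, seed = 1)
  expect_identical(nrow(ext$haplo), nrow(fit$model$haplo))
  expect_true(all(substr(ext$haplo$snp, nchar(ext$haplo$snp),
                         nchar(ext$haplo$snp)) == "a"))
  expect_equal(conditional_nll(ext, gt2, co$typing),
               conditional_nll(fit$model, co$genotypes, co$typing),
               tolerance = 1e-6)
})

test_that("extend then drop returns the marginalized model", {
  co <- tagging_cohort(n = 60, n_alleles = 2, d = 2, noise = 0, seed = 6)
  full <- fit_em(co$genotypes, co$typing, "A", "high", seed = 1)$model
  dropped <- drop_snp(full, co$genotypes$snps$snp_id[2],
                      co$genotypes, co$typing, seed = 1)
  refit <- fit_em(co$genotypes, co$typing, "A", "high",
                  snp_ids = co$genotypes$snps$snp_id[-2], seed = 1)$model
  d <- dropped$haplo[order(dropped$haplo$hla, dropped$haplo$snp), ]
  r <- refit$haplo[order(refit$haplo$hla, refit$haplo$snp), ]
  expect_identical(d$hla, r$hla)
  expect_equal(d$freq, r$freq, tolerance = 1e-4)
})

test_that("missing truth is a training error, not a silent drop", {
  gt <- toy_genotypes(matrix(0L, 2, 1), ids = "rs1",
                      sample_ids = c("s1", "s2"))
  typ <- toy_typing("s1", "01:01", "01:01")
  expect_error(fit_em(gt, typ, "A", "high"), "missing")
})

test_that("genotype tables with swapped allele orientation are flipped on alignment", {
  m <- toy_model3()
  meta_sw <- m$snps
  meta_sw$allele_a <- "G"; meta_sw$allele_b <- "A"
  gt_sw <- genotype_table(matrix(2L, 1, 1, dimnames = list("s1", "rs1")),
                          meta_sw, "s1")
  p <- posterior_hla(m, hlapredict:::align_genotypes(m, gt_sw)[1, ])
  expect_equal(unname(p["01:01/02:01"]), 0.46875)   # 2 copies of A = 0 of G

  meta_bad <- m$snps
  meta_bad$allele_a <- "C"; meta_bad$allele_b <- "T"
  gt_bad <- genotype_table(matrix(0L, 1, 1, dimnames = list("s1", "rs1")),
                           meta_bad, "s1")
  expect_error(hlapredict:::align_genotypes(m, gt_bad), "harmonize")
})
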