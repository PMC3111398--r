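test_that("perfect-tagging pools have one distinguishable haplotype per allele", {
  sp <- population_spec("p", n_snps = 6, n_hla_alleles = 2,
                        tags_per_allele = 1, haplotype_noise = 0)
  pool <- build_haplotype_pool(sp, seed = 5)
  expect_identical(nrow(pool$haplo), 2L)
  expect_identical(anyDuplicated(pool$haplo$snp), 0L)
  expect_equal(sum(pool$haplo$freq), 1)
})

test_that("pools with disjoint HLA alleles share no joint haplotype", {
  f1 <- setNames(c(0.5, 0.5), c("01:01", "02:01"))
  f2 <- setNames(c(0.5, 0.5), c("11:01", "12:01"))
  sp1 <- population_spec("a", n_snps = 8, hla_freqs = f1)
  sp2 <- population_spec("b", n_snps = 8, hla_freqs = f2)
  p1 <- build_haplotype_pool(sp1, seed = 1)
  p2 <- build_haplotype_pool(sp2, seed = 2, snps = p1$snps)
  k1 <- paste(p1$haplo$hla, p1$haplo$snp)
  k2 <- paste(p2$haplo$hla, p2$haplo$snp)
  expect_length(intersect(k1, k2), 0)
})

test_that("cohorts are bit-identical under the same seed and differ otherwise", {
  sp <- population_spec("p", n_snps = 6, n_hla_alleles = 3,
                        haplotype_noise = 0.02)
  cs <- cohort_spec(list(list(spec = sp, n = 50)), missing_rate = 0.02,
                    seed = 99)
  c1 <- sample_cohort(cs)
  c2 <- sample_cohort(cs)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$genotypes$calls, c2$genotypes$calls)
  cs2 <- cs; cs2$seed <- 100L
  c3 <- sample_cohort(cs2)
  expect_false(identical(c1$truth, c3$truth))
})

test_that("observable genotypes are the allele-count sums of the truth haplotypes", {
  sp <- population_spec("p", n_snps = 7, n_hla_alleles = 3,
                        haplotype_noise = 0.1)
  co <- sample_cohort(cohort_spec(list(list(spec = sp, n = 100)), seed = 3))
  expect_identical(sum(is.na(co$genotypes$calls)), 0L)
  for (i in sample(100, 5)) {
    h1 <- as.integer(strsplit(co$truth$hap1[i], "")[[1]] == "b")
    h2 <- as.integer(strsplit(co$truth$hap2[i], "")[[1]] == "b")
    expect_identical(unname(co$genotypes$calls[co$truth$sample_id[i], ]),
                     h1 + h2)
  }
  # and the typing table mirrors the truth alleles
  expect_identical(co$typing$allele1, co$truth$hla1)
})

test_that("missingness lands near its nominal rate", {
  sp <- population_spec("p", n_snps = 50, n_hla_alleles = 3)
  co <- sample_cohort(cohort_spec(list(list(spec = sp, n = 200)),
                                  missing_rate = 0.05, seed = 8))
  frac <- mean(is.na(co$genotypes$calls))
  se <- sqrt(0.05 * 0.95 / (200 * 50))
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("simulated posteriors peak at the true genotype and sharpen with concentration", {
  sp <- population_spec("p", n_snps = 6, n_hla_alleles = 2)
  co <- sample_cohort(cohort_spec(list(list(spec = sp, n = 60)),
                                  posterior_mode = TRUE, posterior_conc = 200,
                                  seed = 4))
  p <- co$posteriors$p
  truth <- co$genotypes$calls
  hit <- 0
  for (i in seq_len(nrow(truth))) for (s in seq_len(ncol(truth))) {
    if (which.max(p[i, s, ]) - 1L == truth[i, s]) hit <- hit + 1
  }
  expect_gt(hit / length(truth), 0.99)
  # triples are valid probabilities
  expect_true(all(abs(p[, , 1] + p[, , 2] + p[, , 3] - 1) < 1e-9))
})

test_that("empirical haplotype frequencies converge to the pool at large n", {
  sp <- population_spec("p", n_snps = 6, n_hla_alleles = 3,
                        haplotype_noise = 0)
  co <- sample_cohort(cohort_spec(list(list(spec = sp, n = 5000)), seed = 12))
  pool <- co$pools[["p"]]
  emp <- table(c(paste(co$truth$hla1, co$truth$hap1),
                 paste(co$truth$hla2, co$truth$hap2))) / (2 * 5000)
  keys <- paste(pool$haplo$hla, pool$haplo$snp)
  emp_v <- as.numeric(emp[keys])
  emp_v[is.na(emp_v)] <- 0
  tv <- sum(abs(pool$haplo$freq - emp_v)) / 2
  expect_lt(tv, 0.02)
})

test_that("noise at one half makes SNP haplotypes uninformative about HLA", {
  f <- setNames(c(0.5, 0.5), c("01:01", "02:01"))
  sp <- population_spec("p", n_snps = 6, hla_freqs = f,
                        haplotype_noise = 0.5, pool_draws = 2000)
  pool <- build_haplotype_pool(sp, seed = 21)
  # mutual information between allele and haplotype is ~0: the conditional
  # allele distribution given any common haplotype stays near the prior
  agg <- tapply(pool$haplo$freq, pool$haplo$snp, sum)
  common <- names(agg)[agg > 0.005]
  for (h in common) {
    sub <- pool$haplo[pool$haplo$snp == h, ]
    p1 <- sum(sub$freq[sub$hla == "01:01"]) / sum(sub$freq)
    expect_lt(abs(p1 - 0.5), 0.25)
  }
})

test_that("admixed cohorts show the expected excess homozygosity", {
  f1 <- setNames(c(0.9, 0.1), c("01:01", "02:01"))
  f2 <- setNames(c(0.1, 0.9), c("01:01", "02:01"))
  sp1 <- population_spec("a", n_snps = 6, hla_freqs = f1, haplotype_noise = 0)
  sp2 <- population_spec("b", n_snps = 6, hla_freqs = f2, haplotype_noise = 0)
  co <- sample_cohort(cohort_spec(list(list(spec = sp1, n = 400),
                                       list(spec = sp2, n = 400)),
                                  seed = 31))
  a1 <- co$truth$hla1; a2 <- co$truth$hla2
  hom <- mean(a1 == a2)
  p <- mean(c(a1, a2) == "01:01")
  hw_hom <- p^2 + (1 - p)^2          # expected homozygosity under pooled HWE
  expect_gt(hom, hw_hom + 0.05)      # Wahlund excess
})

test_that("a model trained on half a perfect-tagging cohort predicts the other half exactly", {
  f <- setNames(rep(0.25, 4), sprintf("%02d:01", 1:4))
  sp <- population_spec("p", n_snps = 6, hla_freqs = f,
                        tags_per_allele = 1, haplotype_noise = 0)
  co <- sample_cohort(cohort_spec(list(list(spec = sp, n = 200)), seed = 44))
  h <- split_train_validate(co, 0.5, seed = 2)
  fit <- fit_em(h$train$genotypes, h$train$typing, "A", "high", seed = 1)
  calls <- predict_hla(fit$model, h$validate$genotypes, ct = 0)
  rep <- accuracy(calls, h$validate$typing)
  expect_equal(rep$acc_allele, 1)
  expect_equal(rep$call_rate, 1)
})
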