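.mk_calls <- function(a1, a2, called = TRUE, locus = "A",
                      resolution = "high", ct = 0) {
  df <- data.frame(sample_id = sprintf("s%d", seq_along(a1)),
                   allele1 = a1, allele2 = a2,
                   prob = 1, called = called, fallback = FALSE,
                   stringsAsFactors = FALSE)
  attr(df, "locus") <- locus
  attr(df, "resolution") <- resolution
  attr(df, "ct") <- ct
  class(df) <- c("hla_calls", "data.frame")
  df
}

test_that("per-allele accuracy pairs predicted and true alleles optimally", {
  # exact het match: 2/2
  calls <- .mk_calls("01:01", "02:01")
  typ <- toy_typing("s1", "01:01", "02:01")
  rep <- accuracy(calls, typ)
  expect_equal(rep$acc_allele, 1)
  expect_equal(rep$acc_sample, 1)

  # homozygous prediction vs het truth: best pairing gives 1/2, sample 0
  rep2 <- accuracy(.mk_calls("01:01", "01:01"), typ)
  expect_equal(rep2$acc_allele, 0.5)
  expect_equal(rep2$acc_sample, 0)

  # swapped order still matches fully (pairing is over both arrangements)
  rep3 <- accuracy(.mk_calls("02:01", "01:01"), typ)
  expect_equal(rep3$acc_allele, 1)

  # ambiguity credit: prediction hits one alternative of the truth set
  typ_amb <- toy_typing("s1", "02:01/02:05", "03:01")
  rep4 <- accuracy(.mk_calls("02:05", "03:01"), typ_amb)
  expect_equal(rep4$acc_allele, 1)
})

test_that("per-sample accuracy never exceeds per-allele accuracy", {
  set.seed(41)
  pool <- sprintf("%02d:01", 1:6)
  for (rep in 1:10) {
    n <- 25
    truth <- toy_typing(sprintf("s%d", 1:n),
                        sample(pool, n, TRUE), sample(pool, n, TRUE))
    calls <- .mk_calls(sample(pool, n, TRUE), sample(pool, n, TRUE))
    r <- accuracy(calls, truth)
    expect_lte(r$acc_sample, r$acc_allele + 1e-12)
  }
})

test_that("uncalled samples and samples without truth leave the denominators", {
  calls <- .mk_calls(c("01:01", "02:01", "03:01"),
                     c("01:01", "02:01", "03:01"),
                     called = c(TRUE, FALSE, TRUE))
  typ <- toy_typing(c("s1", "s3"), c("01:01", "04:01"), c("01:01", "04:01"))
  r <- accuracy(calls, typ)        # s2 has no truth row and is excluded
  expect_identical(r$n_evaluated, 2L)
  expect_identical(r$n_called, 2L)
  expect_equal(r$acc_allele, 0.5)  # s1 both right, s3 both wrong
})

test_that("intermediate-resolution scoring reduces 4-digit calls first", {
  calls <- .mk_calls("02:01", "03:01")
  typ <- toy_typing("s1", "A*02", "A*03")
  r <- accuracy(calls, typ, resolution = "intermediate")
  expect_equal(r$acc_allele, 1)
})

test_that("the frequency floor restricts denominators without changing matches", {
  calls <- .mk_calls(c("01:01", "02:01"), c("03:01", "04:01"))
  typ <- toy_typing(c("s1", "s2"), c("01:01", "02:01"), c("03:01", "05:01"))
  freqs <- c("01:01" = 0.40, "02:01" = 0.30, "03:01" = 0.05,
             "04:01" = 0.05, "05:01" = 0.004)
  r_all <- accuracy(calls, typ)
  expect_equal(r_all$acc_allele, 3 / 4)
  # only truth alleles with training frequency > 0.01 are scored:
  # s1 (01:01 matched), s2 (02:01 matched, 05:01 below floor and excluded)
  r_thr <- accuracy(calls, typ, min_allele_freq = 0.01, training_freqs = freqs)
  expect_identical(r_thr$n_alleles_scored, 3L)
  expect_equal(r_thr$acc_allele, 1)
  expect_error(accuracy(calls, typ, min_allele_freq = 0.01), "training_freqs")
})

test_that("kappa matches its closed-form cases and the contingency oracle", {
  expect_equal(kappa_stat(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  expect_equal(kappa_stat(c(0, 1), c(1, 0)), -1)
  x <- c(0, 0, 1, 1, 2, 2, 0, 1)
  y <- c(0, 0, 1, 2, 2, 2, 0, 1)
  expect_equal(kappa_stat(x, y), kappa_oracle(x, y))
  # symmetry and relabeling invariance
  expect_equal(kappa_stat(x, y), kappa_stat(y, x))
  relab <- function(v) c(2, 0, 1)[v + 1]
  expect_equal(kappa_stat(relab(x), relab(y)), kappa_stat(x, y))
  # degenerate conventions
  expect_equal(as.numeric(kappa_stat(c(1, 1), c(1, 1))), 1)
  k0 <- kappa_stat(c(1, 1), c(2, 2))
  expect_equal(as.numeric(k0), 0)
  expect_true(isTRUE(attr(k0, "degenerate")))
  # missing entries drop pairwise
  expect_equal(kappa_stat(c(x, NA), c(y, 0)), kappa_stat(x, y))
})

test_that("kappa equals the oracle on random vectors", {
  set.seed(57)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    x <- sample(0:2, n, TRUE)
    y <- ifelse(runif(n) < 0.8, x, sample(0:2, n, TRUE))
    expect_equal(kappa_stat(x, y), kappa_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("platform concordance pools pairs by source class", {
  set.seed(63)
  n <- 40; S <- 10
  calls <- matrix(sample(0:2, n * S, TRUE), n, S)
  meta <- snp_meta(sprintf("rs%d", 1:S))
  gt_a <- genotype_table(calls, meta, sprintf("s%d", 1:n))
  # identical tables, all observed: O-O kappa 1, no other genotype classes
  tags <- setNames(rep("observed", S), meta$snp_id)
  res <- platform_concordance(gt_a, gt_a, tags, tags)
  expect_setequal(res$class, c("O-O", "overall"))
  expect_equal(res$kappa[res$class == "O-O"], 1)

  # corrupt 5% of the second table; classes partition the overall pool
  calls_b <- calls
  flip <- sample(length(calls_b), round(0.05 * length(calls_b)))
  calls_b[flip] <- (calls_b[flip] + 1L) %% 3L
  gt_b <- genotype_table(calls_b, meta, sprintf("s%d", 1:n))
  tags_a <- setNames(rep(c("observed", "imputed"), each = S / 2), meta$snp_id)
  tags_b <- setNames(rep(c("observed", "imputed"), times = S / 2), meta$snp_id)
  res2 <- platform_concordance(gt_a, gt_b, tags_a, tags_b)
  by_class <- res2[res2$class != "overall", ]
  expect_identical(sum(by_class$n_pairs),
                   res2$n_pairs[res2$class == "overall"])
  # each pooled kappa equals the brute-force oracle on the pooled cells
  for (cl in by_class$class) {
    ids <- meta$snp_id[paste0(
      ifelse(tags_a == "observed", "O", "I"), "-",
      ifelse(tags_b == "observed", "O", "I")) == cl]
    expect_equal(res2$kappa[res2$class == cl],
                 kappa_oracle(as.vector(calls[, match(ids, meta$snp_id)]),
                              as.vector(calls_b[, match(ids, meta$snp_id)])),
                 tolerance = 1e-12, info = cl)
  }
})

test_that("platform concordance refuses unharmonized counted alleles", {
  meta <- snp_meta("rs1")
  gt_a <- genotype_table(matrix(1L, 2, 1), meta, c("s1", "s2"))
  meta_b <- meta
  meta_b$allele_a <- "G"; meta_b$allele_b <- "A"
  gt_b <- genotype_table(matrix(1L, 2, 1), meta_b, c("s1", "s2"))
  tags <- c(rs1 = "observed")
  expect_error(platform_concordance(gt_a, gt_b, tags, tags), "harmonize")
})
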