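#' @name qc
#' @title SNP quality control and hard-calling of imputed genotypes
#'
#' @description
#' Standard pre-modelling censoring of a SNP panel: minor allele frequency
#' (MAF) below a floor, missingness above a cap, and gross departure from
#' Hardy-Weinberg equilibrium (HWE, asymptotic 1-df chi-square test).
#' Defaults follow common GWAS practice for this problem: MAF >= 0.01,
#' missingness <= 0.05, HWE p >= 1e-20. Posterior-probability genotypes
#' from imputation are hard-called when the maximum posterior strictly
#' exceeds 0.8, then re-filtered on call rate (>= 95%) and MAF (>= 1%).
#' All filters are evaluated on the pre-filter table, so reports are
#' independent of filter ordering and filtering is idempotent.
NULL

#' Default QC thresholds
#'
#' @param maf_min minimum minor allele frequency for observed SNPs.
#' @param miss_max maximum missing fraction.
#' @param hwe_p_min minimum HWE p-value.
#' @param post_call_min posterior a genotype must exceed to be hard-called.
#' @param imputed_callrate_min minimum post-calling call rate for an
#'   imputed SNP.
#' @param imputed_maf_min minimum MAF for an imputed SNP after calling.
#' @return A list of thresholds (class `qc_thresholds`).
#' @export
qc_thresholds <- function(maf_min = 0.01, miss_max = 0.05, hwe_p_min = 1e-20,
                          post_call_min = 0.8, imputed_callrate_min = 0.95,
                          imputed_maf_min = 0.01) {
  th <- list(maf_min = maf_min, miss_max = miss_max, hwe_p_min = hwe_p_min,
             post_call_min = post_call_min,
             imputed_callrate_min = imputed_callrate_min,
             imputed_maf_min = imputed_maf_min)
  if (any(unlist(th) < 0 | unlist(th) > 1))
    stop_hla("all QC thresholds must lie in [0, 1]")
  structure(th, class = "qc_thresholds")
}

#' Minor allele frequency of one SNP column
#'
#' `min(p, 1 - p)` with `p` the allele-b frequency among non-missing calls.
#'
#' @param calls integer vector of allele-b counts (0/1/2/NA).
#' @export
snp_maf <- function(calls) {
  ok <- !is.na(calls)
  if (!any(ok)) stop_hla("MAF undefined: all calls missing")
  p <- sum(calls[ok]) / (2 * sum(ok))
  min(p, 1 - p)
}

#' Hardy-Weinberg equilibrium p-value
#'
#' Asymptotic 1-df chi-square goodness-of-fit test of the observed genotype
#' counts against HWE proportions at the observed allele frequency.
#' Monomorphic SNPs return p = 1 by convention.
#'
#' @param n0,n1,n2 counts of genotypes 0, 1 and 2.
#' @export
hwe_pvalue <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n < 1) stop_hla("HWE test needs at least one genotype")
  p <- (n1 + 2 * n2) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((c(n0, n1, n2) - e)^2 / e)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

.snp_qc_stats <- function(gt) {
  calls <- gt$calls
  n <- nrow(calls)
  miss <- colSums(is.na(calls)) / n
  maf <- hwe <- rep(NA_real_, ncol(calls))
  for (s in seq_len(ncol(calls))) {
    col <- calls[, s]
    ok <- !is.na(col)
    if (!any(ok)) next
    maf[s] <- snp_maf(col)
    hwe[s] <- hwe_pvalue(sum(col[ok] == 0L), sum(col[ok] == 1L),
                         sum(col[ok] == 2L))
  }
  data.frame(snp_id = gt$snps$snp_id, maf = maf, miss_frac = miss,
             hwe_p = hwe, stringsAsFactors = FALSE)
}

#' Censor a SNP panel
#'
#' Retains SNPs with MAF >= `maf_min`, missing fraction <= `miss_max` and
#' HWE p >= `hwe_p_min`. SNPs failing several filters are reported with all
#' triggered reasons, evaluated on the pre-filter table.
#'
#' @param gt a `genotype_table`.
#' @param th a `qc_thresholds` list.
#' @return A list with `genotypes` (filtered table; may have zero SNPs) and
#'   `report` (per-SNP statistics, pass flag and comma-joined reasons,
#'   with a `summary` attribute of pass/fail counts).
#' @export
filter_snps <- function(gt, th = qc_thresholds()) {
  stopifnot(inherits(gt, "genotype_table"))
  st <- .snp_qc_stats(gt)
  fail_maf <- is.na(st$maf) | st$maf < th$maf_min
  fail_miss <- st$miss_frac > th$miss_max
  fail_hwe <- !is.na(st$hwe_p) & st$hwe_p < th$hwe_p_min
  reasons <- mapply(function(a, b, c)
    paste(c(if (a) "maf", if (b) "missing", if (c) "hwe"), collapse = ","),
    fail_maf, fail_miss, fail_hwe)
  st$pass <- !(fail_maf | fail_miss | fail_hwe)
  st$reasons <- ifelse(st$pass, "", reasons)
  keep <- st$snp_id[st$pass]
  out <- if (length(keep)) subset_genotypes(gt, snps = keep) else {
    gt2 <- gt
    gt2$calls <- gt$calls[, integer(0), drop = FALSE]
    gt2$snps <- gt$snps[integer(0), , drop = FALSE]
    gt2
  }
  attr(st, "summary") <- c(n_snps = nrow(st), n_pass = sum(st$pass),
                           n_fail = sum(!st$pass))
  list(genotypes = out, report = st)
}

#' Hard-call imputed genotypes and filter the resulting SNPs
#'
#' Each cell is called to the argmax genotype when its posterior strictly
#' exceeds `post_call_min` (set `boundary = "inclusive"` for `>=`),
#' otherwise missing. SNPs are then removed when the call rate falls below
#' `imputed_callrate_min` or the post-calling MAF below `imputed_maf_min`,
#' both evaluated on the full called table.
#'
#' @param pt a `posterior_table`.
#' @param th a `qc_thresholds` list.
#' @param boundary how to treat a posterior exactly at `post_call_min`.
#' @return A list with `genotypes` (called + filtered `genotype_table`) and
#'   `report` (per-SNP call rate, MAF, pass flag and reasons).
#' @export
call_imputed <- function(pt, th = qc_thresholds(),
                         boundary = c("strict", "inclusive")) {
  stopifnot(inherits(pt, "posterior_table"))
  boundary <- match.arg(boundary)
  p <- pt$p
  n <- dim(p)[1]; S <- dim(p)[2]
  pm <- pmax(p[, , 1, drop = FALSE], p[, , 2, drop = FALSE],
             p[, , 3, drop = FALSE])[, , 1, drop = TRUE]
  pm <- matrix(pm, n, S)
  arg <- (p[, , 2] > p[, , 1]) + 0L
  arg[p[, , 3] > pmax(p[, , 1], p[, , 2])] <- 2L
  called <- if (boundary == "strict") pm > th$post_call_min else
    pm >= th$post_call_min
  calls <- matrix(NA_integer_, n, S)
  calls[called] <- as.integer(arg[called])
  gt <- genotype_table(calls, pt$snps, dimnames(p)[[1]],
                       sort_by_position = FALSE)
  callrate <- colSums(!is.na(calls)) / n
  maf <- vapply(seq_len(S), function(s) {
    col <- calls[, s]
    if (all(is.na(col))) NA_real_ else snp_maf(col)
  }, 0)
  fail_cr <- callrate < th$imputed_callrate_min
  fail_maf <- is.na(maf) | maf < th$imputed_maf_min
  report <- data.frame(snp_id = pt$snps$snp_id, call_rate = callrate,
                       maf = maf, pass = !(fail_cr | fail_maf),
                       stringsAsFactors = FALSE)
  report$reasons <- ifelse(report$pass, "", mapply(function(a, b)
    paste(c(if (a) "callrate", if (b) "maf"), collapse = ","),
    fail_cr, fail_maf))
  keep <- report$snp_id[report$pass]
  out <- if (length(keep)) subset_genotypes(gt, snps = keep) else {
    gt2 <- gt
    gt2$calls <- gt$calls[, integer(0), drop = FALSE]
    gt2$snps <- gt$snps[integer(0), , drop = FALSE]
    gt2
  }
  list(genotypes = out, report = report)
}
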