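#' @name evaluation
#' @title Prediction accuracy and cross-platform genotype concordance
#'
#' @description
#' Accuracy compares predicted HLA genotype pairs with known typings:
#' per-allele accuracy counts matched alleles over `2 x` called samples,
#' pairing predicted with true alleles so as to maximize matches (which
#' handles the homozygote/heterozygote asymmetry); per-sample accuracy is
#' the fraction of called samples with both alleles matched, and is never
#' larger. Ambiguous truth credits a match to any alternative; samples with
#' missing or unresolved truth are excluded from denominators. Accuracy can
#' be restricted to truth alleles whose training-set frequency exceeds a
#' floor, leaving individual match outcomes untouched.
#'
#' Cross-platform genotype agreement is quantified by Cohen's kappa,
#' `kappa = (Pr(a) - Pr(e)) / (1 - Pr(e))`, pooled over all SNP-sample
#' pairs within each observed/imputed source class (O-O, O-I, I-O, I-I)
#' rather than averaged over per-SNP kappas.
NULL

#' Prediction accuracy against known HLA typings
#'
#' @param calls an `hla_calls` data frame from [predict_hla()].
#' @param typing truth typing table; samples with missing truth are
#'   excluded.
#' @param resolution resolution to score at (predictions are reduced as
#'   needed; defaults to the calls' resolution).
#' @param min_allele_freq restrict the per-allele denominator to truth
#'   alleles whose training frequency strictly exceeds this value.
#' @param training_freqs named allele-key frequency vector (e.g.
#'   [hla_marginals()] of the training model); required when
#'   `min_allele_freq > 0`.
#' @return A list of class `accuracy_report`: counts, call rate, per-allele
#'   and per-sample accuracy.
#' @export
accuracy <- function(calls, typing, resolution = NULL, min_allele_freq = 0,
                     training_freqs = NULL) {
  locus <- attr(calls, "locus")
  resolution <- resolution %||% attr(calls, "resolution")
  resolution <- match.arg(resolution, c("high", "intermediate"))
  if (min_allele_freq > 0 && is.null(training_freqs))
    stop_hla("training_freqs required when min_allele_freq > 0")
  truth <- truth_key_sets(typing, locus, resolution, calls$sample_id)
  usable <- vapply(truth, is.list, TRUE)
  ev <- calls[usable, , drop = FALSE]
  tr <- truth[usable]
  n_eval <- nrow(ev)
  called <- ev$called
  n_called <- sum(called)
  if (!n_called) {
    rep <- structure(list(locus = locus, resolution = resolution,
                          ct = attr(calls, "ct"), n_evaluated = n_eval,
                          n_called = 0L, call_rate = 0,
                          acc_allele = NA_real_, acc_sample = NA_real_,
                          min_allele_freq = min_allele_freq,
                          n_alleles_scored = 0L, flagged = TRUE),
                     class = "accuracy_report")
    return(rep)
  }
  pred1 <- ev$allele1; pred2 <- ev$allele2
  if (resolution == "intermediate") {
    pred1 <- reduce_key(pred1); pred2 <- reduce_key(pred2)
  }
  matched_total <- 0L
  denom_total <- 0L
  both <- logical(n_called)
  j <- 0L
  for (i in seq_len(n_eval)) {
    if (!called[i]) next
    j <- j + 1L
    t <- tr[[i]]
    m11 <- pred1[i] %in% t$s1; m12 <- pred1[i] %in% t$s2
    m21 <- pred2[i] %in% t$s1; m22 <- pred2[i] %in% t$s2
    # two pairings of predicted to true slots; keep the better
    a <- c(m11, m22)
    b <- c(m12, m21)          # b[1]: slot2 matched, b[2]: slot1 matched
    use_a <- sum(a) >= sum(b)
    slot_matched <- if (use_a) c(a[1], a[2]) else c(b[2], b[1])
    both[j] <- all(slot_matched)
    if (min_allele_freq > 0) {
      fr1 <- .truth_slot_freq(t$s1, training_freqs)
      fr2 <- .truth_slot_freq(t$s2, training_freqs)
      inc <- c(fr1 > min_allele_freq, fr2 > min_allele_freq)
    } else inc <- c(TRUE, TRUE)
    denom_total <- denom_total + sum(inc)
    matched_total <- matched_total + sum(slot_matched & inc)
  }
  structure(list(locus = locus, resolution = resolution,
                 ct = attr(calls, "ct"), n_evaluated = n_eval,
                 n_called = n_called, call_rate = n_called / n_eval,
                 acc_allele = if (denom_total) matched_total / denom_total
                              else NA_real_,
                 acc_sample = mean(both),
                 min_allele_freq = min_allele_freq,
                 n_alleles_scored = denom_total, flagged = FALSE),
            class = "accuracy_report")
}

# frequency of a (possibly ambiguous) truth slot: the maximum training
# frequency over its alternatives; alleles unseen in training count as 0.
.truth_slot_freq <- function(keys, freqs) {
  f <- freqs[keys]
  f[is.na(f)] <- 0
  max(f)
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("accuracy_report: HLA-", x$locus, " (", x$resolution, "), CT = ",
      x$ct, "\n  called ", x$n_called, "/", x$n_evaluated,
      " (call rate ", sprintf("%.3f", x$call_rate), ")\n", sep = "")
  cat("  per-allele accuracy: ",
      if (is.na(x$acc_allele)) "undefined" else sprintf("%.4f", x$acc_allele),
      if (x$min_allele_freq > 0)
        paste0(" (truth alleles with training freq > ", x$min_allele_freq, ")"),
      "\n  per-sample accuracy: ",
      if (is.na(x$acc_sample)) "undefined" else sprintf("%.4f", x$acc_sample),
      "\n", sep = "")
  invisible(x)
}

#' Cohen's kappa for genotype agreement
#'
#' `kappa = (Pr(a) - Pr(e)) / (1 - Pr(e))` with `Pr(e)` the chance
#' agreement from the two marginal category distributions. Pairs with a
#' missing value on either side are dropped first. When both vectors are
#' constant: equal constants give 1, different give 0 (flagged via the
#' `"degenerate"` attribute).
#'
#' @param x,y equal-length genotype vectors with categories 0/1/2 (NA
#'   allowed, dropped pairwise).
#' @export
kappa_stat <- function(x, y) {
  if (length(x) != length(y)) stop_hla("vectors differ in length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (!length(x)) stop_hla("no complete pairs")
  pa <- mean(x == y)
  if (length(unique(x)) == 1L && length(unique(y)) == 1L) {
    k <- if (pa == 1) 1 else 0
    attr(k, "degenerate") <- TRUE
    return(k)
  }
  cats <- union(unique(x), unique(y))
  px <- vapply(cats, function(c) mean(x == c), 0)
  py <- vapply(cats, function(c) mean(y == c), 0)
  pe <- sum(px * py)
  if (pe >= 1) {
    k <- if (pa == 1) 1 else 0
    attr(k, "degenerate") <- TRUE
    return(k)
  }
  (pa - pe) / (1 - pe)
}

#' Pooled observed/imputed concordance between two platforms
#'
#' Genotype calls from two platform views of the same samples are pooled
#' into classes by the per-SNP source on each side — observed on both
#' (O-O), observed on one and imputed on the other (O-I / I-O), imputed on
#' both (I-I) — plus the overall pool, and Cohen's kappa is computed per
#' pooled class. Only SNPs present on both sides (after intersection) are
#' compared; cells missing on either side are excluded pairwise. The
#' counted allele must be identical per SNP on both sides; mismatches are
#' an error, not a silent strand flip.
#'
#' @param gt_a,gt_b `genotype_table`s sharing samples and SNP ids.
#' @param tags_a,tags_b named character vectors (snp_id ->
#'   `"observed"`/`"imputed"`) for each side.
#' @return Data frame with one row per non-empty class (`class`,
#'   `n_pairs`, `kappa`); classes with no pairs are absent.
#' @export
platform_concordance <- function(gt_a, gt_b, tags_a, tags_b) {
  shared_s <- intersect(rownames(gt_a$calls), rownames(gt_b$calls))
  shared_snp <- intersect(gt_a$snps$snp_id, gt_b$snps$snp_id)
  if (!length(shared_s) || !length(shared_snp))
    stop_hla("no shared samples or SNPs between platforms")
  a <- subset_genotypes(gt_a, samples = shared_s, snps = shared_snp)
  b <- subset_genotypes(gt_b, samples = shared_s, snps = shared_snp)
  bad <- a$snps$allele_b != b$snps$allele_b[match(a$snps$snp_id, b$snps$snp_id)]
  if (any(bad))
    stop_hla("counted allele differs between platforms at: ",
             paste(a$snps$snp_id[bad], collapse = ", "),
             " — harmonize orientation first")
  ids <- a$snps$snp_id
  ta <- tags_a[ids]; tb <- tags_b[ids]
  if (any(is.na(ta)) || any(is.na(tb)))
    stop_hla("source tags missing for some shared SNPs")
  cls <- paste0(ifelse(ta == "observed", "O", "I"), "-",
                ifelse(tb == "observed", "O", "I"))
  xa <- a$calls[, ids, drop = FALSE]
  xb <- b$calls[match(rownames(a$calls), rownames(b$calls)), ids, drop = FALSE]
  out <- list()
  for (cl in c("O-O", "O-I", "I-O", "I-I")) {
    cols <- which(cls == cl)
    if (!length(cols)) next
    x <- as.vector(xa[, cols]); y <- as.vector(xb[, cols])
    ok <- !is.na(x) & !is.na(y)
    if (!any(ok)) next
    out[[cl]] <- data.frame(class = cl, n_pairs = sum(ok),
                            kappa = as.numeric(kappa_stat(x, y)),
                            stringsAsFactors = FALSE)
  }
  x <- as.vector(xa); y <- as.vector(xb)
  ok <- !is.na(x) & !is.na(y)
  out[["overall"]] <- data.frame(class = "overall", n_pairs = sum(ok),
                                 kappa = as.numeric(kappa_stat(x, y)),
                                 stringsAsFactors = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
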