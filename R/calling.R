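#' @name calling
#' @title Confidence-threshold HLA genotype calling
#'
#' @description
#' The unordered HLA genotype pair with the maximum posterior probability
#' is the call; it is emitted when that probability strictly exceeds the
#' confidence threshold (CT). At CT = 0 every sample is called — including
#' prior-fallback samples — so the call rate is 100%; raising CT trades
#' call rate for accuracy and never changes which pair is best.
NULL

#' Call one sample from its posterior
#'
#' @param posterior named numeric vector over unordered pair keys
#'   `"h1/h2"` (as returned by [posterior_hla()]), summing to 1.
#' @param ct confidence threshold in `[0, 1)`.
#' @param sample_id optional id carried into the result.
#' @return One-row data frame: `sample_id`, `allele1`, `allele2`, `prob`,
#'   `called`, `fallback`.
#' @export
call_sample <- function(posterior, ct = 0, sample_id = NA_character_) {
  if (!length(posterior)) stop_hla("empty posterior")
  if (ct < 0 || ct >= 1) stop_hla("ct must lie in [0, 1)")
  ord <- order(-posterior, names(posterior))
  best <- names(posterior)[ord[1]]
  prob <- unname(posterior[ord[1]])
  pair <- strsplit(best, "/", fixed = TRUE)[[1]]
  called <- if (ct == 0) TRUE else prob > ct
  data.frame(sample_id = sample_id, allele1 = pair[1], allele2 = pair[2],
             prob = prob, called = called,
             fallback = isTRUE(attr(posterior, "fallback")),
             stringsAsFactors = FALSE)
}

#' Predict HLA genotypes for a cohort
#'
#' @param model a fitted `haplotype_model`.
#' @param genotypes a `genotype_table` of the samples to predict.
#' @param ct confidence threshold.
#' @return Data frame of per-sample calls (class `hla_calls`), one row per
#'   sample, with the locus and resolution as attributes.
#' @export
predict_hla <- function(model, genotypes, ct = 0) {
  geno <- align_genotypes(model, genotypes)
  sigs <- dedupe_signatures(geno)
  posts <- vector("list", nrow(sigs$sig_geno))
  for (k in seq_len(nrow(sigs$sig_geno)))
    posts[[k]] <- posterior_hla(model, sigs$sig_geno[k, ])
  rows <- lapply(seq_len(nrow(geno)), function(i)
    call_sample(posts[[sigs$map[i]]], ct, rownames(geno)[i]))
  out <- do.call(rbind, rows)
  attr(out, "locus") <- model$locus
  attr(out, "resolution") <- model$resolution
  attr(out, "ct") <- ct
  class(out) <- c("hla_calls", "data.frame")
  out
}

#' Call rate of a set of predictions
#'
#' @param calls an `hla_calls` data frame (or anything with a logical
#'   `called` column).
#' @return Fraction of samples called.
#' @export
call_rate <- function(calls) {
  if (!nrow(calls)) stop_hla("no prediction results")
  mean(calls$called)
}
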