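#' @name haplotype_model_module
#' @title Joint (HLA allele, SNP haplotype) frequency models
#'
#' @description
#' The statistical core. A model for one HLA locus and resolution holds an
#' ordered SNP list and a frequency table over joint haplotypes — an HLA
#' allele together with a string of SNP alleles (`a`/`b`) carried on the
#' same chromosome copy. Under Hardy-Weinberg random pairing the likelihood
#' of a sample's unphased data is the sum of `f_g * f_g'` over all ordered
#' haplotype pairs `(g, g')` that explain its genotypes; frequencies are
#' estimated by expectation-maximization (EM), and HLA genotype posteriors
#' for new samples follow by conditioning on the SNP genotypes alone.
#'
#' The haplotype space is never enumerated exhaustively: models grow one
#' SNP at a time ([extend_model()]), each extension splitting every
#' retained haplotype into at most two children followed by EM re-estimation
#' and pruning of haplotypes below `prune_eps`. Missing SNP genotypes are
#' marginalized, not imputed.
NULL

#' Construct a haplotype model
#'
#' @param locus HLA locus.
#' @param resolution `"high"` (4-digit) or `"intermediate"` (2-digit).
#' @param snps ordered SNP metadata data frame (may have zero rows).
#' @param haplo data frame with columns `hla` (allele key), `snp` (string
#'   over `a`/`b`, `""` for a zero-SNP model) and `freq`.
#' @param n_train number of training samples behind the frequencies.
#' @param prune_eps haplotype-frequency pruning threshold.
#' @return An object of class `haplotype_model`.
#' @export
haplotype_model <- function(locus, resolution, snps, haplo, n_train = 0L,
                            prune_eps = 1e-5) {
  if (!locus %in% .hla_loci) stop_hla("unknown HLA locus: ", locus)
  resolution <- match.arg(resolution, c("high", "intermediate"))
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  haplo <- as.data.frame(haplo, stringsAsFactors = FALSE)
  if (!all(c("hla", "snp", "freq") %in% names(haplo)))
    stop_hla("haplo must have columns hla, snp, freq")
  haplo$snp[is.na(haplo$snp)] <- ""
  if (nrow(haplo) == 0L) stop_hla("a model needs at least one haplotype")
  if (any(nchar(haplo$snp) != nrow(snps)))
    stop_hla("haplotype SNP strings must have length ", nrow(snps))
  if (any(haplo$freq < 0)) stop_hla("negative haplotype frequency")
  s <- sum(haplo$freq)
  if (abs(s - 1) > 1e-8)
    stop_hla("haplotype frequencies sum to ", format(s), ", not 1")
  haplo$freq <- haplo$freq / s
  key <- paste(haplo$hla, haplo$snp, sep = "#")
  if (anyDuplicated(key)) stop_hla("duplicate joint haplotype in model")
  rownames(haplo) <- NULL
  rownames(snps) <- NULL
  structure(list(locus = locus, resolution = resolution, snps = snps,
                 haplo = haplo, n_train = as.integer(n_train),
                 prune_eps = prune_eps),
            class = "haplotype_model")
}

#' @export
print.haplotype_model <- function(x, ...) {
  cat("haplotype_model: HLA-", x$locus, " (", x$resolution, " resolution)\n",
      "  ", nrow(x$snps), " SNPs, ", nrow(x$haplo), " joint haplotypes, ",
      length(unique(x$haplo$hla)), " HLA alleles, n_train = ", x$n_train,
      "\n", sep = "")
  invisible(x)
}

# ---- truth handling -------------------------------------------------------

# Extract per-sample truth alternative sets (allele keys at the model
# resolution) from a typing table. Returns a named list of
# list(s1 = keys, s2 = keys), or NA entries for missing/unusable truth.
truth_key_sets <- function(typing, locus, resolution, sample_ids) {
  rows <- typing[typing$locus == locus, , drop = FALSE]
  idx <- match(sample_ids, rows$sample_id)
  out <- vector("list", length(sample_ids))
  names(out) <- sample_ids
  for (i in seq_along(sample_ids)) {
    r <- idx[i]
    if (is.na(r) || is.na(rows$allele1[r]) || is.na(rows$allele2[r])) {
      out[[i]] <- NA
      next
    }
    s1 <- tryCatch(.set_keys(rows$allele1[r], locus, resolution),
                   error = function(e) NULL)
    s2 <- tryCatch(.set_keys(rows$allele2[r], locus, resolution),
                   error = function(e) NULL)
    out[[i]] <- if (is.null(s1) || is.null(s2)) NA else list(s1 = s1, s2 = s2)
  }
  out
}

.set_keys <- function(text, locus, resolution) {
  set <- parse_allele_set(text, locus)
  keys <- vapply(unclass(set), allele_key, "")
  if (resolution == "intermediate") return(unique(reduce_key(keys)))
  if (allele_resolution(set[[1]]) == "intermediate")
    stop_hla("truth at intermediate resolution cannot train a high-resolution model")
  unique(keys)
}

# ---- alignment ------------------------------------------------------------

# Align a genotype table's calls to a model's SNP order. SNPs absent from
# the table become all-missing columns; counted-allele orientation is
# checked and flipped where allele_a/allele_b are swapped, any other
# mismatch errors (strand harmonization is the caller's job).
align_genotypes <- function(model, gt) {
  stopifnot(inherits(gt, "genotype_table"))
  S <- nrow(model$snps)
  n <- nrow(gt$calls)
  out <- matrix(NA_integer_, n, S,
                dimnames = list(rownames(gt$calls), model$snps$snp_id))
  if (!S) return(out)
  idx <- match(model$snps$snp_id, gt$snps$snp_id)
  for (s in seq_len(S)) {
    j <- idx[s]
    if (is.na(j)) next
    same <- gt$snps$allele_a[j] == model$snps$allele_a[s] &&
      gt$snps$allele_b[j] == model$snps$allele_b[s]
    flipped <- gt$snps$allele_a[j] == model$snps$allele_b[s] &&
      gt$snps$allele_b[j] == model$snps$allele_a[s]
    if (same) {
      out[, s] <- gt$calls[, j]
    } else if (flipped) {
      out[, s] <- 2L - gt$calls[, j]
    } else {
      stop_hla("allele mismatch at ", model$snps$snp_id[s],
               ": model counts ", model$snps$allele_b[s], ", table counts ",
               gt$snps$allele_b[j], " — harmonize orientation first")
    }
  }
  out
}

# ---- exported operations --------------------------------------------------

#' Enumerate haplotype pairs compatible with one sample
#'
#' Returns every ordered joint-haplotype pair that explains the sample's
#' unphased SNP genotypes (allele counts add up at each non-missing SNP)
#' and, if supplied, its unphased HLA genotype. Pair weights are the
#' products of model frequencies; an empty result marks a zero-likelihood
#' sample.
#'
#' @param model a `haplotype_model`.
#' @param snp_genotypes integer vector of allele-b counts aligned to
#'   `model$snps` (NA = missing, no constraint).
#' @param hla optional unphased HLA truth: a character vector of length 2
#'   of allele keys, or a list `list(s1 =, s2 =)` of alternative key sets.
#' @return Data frame with columns `hla1`, `snp1`, `hla2`, `snp2`, `weight`.
#' @export
enumerate_compatible_pairs <- function(model, snp_genotypes, hla = NULL) {
  g <- .check_geno_vector(model, snp_genotypes)
  code <- snp_code_matrix(model$haplo$snp)
  pairs <- compatible_pair_idx(code, g)
  if (!is.null(hla)) {
    if (is.character(hla) && length(hla) == 2L)
      hla <- list(s1 = hla[1], s2 = hla[2])
    pairs <- filter_pairs_hla(pairs, model$haplo$hla, hla$s1, hla$s2)
  }
  data.frame(hla1 = model$haplo$hla[pairs[, 1]],
             snp1 = model$haplo$snp[pairs[, 1]],
             hla2 = model$haplo$hla[pairs[, 2]],
             snp2 = model$haplo$snp[pairs[, 2]],
             weight = model$haplo$freq[pairs[, 1]] * model$haplo$freq[pairs[, 2]],
             stringsAsFactors = FALSE)
}

.check_geno_vector <- function(model, g) {
  S <- nrow(model$snps)
  g <- as.integer(g)
  if (length(g) != S)
    stop_hla("genotype vector has length ", length(g), ", model has ", S, " SNPs")
  bad <- !is.na(g) & !(g %in% 0:2)
  if (any(bad)) stop_hla("genotypes must be 0, 1, 2 or NA")
  g
}

#' Fit a haplotype model by EM from unphased training data
#'
#' Frequencies over joint (HLA allele, SNP haplotype) configurations are
#' estimated by maximizing the unphased-genotype likelihood
#' `L = prod_i sum_{(g,g') compatible with i} f_g f_g'` by EM. The model is
#' grown one SNP at a time in genomic order: each extension splits retained
#' haplotypes into `a`/`b` children (warm-started proportional to the new
#' SNP's allele frequency, with a small seeded Dirichlet jitter to escape
#' symmetric saddles), runs EM to convergence, and prunes haplotypes below
#' `prune_eps` — re-admitting at the floor any haplotype a training sample
#' still needs. The observed-data log-likelihood is non-decreasing within
#' every EM stage; the fit is deterministic given `seed` and invariant to
#' sample order.
#'
#' @param genotypes a `genotype_table` holding the training SNPs.
#' @param typing HLA typing data frame (see [read_hla_typing()]); every
#'   training sample must have non-missing truth at `locus`.
#' @param locus HLA locus to model.
#' @param resolution `"high"` or `"intermediate"`.
#' @param snp_ids SNPs to use, in any order (fitted in position order);
#'   default all SNPs in `genotypes`. May be empty for an HLA-only model.
#' @param max_iter,tol EM controls: iteration cap and per-sample
#'   log-likelihood gain threshold.
#' @param prune_eps haplotype pruning threshold.
#' @param seed integer seed for the initialization jitter.
#' @return A list with components `model` (the fitted `haplotype_model`)
#'   and `diagnostics` (per-stage log-likelihood traces, iteration count,
#'   convergence flag).
#' @export
fit_em <- function(genotypes, typing, locus, resolution = c("high", "intermediate"),
                   snp_ids = NULL, max_iter = 500L, tol = 1e-6,
                   prune_eps = 1e-5, seed = 1L) {
  resolution <- match.arg(resolution)
  stopifnot(inherits(genotypes, "genotype_table"))
  sample_ids <- rownames(genotypes$calls)
  truth <- truth_key_sets(typing, locus, resolution, sample_ids)
  bad <- vapply(truth, function(t) !is.list(t), TRUE)
  if (any(bad))
    stop_hla("missing or unusable HLA truth at ", locus, " for: ",
             paste(utils::head(sample_ids[bad], 5), collapse = ", "))
  if (is.null(snp_ids)) snp_ids <- genotypes$snps$snp_id
  miss <- setdiff(snp_ids, genotypes$snps$snp_id)
  if (length(miss)) stop_hla("unknown snp ids: ", paste(miss, collapse = ", "))
  meta <- genotypes$snps[match(snp_ids, genotypes$snps$snp_id), , drop = FALSE]
  ord <- order(meta$position, meta$snp_id)
  meta <- meta[ord, , drop = FALSE]
  geno <- genotypes$calls[, meta$snp_id, drop = FALSE]

  # stage 0: HLA-only model over alleles seen in the truth alternatives
  alleles <- sort(unique(unlist(lapply(truth, function(t) c(t$s1, t$s2)))))
  haplo <- data.frame(hla = alleles, snp = "", freq = NA_real_,
                      stringsAsFactors = FALSE)
  empty_geno <- geno[, integer(0), drop = FALSE]
  sigs <- dedupe_signatures(empty_geno, truth)
  pl <- build_pairlists(snp_code_matrix(haplo$snp), haplo$hla, sigs)
  f0 <- init_frequencies(pl, sigs$weight, nrow(haplo), seed)
  fit <- em_run(pl, sigs$weight, nrow(haplo), f0, max_iter, tol)
  haplo$freq <- fit$f
  stages <- list(fit$loglik)
  iters <- fit$iters
  converged <- fit$converged

  snp_meta_now <- meta[integer(0), , drop = FALSE]
  for (s in seq_len(nrow(meta))) {
    ext <- .extend_and_fit(haplo, snp_meta_now, meta[s, , drop = FALSE],
                           geno[, seq_len(s), drop = FALSE], truth,
                           max_iter, tol, prune_eps, seed + s)
    haplo <- ext$haplo
    snp_meta_now <- ext$snps
    stages <- c(stages, list(ext$loglik))
    iters <- iters + ext$iters
    converged <- ext$converged
  }
  model <- haplotype_model(locus, resolution, snp_meta_now, haplo,
                           n_train = nrow(geno), prune_eps = prune_eps)
  diagnostics <- list(loglik = stages[[length(stages)]], stages = stages,
                      iterations = iters, converged = converged)
  list(model = model, diagnostics = diagnostics)
}

# Split every haplotype on a new SNP (inserted in position order), jitter,
# EM to convergence, prune with coverage guard. geno columns must align to
# the post-insertion SNP order. Internal; extend_model is the public face.
.extend_and_fit <- function(haplo, snps_now, new_snp, geno, truth,
                            max_iter, tol, prune_eps, seed) {
  at <- findInterval(new_snp$position, snps_now$position) # children insert after `at` existing SNPs
  snps_new <- rbind(
    if (at > 0) snps_now[seq_len(at), , drop = FALSE],
    new_snp,
    if (at < nrow(snps_now)) snps_now[(at + 1):nrow(snps_now), , drop = FALSE])
  rownames(snps_new) <- NULL
  # allele-b frequency of the new SNP for the warm-start split
  newcol <- geno[, at + 1L]
  pb <- if (all(is.na(newcol))) 0.5 else mean(newcol, na.rm = TRUE) / 2
  pb <- min(max(pb, 1e-6), 1 - 1e-6)
  ins <- function(str, ch) paste0(substr(str, 1, at), ch,
                                  substr(str, at + 1L, nchar(str)))
  child <- data.frame(
    hla = rep(haplo$hla, each = 2L),
    snp = as.vector(rbind(ins(haplo$snp, "a"), ins(haplo$snp, "b"))),
    freq = as.vector(rbind(haplo$freq * (1 - pb), haplo$freq * pb)),
    stringsAsFactors = FALSE)
  H <- nrow(child)
  jit <- with_seed(seed, rdirichlet1(rep(1, H)))
  f0 <- 0.98 * child$freq + 0.02 * jit
  f0 <- f0 / sum(f0)
  sigs <- dedupe_signatures(geno, truth)
  pl <- build_pairlists(snp_code_matrix(child$snp), child$hla, sigs)
  if (any(vapply(pl, nrow, 1L) == 0L))
    stop_hla("training sample incompatible with the split haplotype space")
  fit <- em_run(pl, sigs$weight, H, f0, max_iter, tol)
  pruned <- prune_with_coverage(fit$f, prune_eps, pl)
  haplo_out <- child[pruned$keep, , drop = FALSE]
  haplo_out$freq <- pruned$f[pruned$keep]
  rownames(haplo_out) <- NULL
  list(haplo = haplo_out, snps = snps_new, loglik = fit$loglik,
       iters = fit$iters, converged = fit$converged)
}

#' Extend a fitted model by one SNP
#'
#' Each retained haplotype splits into at most two children (suffix `a`/`b`
#' at the new SNP, inserted in genomic order); child frequencies are
#' re-estimated by EM warm-started from the parent frequency split
#' proportional to the new SNP's allele frequency, then pruned.
#'
#' @param model a fitted `haplotype_model`.
#' @param new_snp one-row SNP metadata data frame (not already in the model).
#' @param genotypes training `genotype_table` containing the model's SNPs
#'   and `new_snp`.
#' @param typing training HLA typing table.
#' @inheritParams fit_em
#' @return The extended `haplotype_model`.
#' @export
extend_model <- function(model, new_snp, genotypes, typing,
                         max_iter = 500L, tol = 1e-6, seed = 1L) {
  new_snp <- as.data.frame(new_snp, stringsAsFactors = FALSE)
  if (new_snp$snp_id %in% model$snps$snp_id)
    stop_hla("SNP ", new_snp$snp_id, " is already in the model")
  sample_ids <- rownames(genotypes$calls)
  truth <- truth_key_sets(typing, model$locus, model$resolution, sample_ids)
  at <- findInterval(new_snp$position, model$snps$position)
  ids_new <- append(model$snps$snp_id, new_snp$snp_id, after = at)
  gt_sub <- subset_genotypes(genotypes, snps = c(model$snps$snp_id, new_snp$snp_id))
  tmp_model <- model
  tmp_model$snps <- gt_sub$snps # aligned superset in position order
  geno <- align_genotypes(tmp_model, gt_sub)[, ids_new, drop = FALSE]
  ext <- .extend_and_fit(model$haplo, model$snps, new_snp, geno, truth,
                         max_iter, tol, model$prune_eps, seed)
  haplotype_model(model$locus, model$resolution, ext$snps, ext$haplo,
                  n_train = nrow(geno), prune_eps = model$prune_eps)
}

#' Remove a SNP from a model by marginalization
#'
#' Haplotypes identical except at the dropped SNP merge with summed
#' frequencies. If training data are supplied the merged model is then
#' re-estimated by EM.
#'
#' @param model a `haplotype_model`.
#' @param snp_id SNP to drop.
#' @param genotypes,typing optional training data for the refit.
#' @inheritParams fit_em
#' @return The reduced `haplotype_model`.
#' @export
drop_snp <- function(model, snp_id, genotypes = NULL, typing = NULL,
                     max_iter = 500L, tol = 1e-6, seed = 1L) {
  s <- match(snp_id, model$snps$snp_id)
  if (is.na(s)) stop_hla("SNP ", snp_id, " is not in the model")
  strip <- function(str) paste0(substr(str, 1, s - 1L),
                                substr(str, s + 1L, nchar(str)))
  h <- model$haplo
  h$snp <- strip(h$snp)
  agg <- stats::aggregate(freq ~ hla + snp, data = h, FUN = sum)
  snps_new <- model$snps[-s, , drop = FALSE]
  rownames(snps_new) <- NULL
  out <- haplotype_model(model$locus, model$resolution, snps_new,
                         agg[order(agg$hla, agg$snp), , drop = FALSE],
                         n_train = model$n_train, prune_eps = model$prune_eps)
  if (is.null(genotypes)) return(out)
  sample_ids <- rownames(genotypes$calls)
  truth <- truth_key_sets(typing, model$locus, model$resolution, sample_ids)
  geno <- align_genotypes(out, genotypes)
  sigs <- dedupe_signatures(geno, truth)
  pl <- build_pairlists(snp_code_matrix(out$haplo$snp), out$haplo$hla, sigs)
  if (any(vapply(pl, nrow, 1L) == 0L))
    stop_hla("training sample incompatible with the marginalized model")
  fit <- em_run(pl, sigs$weight, nrow(out$haplo), out$haplo$freq, max_iter, tol)
  pruned <- prune_with_coverage(fit$f, model$prune_eps, pl)
  haplo2 <- out$haplo[pruned$keep, , drop = FALSE]
  haplo2$freq <- pruned$f[pruned$keep]
  haplotype_model(model$locus, model$resolution, snps_new, haplo2,
                  n_train = nrow(geno), prune_eps = model$prune_eps)
}

#' HLA genotype posterior for one sample
#'
#' The probability of the unordered HLA pair `{h1, h2}` is proportional to
#' the summed weights of compatible joint-haplotype pairs carrying it. A
#' sample whose SNP genotypes no retained haplotype pair can explain falls
#' back to the Hardy-Weinberg prior implied by the model's marginal HLA
#' frequencies, flagged via the `"fallback"` attribute — prediction never
#' fails.
#'
#' @inheritParams enumerate_compatible_pairs
#' @return Named numeric vector over unordered pair keys `"h1/h2"`
#'   (keys sorted within a pair), summing to 1, with attribute `fallback`.
#' @export
posterior_hla <- function(model, snp_genotypes) {
  g <- .check_geno_vector(model, snp_genotypes)
  code <- snp_code_matrix(model$haplo$snp)
  pairs <- compatible_pair_idx(code, g)
  f <- model$haplo$freq
  hk <- model$haplo$hla
  if (nrow(pairs)) {
    w <- f[pairs[, 1]] * f[pairs[, 2]]
    tot <- sum(w)
  } else tot <- 0
  if (tot <= 0) {
    marg <- rowsum(f, hk)
    p <- as.numeric(marg)
    names(p) <- rownames(marg)
    keys <- names(p)
    k <- length(keys)
    i1 <- rep(seq_len(k), times = k:1)
    i2 <- unlist(lapply(seq_len(k), function(i) i:k))
    prob <- ifelse(i1 == i2, p[i1]^2, 2 * p[i1] * p[i2])
    names(prob) <- paste(keys[i1], keys[i2], sep = "/")
    prob <- prob / sum(prob)
    attr(prob, "fallback") <- TRUE
    return(prob)
  }
  h1 <- hk[pairs[, 1]]
  h2 <- hk[pairs[, 2]]
  key <- ifelse(h1 <= h2, paste(h1, h2, sep = "/"), paste(h2, h1, sep = "/"))
  agg <- rowsum(w, key)
  prob <- as.numeric(agg) / tot
  names(prob) <- rownames(agg)
  attr(prob, "fallback") <- FALSE
  prob
}

#' Conditional negative log-likelihood of HLA truth given SNP genotypes
#'
#' `-sum_i log P(truth_i | SNPs_i, model)`; ambiguous truth contributes the
#' posterior mass summed over all pairs formable from its alternative sets,
#' prior-fallback samples contribute through the prior. Probabilities are
#' floored at 1e-300 before the log.
#'
#' @param model a `haplotype_model`.
#' @param genotypes a `genotype_table` (aligned/harmonized to the model).
#' @param typing HLA typing table with truth for every sample.
#' @return A single number (sum over samples).
#' @export
conditional_nll <- function(model, genotypes, typing) {
  sample_ids <- rownames(genotypes$calls)
  truth <- truth_key_sets(typing, model$locus, model$resolution, sample_ids)
  bad <- vapply(truth, function(t) !is.list(t), TRUE)
  if (any(bad))
    stop_hla("missing HLA truth for: ",
             paste(utils::head(sample_ids[bad], 5), collapse = ", "))
  geno <- align_genotypes(model, genotypes)
  sigs <- dedupe_signatures(geno, truth)
  nll <- 0
  for (k in seq_len(nrow(sigs$sig_geno))) {
    post <- posterior_hla(model, sigs$sig_geno[k, ])
    t <- sigs$sig_truth[[k]]
    cmb <- expand.grid(x = t$s1, y = t$s2, stringsAsFactors = FALSE)
    keys <- unique(ifelse(cmb$x <= cmb$y,
                          paste(cmb$x, cmb$y, sep = "/"),
                          paste(cmb$y, cmb$x, sep = "/")))
    mass <- sum(post[names(post) %in% keys])
    nll <- nll - sigs$weight[k] * log(max(mass, 1e-300))
  }
  nll
}

#' Marginal HLA allele frequencies of a model
#' @param model a `haplotype_model`.
#' @return Named numeric vector of allele-key frequencies.
#' @export
hla_marginals <- function(model) {
  m <- rowsum(model$haplo$freq, model$haplo$hla)
  out <- as.numeric(m)
  names(out) <- rownames(m)
  out
}
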