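#' @name experiments
#' @title Re-enactments of the four evaluation designs on synthetic cohorts
#'
#' @description
#' Scripted versions of the method's standard evaluation designs, run on
#' simulated cohorts: (1) models built with observed SNPs only versus
#' observed plus hard-called imputed SNPs; (2) training and validating
#' across genotyping-platform views that observe different SNP subsets of
#' the same truth; (3) transferring a model across study populations; and
#' (4) multi-ethnic versus single-ethnicity training sets validated on a
#' minority population. Every design cell reports per-allele and
#' per-sample accuracy and call rate over the confidence-threshold grid
#' `{0, 0.5, 0.9}`, and is deterministic given its seeds. Comparative
#' claims should be read over many seeded replicates: single-replicate
#' differences of under a point are within simulation noise.
NULL

#' Split a cohort into training and validation halves
#'
#' Disjoint, exhaustive, seeded; stratified by population label. Stratum
#' training counts are `floor(n * fraction + 0.5)`.
#'
#' @param cohort a `sim_cohort`.
#' @param fraction training fraction.
#' @param seed integer seed.
#' @return List with `train` and `validate` (`sim_cohort`s).
#' @export
split_train_validate <- function(cohort, fraction = 0.5, seed = 1L) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (nrow(cohort$truth) < 2L) stop_hla("cohort needs at least 2 samples")
  ids <- with_seed(seed, {
    out <- character(0)
    for (p in unique(cohort$truth$population)) {
      sp <- cohort$truth$sample_id[cohort$truth$population == p]
      k <- floor(length(sp) * fraction + 0.5)
      out <- c(out, sample(sp, k))
    }
    out
  })
  list(train = subset_cohort(cohort, ids),
       validate = subset_cohort(cohort,
                                setdiff(cohort$truth$sample_id, ids)))
}

.ct_grid_default <- c(0, 0.5, 0.9)

# fit on a training cohort and score on a validation cohort over a CT grid
.fit_and_score <- function(train_gt, train_typing, val_gt, val_typing,
                           locus, resolution, cell, ct_grid, seed,
                           prune_eps = 1e-5) {
  fit <- fit_em(train_gt, train_typing, locus, resolution,
                prune_eps = prune_eps, seed = seed)
  rows <- lapply(ct_grid, function(ct) {
    calls <- predict_hla(fit$model, val_gt, ct = ct)
    rep <- accuracy(calls, val_typing)
    data.frame(cell = cell, locus = locus, resolution = resolution,
               ct = ct, n_evaluated = rep$n_evaluated,
               n_called = rep$n_called, call_rate = rep$call_rate,
               acc_allele = rep$acc_allele, acc_sample = rep$acc_sample,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run one evaluation design
#'
#' @param design one of `"imputed-vs-observed"`, `"cross-platform"`,
#'   `"cross-population"`, `"multi-ethnic"`.
#' @param config a named list; common entries are `seed`, `resolution`
#'   (default `"high"`), `ct_grid` (default `c(0, 0.5, 0.9)`), and design
#'   specific entries:
#'   \describe{
#'     \item{imputed-vs-observed}{`cohort_spec` (with `posterior_mode`
#'       truthy), `observed_snp_ids` (the "array" subset; default the
#'       first half of the panel), `thresholds` (a [qc_thresholds()]).}
#'     \item{cross-platform}{`cohort_spec`, `panel_a`, `panel_b`
#'       (snp id vectors observed on each platform).}
#'     \item{cross-population}{`cohort_a`, `cohort_b` (two `cohort_spec`s
#'       over a shared panel layout).}
#'     \item{multi-ethnic}{`majority_spec`, `minority_spec`
#'       (`population_spec`s), `n_majority`, `n_minority`, `n_train_each`,
#'       `n_validate`.}
#'   }
#' @return A tidy data frame: one row per design cell x CT with accuracy
#'   and call rate.
#' @export
run_design <- function(design = c("imputed-vs-observed", "cross-platform",
                                  "cross-population", "multi-ethnic"),
                       config) {
  design <- match.arg(design)
  if (!is.list(config)) stop_hla("config must be a list")
  res <- config$resolution %||% "high"
  ct_grid <- config$ct_grid %||% .ct_grid_default
  seed <- config$seed %||% 1L
  out <- switch(design,
    "imputed-vs-observed" = .design_imputed(config, res, ct_grid, seed),
    "cross-platform" = .design_platform(config, res, ct_grid, seed),
    "cross-population" = .design_population(config, res, ct_grid, seed),
    "multi-ethnic" = .design_multiethnic(config, res, ct_grid, seed))
  out$design <- design
  out$seed <- seed
  out[c("design", "cell", "locus", "resolution", "ct", "n_evaluated",
        "n_called", "call_rate", "acc_allele", "acc_sample", "seed")]
}

.design_imputed <- function(config, res, ct_grid, seed) {
  cs <- config$cohort_spec
  if (!inherits(cs, "cohort_spec") || !cs$posterior_mode)
    stop_hla("imputed-vs-observed needs a cohort_spec with posterior_mode")
  cohort <- sample_cohort(cs)
  panel <- cohort$genotypes$snps$snp_id
  obs_ids <- config$observed_snp_ids %||% panel[seq_len(ceiling(length(panel) / 2))]
  th <- config$thresholds %||% qc_thresholds()
  halves <- split_train_validate(cohort, 0.5, seed)
  arm <- function(cohort_half) {
    obs <- subset_genotypes(cohort_half$genotypes, snps = obs_ids)
    imp_ids <- setdiff(panel, obs_ids)
    p <- cohort_half$posteriors$p[, imp_ids, , drop = FALSE]
    pt <- posterior_table(p,
                          cohort_half$posteriors$snps[
                            match(imp_ids, cohort_half$posteriors$snps$snp_id), ,
                            drop = FALSE],
                          dimnames(cohort_half$posteriors$p)[[1]])
    called <- call_imputed(pt, th)
    merged <- genotype_table(
      cbind(obs$calls, called$genotypes$calls),
      rbind(obs$snps, called$genotypes$snps),
      rownames(obs$calls))
    list(observed = obs, with_imputed = merged)
  }
  tr <- arm(halves$train)
  va <- arm(halves$validate)
  rbind(
    .fit_and_score(tr$observed, halves$train$typing,
                   va$observed, halves$validate$typing,
                   cohort$locus, res, "observed-only", ct_grid, seed),
    .fit_and_score(tr$with_imputed, halves$train$typing,
                   va$with_imputed, halves$validate$typing,
                   cohort$locus, res, "with-imputed", ct_grid, seed))
}

.design_platform <- function(config, res, ct_grid, seed) {
  cs <- config$cohort_spec
  if (!inherits(cs, "cohort_spec"))
    stop_hla("cross-platform needs a cohort_spec")
  cohort <- sample_cohort(cs)
  panel <- cohort$genotypes$snps$snp_id
  pa <- config$panel_a %||% panel[seq_along(panel) %% 2L == 1L]
  pb <- config$panel_b %||% panel[seq_along(panel) %% 2L == 0L]
  halves <- split_train_validate(cohort, 0.5, seed)
  views <- list(
    A = list(train = subset_genotypes(halves$train$genotypes, snps = pa),
             val = subset_genotypes(halves$validate$genotypes, snps = pa)),
    B = list(train = subset_genotypes(halves$train$genotypes, snps = pb),
             val = subset_genotypes(halves$validate$genotypes, snps = pb)))
  rows <- list()
  for (tr in names(views)) for (va in names(views)) {
    # validation SNPs are aligned to the trained model; SNPs the validation
    # platform does not carry are marginalized as missing
    rows[[paste(tr, va)]] <- .fit_and_score(
      views[[tr]]$train, halves$train$typing,
      views[[va]]$val, halves$validate$typing,
      cohort$locus, res, paste0("train-", tr, "_validate-", va),
      ct_grid, seed)
  }
  do.call(rbind, rows)
}

.design_population <- function(config, res, ct_grid, seed) {
  ca <- config$cohort_a; cb <- config$cohort_b
  if (!inherits(ca, "cohort_spec") || !inherits(cb, "cohort_spec"))
    stop_hla("cross-population needs cohort_a and cohort_b cohort_specs")
  A <- sample_cohort(ca)
  B <- sample_cohort(cb)
  ha <- split_train_validate(A, 0.5, seed)
  hb <- split_train_validate(B, 0.5, seed + 1L)
  rbind(
    .fit_and_score(ha$train$genotypes, ha$train$typing,
                   ha$validate$genotypes, ha$validate$typing,
                   A$locus, res, "within-A", ct_grid, seed),
    .fit_and_score(ha$train$genotypes, ha$train$typing,
                   hb$validate$genotypes, hb$validate$typing,
                   A$locus, res, "A-to-B", ct_grid, seed),
    .fit_and_score(hb$train$genotypes, hb$train$typing,
                   ha$validate$genotypes, ha$validate$typing,
                   B$locus, res, "B-to-A", ct_grid, seed),
    .fit_and_score(hb$train$genotypes, hb$train$typing,
                   hb$validate$genotypes, hb$validate$typing,
                   B$locus, res, "within-B", ct_grid, seed))
}

.design_multiethnic <- function(config, res, ct_grid, seed) {
  maj <- config$majority_spec; mino <- config$minority_spec
  if (!inherits(maj, "population_spec") || !inherits(mino, "population_spec"))
    stop_hla("multi-ethnic needs majority_spec and minority_spec")
  n_maj <- config$n_majority %||% 300L
  n_min <- config$n_minority %||% 250L
  k <- config$n_train_each %||% 150L
  nv <- config$n_validate %||% (n_min - k)
  cs <- cohort_spec(list(list(spec = maj, n = n_maj),
                         list(spec = mino, n = n_min)),
                    shared_snp_panel = TRUE, seed = seed)
  cohort <- sample_cohort(cs)
  tr <- cohort$truth
  ids_maj <- tr$sample_id[tr$population == maj$name]
  ids_min <- tr$sample_id[tr$population == mino$name]
  picks <- with_seed(seed + 7L, list(
    maj_train = sample(ids_maj, min(k, length(ids_maj))),
    min_train = sample(ids_min, min(k, length(ids_min)))))
  val_ids <- setdiff(ids_min, picks$min_train)
  val_ids <- val_ids[seq_len(min(nv, length(val_ids)))]
  mixture <- subset_cohort(cohort, c(picks$maj_train, picks$min_train))
  majority <- subset_cohort(cohort, ids_maj[seq_len(min(2L * k, length(ids_maj)))])
  validate <- subset_cohort(cohort, val_ids)
  rbind(
    .fit_and_score(mixture$genotypes, mixture$typing,
                   validate$genotypes, validate$typing,
                   cohort$locus, res, "mixture-on-minority", ct_grid, seed),
    .fit_and_score(majority$genotypes, majority$typing,
                   validate$genotypes, validate$typing,
                   cohort$locus, res, "majority-on-minority", ct_grid, seed))
}
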