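#' @name snp_selection
#' @title Forward-and-backward SNP selection with a penalized objective
#'
#' @description
#' Predictor SNPs for a locus are chosen greedily: the search starts among
#' SNPs inside the HLA gene (when any are available) and gradually widens
#' to flanking regions in `window_step` increments up to `max_window` per
#' side. A forward step adds the in-window candidate that most lowers the
#' objective; a backward step removes any selected SNP whose removal lowers
#' it. The objective is the conditional negative log-likelihood of the HLA
#' genotypes given the SNP genotypes, penalized by the number of free
#' haplotype-frequency parameters: `nll + lambda * (H - 1)` for `H`
#' retained joint haplotypes. `lambda = 1` (AIC-like) is the default;
#' `log(n)/2` gives a BIC-like penalty. Candidate moves are screened with a
#' warm-started, iteration-capped refit and re-confirmed with a full refit
#' before acceptance, so the accepted objective sequence is strictly
#' decreasing and the search terminates.
NULL

#' Search configuration for SNP selection
#'
#' @param gene_start,gene_end 1-based chromosomal positions bounding the
#'   HLA gene.
#' @param window_step flank widening per round, in base pairs.
#' @param max_window maximum flank on each side, in base pairs.
#' @param penalty_lambda per-parameter penalty weight (>= 0).
#' @param max_snps cap on the number of selected SNPs.
#' @param seed integer seed (EM initialization jitter).
#' @param force_gene_snps start from all within-gene candidates instead of
#'   searching among them.
#' @param quick_max_iter EM iteration cap for candidate screening.
#' @return A list of class `search_config`.
#' @export
search_config <- function(gene_start, gene_end, window_step = 50000L,
                          max_window = 500000L, penalty_lambda = 1,
                          max_snps = 100L, seed = 1L,
                          force_gene_snps = FALSE, quick_max_iter = 20L) {
  if (gene_start >= gene_end) stop_hla("gene_start must be < gene_end")
  if (window_step <= 0 || max_window <= 0) stop_hla("window sizes must be positive")
  if (penalty_lambda < 0) stop_hla("penalty_lambda must be >= 0")
  structure(list(gene_start = gene_start, gene_end = gene_end,
                 window_step = as.integer(window_step),
                 max_window = as.integer(max_window),
                 penalty_lambda = penalty_lambda,
                 max_snps = as.integer(max_snps), seed = as.integer(seed),
                 force_gene_snps = isTRUE(force_gene_snps),
                 quick_max_iter = as.integer(quick_max_iter)),
            class = "search_config")
}

#' Penalized selection objective
#'
#' `conditional_nll(model, data) + penalty_lambda * K` with
#' `K = nrow(model$haplo) - 1`, the free frequency parameters.
#'
#' @param model a fitted `haplotype_model`.
#' @param genotypes,typing the training data.
#' @param penalty_lambda penalty weight.
#' @export
penalized_objective <- function(model, genotypes, typing, penalty_lambda = 1) {
  conditional_nll(model, genotypes, typing) +
    penalty_lambda * (nrow(model$haplo) - 1L)
}

#' Select predictor SNPs by forward-and-backward search
#'
#' @param genotypes QC-filtered candidate `genotype_table` (training
#'   samples).
#' @param typing HLA typing table with truth for every training sample.
#' @param locus,resolution the model target.
#' @param config a [search_config()].
#' @param max_iter,tol,prune_eps EM controls for full refits.
#' @return A list with `model` (the final fitted `haplotype_model`) and
#'   `trace` (data frame of moves: action `add`/`drop`/`widen`, id,
#'   objective before/after).
#' @export
select_snps <- function(genotypes, typing, locus,
                        resolution = c("high", "intermediate"), config,
                        max_iter = 500L, tol = 1e-6, prune_eps = 1e-5) {
  resolution <- match.arg(resolution)
  stopifnot(inherits(config, "search_config"))
  meta <- genotypes$snps
  mid <- (config$gene_start + config$gene_end) / 2
  dist_mid <- abs(meta$position - mid)

  full_fit <- function(ids) {
    fit_em(genotypes, typing, locus, resolution, snp_ids = ids,
           max_iter = max_iter, tol = tol, prune_eps = prune_eps,
           seed = config$seed)$model
  }

  selected <- character(0)
  if (!nrow(meta)) {
    model <- full_fit(character(0))
    trace <- data.frame(action = "warn", id = "no-candidate-snps",
                        obj_before = NA_real_, obj_after = NA_real_,
                        stringsAsFactors = FALSE)
    return(list(model = model, trace = trace))
  }
  in_gene <- meta$position >= config$gene_start & meta$position <= config$gene_end
  if (config$force_gene_snps && any(in_gene))
    selected <- meta$snp_id[in_gene]
  model <- full_fit(selected)
  obj <- penalized_objective(model, genotypes, typing, config$penalty_lambda)
  trace <- list()
  push <- function(action, id, before, after)
    trace[[length(trace) + 1L]] <<- data.frame(
      action = action, id = id, obj_before = before, obj_after = after,
      stringsAsFactors = FALSE)
  if (length(selected))
    push("seed", paste(selected, collapse = ","), NA_real_, obj)

  w <- 0L
  # candidates already screened (and not accepted) against the current
  # model, and whether a backward pass already failed for it; both reset
  # whenever the model changes, so nothing is re-evaluated needlessly
  # while the window widens past an unchanged model
  screened <- character(0)
  backward_clean <- FALSE
  repeat {
    lo <- config$gene_start - w
    hi <- config$gene_end + w
    window_ids <- meta$snp_id[meta$position >= lo & meta$position <= hi]
    moved <- FALSE

    # forward step
    if (length(selected) < config$max_snps) {
      cand <- setdiff(window_ids, c(selected, screened))
      ord <- order(dist_mid[match(cand, meta$snp_id)], cand)
      cand <- cand[ord]
      best_id <- NA_character_; best_obj <- obj
      for (id in cand) {
        m_q <- tryCatch(
          extend_model(model, meta[meta$snp_id == id, , drop = FALSE],
                       genotypes, typing, max_iter = config$quick_max_iter,
                       tol = tol, seed = config$seed),
          error = function(e) NULL)
        if (is.null(m_q)) next
        o_q <- penalized_objective(m_q, genotypes, typing,
                                   config$penalty_lambda)
        if (o_q < best_obj - 1e-9) {
          best_obj <- o_q
          best_id <- id
        }
      }
      screened <- c(screened, setdiff(cand, best_id))
      if (!is.na(best_id)) {
        m_full <- full_fit(c(selected, best_id))
        o_full <- penalized_objective(m_full, genotypes, typing,
                                      config$penalty_lambda)
        if (o_full < obj - 1e-9) {
          push("add", best_id, obj, o_full)
          selected <- c(selected, best_id)
          model <- m_full
          obj <- o_full
          moved <- TRUE
          screened <- character(0)
          backward_clean <- FALSE
        } else screened <- c(screened, best_id)
      }
    }

    # backward step
    if (!moved && !backward_clean && length(selected) >= 1L) {
      ord <- order(dist_mid[match(selected, meta$snp_id)], selected)
      for (id in selected[ord]) {
        m_q <- tryCatch(
          drop_snp(model, id, genotypes, typing,
                   max_iter = config$quick_max_iter, tol = tol,
                   seed = config$seed),
          error = function(e) NULL)
        if (is.null(m_q)) next
        o_q <- penalized_objective(m_q, genotypes, typing,
                                   config$penalty_lambda)
        if (o_q < obj - 1e-9) {
          m_full <- full_fit(setdiff(selected, id))
          o_full <- penalized_objective(m_full, genotypes, typing,
                                        config$penalty_lambda)
          if (o_full < obj - 1e-9) {
            push("drop", id, obj, o_full)
            selected <- setdiff(selected, id)
            model <- m_full
            obj <- o_full
            moved <- TRUE
            screened <- character(0)
            break
          }
        }
      }
      if (!moved) backward_clean <- TRUE
    }

    if (!moved) {
      if (w >= config$max_window) break
      w <- min(w + config$window_step, config$max_window)
      push("widen", paste0("+/-", w), obj, obj)
    }
    if (length(selected) >= config$max_snps && !moved) break
  }
  list(model = model,
       trace = do.call(rbind, trace) %||%
         data.frame(action = character(), id = character(),
                    obj_before = numeric(), obj_after = numeric(),
                    stringsAsFactors = FALSE))
}
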