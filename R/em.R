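# Internal EM machinery for the joint (HLA allele, SNP haplotype) frequency
# model. Haplotype SNP patterns are strings over {a,b}; a sample's unphased
# genotype constrains an ordered pair of haplotypes to add up at every
# non-missing SNP, and (in training) to carry the sample's HLA genotype.
# Samples are deduplicated into signatures (genotype + truth) with weights,
# and pair index lists are built once per model structure and reused over
# EM iterations.

# patterns (character vector over {a,b}) -> H x S 0/1 matrix (1 = allele b)
snp_code_matrix <- function(patterns) {
  H <- length(patterns)
  S <- if (H) nchar(patterns[1]) else 0L
  if (H == 0L || S == 0L) return(matrix(0L, H, max(S, 0L)))
  m <- matrix(0L, H, S)
  sp <- strsplit(patterns, "", fixed = TRUE)
  for (i in seq_len(H)) m[i, ] <- as.integer(sp[[i]] == "b")
  m
}

# Ordered haplotype index pairs compatible with one unphased genotype vector
# g (values 0/1/2/NA over the model's SNPs). Missing entries impose no
# constraint. Returns a 2-column integer matrix of ordered (i, j) pairs.
compatible_pair_idx <- function(code, g) {
  H <- nrow(code)
  if (!H) return(matrix(integer(), 0, 2))
  obs <- which(!is.na(g))
  hom0 <- obs[g[obs] == 0L]
  hom2 <- obs[g[obs] == 2L]
  het  <- obs[g[obs] == 1L]
  keep <- rep(TRUE, H)
  if (length(hom0))
    keep <- keep & rowSums(code[, hom0, drop = FALSE]) == 0L
  if (length(hom2))
    keep <- keep & rowSums(code[, hom2, drop = FALSE]) == length(hom2)
  idx <- which(keep)
  if (!length(idx)) return(matrix(integer(), 0, 2))
  if (!length(het)) {
    k <- length(idx)
    return(cbind(rep(idx, each = k), rep.int(idx, k)))
  }
  P <- code[idx, het, drop = FALSE]
  key <- apply(P, 1, paste, collapse = "")
  ckey <- apply(1L - P, 1, paste, collapse = "")
  jmap <- split(seq_along(idx), key)
  out <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    js <- jmap[[ckey[i]]]
    if (length(js)) out[[i]] <- cbind(rep.int(idx[i], length(js)), idx[js])
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(matrix(integer(), 0, 2))
  do.call(rbind, out)
}

# Restrict ordered pairs to those carrying an HLA genotype compatible with
# truth alternative sets s1, s2 (character vectors of allele keys).
filter_pairs_hla <- function(pairs, hla_keys, s1, s2) {
  if (!nrow(pairs)) return(pairs)
  hi <- hla_keys[pairs[, 1]]
  hj <- hla_keys[pairs[, 2]]
  ok <- (hi %in% s1 & hj %in% s2) | (hi %in% s2 & hj %in% s1)
  pairs[ok, , drop = FALSE]
}

# Deduplicate samples into signatures. geno: n x S matrix (may have 0 cols);
# truth: NULL or list of list(s1=, s2=) per sample. Returns list(sig_geno,
# sig_truth, weight, map) where map[i] is sample i's signature index.
dedupe_signatures <- function(geno, truth = NULL) {
  n <- nrow(geno)
  gstr <- if (ncol(geno)) {
    g <- geno
    g[is.na(g)] <- 9L
    apply(g, 1, paste, collapse = "")
  } else rep("", n)
  tstr <- if (is.null(truth)) rep("", n) else vapply(truth, function(t) {
    paste(paste(sort(t$s1), collapse = "/"), paste(sort(t$s2), collapse = "/"),
          sep = "|")
  }, "")
  key <- paste(gstr, tstr, sep = "#")
  uk <- unique(key)
  map <- match(key, uk)
  first <- match(uk, key)
  list(sig_geno = geno[first, , drop = FALSE],
       sig_truth = if (is.null(truth)) NULL else truth[first],
       weight = as.numeric(tabulate(map, length(uk))),
       map = map)
}

# Build per-signature ordered-pair lists for a haplotype set.
build_pairlists <- function(code, hla_keys, sigs) {
  nsig <- nrow(sigs$sig_geno)
  out <- vector("list", nsig)
  for (k in seq_len(nsig)) {
    pr <- compatible_pair_idx(code, sigs$sig_geno[k, ])
    if (!is.null(sigs$sig_truth)) {
      t <- sigs$sig_truth[[k]]
      pr <- filter_pairs_hla(pr, hla_keys, t$s1, t$s2)
    }
    out[[k]] <- pr
  }
  out
}

# EM over haplotype frequencies given fixed pair lists.
# pairlists: per-signature ordered-pair matrices; w: signature weights;
# f0: start frequencies (length H, sums to 1). Signatures with zero pairs
# must have been handled by the caller. Returns f, per-iteration observed
# log-likelihood, iteration count and convergence flag. tol is the
# per-sample log-likelihood gain threshold.
em_run <- function(pairlists, w, H, f0, max_iter = 500L, tol = 1e-6) {
  npairs <- vapply(pairlists, nrow, 1L)
  if (any(npairs == 0L))
    stop_hla("internal: EM called with an inexplicable sample signature")
  I <- unlist(lapply(pairlists, function(m) m[, 1]), use.names = FALSE)
  J <- unlist(lapply(pairlists, function(m) m[, 2]), use.names = FALSE)
  SI <- rep.int(seq_along(pairlists), npairs)
  n <- sum(w)
  f <- f0 / sum(f0)
  ll_trace <- numeric(0)
  converged <- FALSE
  iters <- 0L
  small_gains <- 0L
  repeat {
    pw <- f[I] * f[J]
    liks <- rowsum(pw, SI, reorder = FALSE)
    lik <- as.numeric(liks)[order(as.integer(rownames(liks)))]
    lik <- pmax(lik, .Machine$double.xmin)
    ll <- sum(w * log(lik))
    ll_trace <- c(ll_trace, ll)
    iters <- iters + 1L
    # two consecutive sub-tolerance gains: a single tiny step can occur
    # while still on the slow approach away from a symmetric saddle
    if (iters > 1L && (ll - ll_trace[iters - 1L]) / n < tol) {
      small_gains <- small_gains + 1L
      if (small_gains >= 2L) {
        converged <- TRUE
        break
      }
    } else small_gains <- 0L
    if (iters >= max_iter) break
    r <- (pw / lik[SI]) * w[SI]
    cf <- numeric(H)
    ci <- rowsum(r, I)
    cf[as.integer(rownames(ci))] <- cf[as.integer(rownames(ci))] + as.numeric(ci)
    cj <- rowsum(r, J)
    cf[as.integer(rownames(cj))] <- cf[as.integer(rownames(cj))] + as.numeric(cj)
    f <- cf / (2 * n)
    f <- f / sum(f)
  }
  list(f = f, loglik = ll_trace, iters = iters, converged = converged)
}

# Initial frequencies proportional to compatible-configuration counts, with
# a small seeded symmetric Dirichlet admixture to break ties (e.g. the
# double-heterozygote saddle). jitter = mixture weight of the Dirichlet draw.
init_frequencies <- function(pairlists, w, H, seed, jitter = 0.02) {
  cnt <- numeric(H)
  for (k in seq_along(pairlists)) {
    pr <- pairlists[[k]]
    if (!nrow(pr)) next
    add <- w[k] / nrow(pr)
    t1 <- tabulate(pr[, 1], H)
    t2 <- tabulate(pr[, 2], H)
    cnt <- cnt + add * (t1 + t2)
  }
  if (sum(cnt) <= 0) cnt <- rep(1, H)
  f <- cnt / sum(cnt)
  jit <- with_seed(seed, rdirichlet1(rep(1, H)))
  f <- (1 - jitter) * f + jitter * jit
  f / sum(f)
}

# Prune haplotypes below eps while guaranteeing every training signature
# keeps at least one compatible pair; pruned haplotypes needed for coverage
# are re-admitted at the floor frequency. Returns list(keep, f) over the
# original index space (f renormalized over kept haplotypes).
prune_with_coverage <- function(f, eps, pairlists) {
  keep <- f >= eps
  if (all(keep)) return(list(keep = keep, f = f / sum(f)))
  floor_set <- logical(length(f))
  for (k in seq_along(pairlists)) {
    pr <- pairlists[[k]]
    if (!nrow(pr)) next
    alive <- keep[pr[, 1]] & keep[pr[, 2]]
    if (any(alive)) next
    # re-admit the best surviving pair's haplotypes at the floor
    wbest <- which.max(f[pr[, 1]] * f[pr[, 2]])
    need <- unique(c(pr[wbest, 1], pr[wbest, 2]))
    keep[need] <- TRUE
    floor_set[need] <- TRUE
  }
  f2 <- f
  f2[floor_set] <- pmax(f2[floor_set], eps)
  f2[!keep] <- 0
  list(keep = keep, f = f2 / sum(f2))
}
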