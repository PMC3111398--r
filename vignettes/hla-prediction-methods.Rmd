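---
title: "Predicting HLA alleles from MHC SNPs: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting HLA alleles from MHC SNPs: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlapredict)
```

## The problem

Classical HLA genes (HLA-A, -B, -C, -DRB1, -DQB1, -DPB1) are the most
polymorphic loci in the human genome, and their alleles matter for
transplantation, drug hypersensitivity and a long list of immune-mediated
diseases. Direct HLA typing is expensive; genome-wide SNP arrays are cheap
and ubiquitous. Because the MHC region carries strong, long-range linkage
disequilibrium (LD), the SNP haplotype surrounding an HLA gene is highly
informative about which HLA allele rides on it. `hlapredict` builds
predictive models that exploit this: given unphased SNP genotypes in the
extended MHC (chromosome 6, 28,799,220–34,204,868), it assigns posterior
probabilities to every possible pair of HLA alleles at a locus.

## The joint haplotype model

For one locus and one resolution (2-digit "intermediate" or 4-digit
"high"), the model is a frequency table over *joint haplotypes*
$g = (h, s)$: an HLA allele $h$ together with the vector $s$ of SNP
alleles carried on the same chromosome copy, over an ordered SNP list.
Under Hardy–Weinberg random pairing within the training population, a
sample's two joint haplotypes are independent draws, so the likelihood of
its unphased data is

$$L_i \;=\; \sum_{(g, g')\;\text{compatible with } i} f_g\, f_{g'},$$

where a pair is *compatible* when the SNP allele counts add up to the
observed genotype at every non-missing SNP and, in training, the two HLA
alleles match the sample's typing (either order; ambiguity alternatives
all count). Missing SNP genotypes are marginalized, never imputed — they
simply impose no constraint.

Maximum-likelihood frequencies come from the classical EM algorithm for
haplotype frequencies from unphased genotypes: the E-step distributes each
sample's mass over its compatible ordered pairs in proportion to
$f_g f_{g'}$, the M-step sets each $f_g$ to its expected count over $2n$
chromosomes. The observed-data log-likelihood is provably non-decreasing,
and the fit asserts this at a $10^{-10}$ tolerance.

Prediction conditions on SNP genotypes only: the posterior probability of
the unordered allele pair $\{h_1, h_2\}$ is the summed weight of
compatible joint-haplotype pairs carrying it, normalized. A validation
sample whose genotypes no retained haplotype pair can explain falls back
to the Hardy–Weinberg prior implied by the model's marginal HLA
frequencies and is flagged; prediction therefore never fails, which is
what makes a 100% call rate at confidence threshold 0 meaningful.

### Growing the haplotype space

With up to dozens of selected SNPs the full space of $2^{|S|}$ SNP strings
per allele is unenumerable. Models therefore grow one SNP at a time
(`extend_model()`): every retained haplotype splits into two children
(`a`/`b` at the new SNP), child frequencies warm-start at the parent
frequency split by the new SNP's allele frequency, EM runs to convergence,
and haplotypes below `prune_eps` (default $10^{-5}$) are removed and the
rest renormalized. If pruning would leave a training sample with no
compatible pair, the best pair it needs is re-admitted at the floor
frequency — a deliberate "never crash, never drop a sample" rule.

### Numerical choices

* **Initialization.** Stage starts are mixed with a 2% symmetric
  Dirichlet jitter drawn under the caller's seed. The jitter breaks the
  exact symmetry of saddle configurations — the canonical case is a
  cohort of double heterozygotes ($A_1/A_2$ with SNP genotype 1), whose
  uniform start is a stationary point of EM. Two percent is large enough
  that the escape direction clears the convergence tolerance within a few
  iterations and small enough to leave well-conditioned fits unaffected.
* **Convergence.** EM stops when the per-sample log-likelihood gain stays
  below `tol` (default $10^{-6}$) on two *consecutive* iterations, or at
  `max_iter` (default 500). The two-in-a-row rule exists because near a
  saddle a single step can be tiny while the iteration is still
  accelerating away from it.
* **Determinism.** Fits are deterministic given the seed and invariant to
  sample order (samples are deduplicated into weighted genotype+truth
  signatures before EM; this is also the main speed lever at cohort
  sizes in the thousands).
* **Floors.** Posterior masses are floored at $10^{-300}$ before logs.

## SNP selection

Predictor SNPs are chosen by a greedy forward-and-backward search scored
by the conditional negative log-likelihood of the HLA genotypes given the
SNP genotypes, penalized by the number of free haplotype parameters:

$$\mathrm{obj} \;=\; -\sum_i \log P(\text{truth}_i \mid \text{SNPs}_i)
\;+\; \lambda\,(H - 1),$$

with $H$ the number of retained joint haplotypes. The search starts among
SNPs inside the HLA gene (when the panel has any), then widens the
flanking window in 50 kb steps to at most 500 kb per side; a forward step
adds the in-window candidate that most lowers the objective, a backward
step removes any selected SNP whose removal lowers it, and moves are
accepted only when a full refit confirms a strict decrease — so the
objective sequence is strictly decreasing and the search terminates.
Candidate screening uses a warm-started, iteration-capped (20) refit;
candidates screened against an unchanged model are not re-evaluated as
the window widens. Ties break by distance to the gene midpoint, then
lexicographic SNP id.

The penalty weight defaults to $\lambda = 1$ (AIC-like); $\log(n)/2$
gives the BIC-like alternative. One behaviour worth knowing: a SNP that
tags alleles *perfectly* adds no free parameters after pruning (each
parent haplotype keeps a single surviving child), so it is accepted at
any $\lambda$; the penalty bites exactly when tagging is imperfect and
both children survive. The noise-rejection property — deterministic tag
SNPs in, independent noise SNPs out — is what the selection tests verify,
rather than any match to a particular published SNP list, which would
require the original cohorts.

## Calling and evaluation

The pair with the maximum posterior is the call, emitted when its
probability strictly exceeds the confidence threshold CT; at CT = 0
everyone is called (call rate 100%), and the reporting grid
$\{0, 0.5, 0.9\}$ is the default. Raising CT never changes which pair is
best, only whether it is reported.

Accuracy compares calls with known typings after excluding samples with
missing or unresolvable truth. Because "compare predicted with known
genotype" is ambiguous between allele-level and sample-level counting,
both are always reported: per-allele accuracy (matched alleles over
$2\times$ called samples, pairing predicted to true alleles to maximize
matches, so a homozygous call against a heterozygous truth scores 1/2)
and per-sample accuracy (both alleles right), which can never exceed it.
A truth given as an ambiguity set (`57:01/57:03`) credits a match to any
alternative — the most conservative scoring that does not punish the
model for truth the assay itself could not resolve. Accuracy can be
restricted to truth alleles whose *training-set* frequency exceeds a
floor; this conditions on the true allele, leaves individual match
outcomes untouched, and keeps rare-allele performance visible in the
unstratified report.

Cross-platform genotype agreement uses Cohen's kappa,
$\kappa = (\Pr(a) - \Pr(e))/(1 - \Pr(e))$, pooled into one 3×3 genotype
table over all SNP–sample pairs per source class (observed-observed,
observed-imputed, imputed-observed, imputed-imputed, overall) rather than
averaging per-SNP kappas — matching how single concordance values per
platform pair are conventionally reported. Counted-allele orientation
must agree per SNP on both sides; mismatches are an error, never a silent
strand flip, because A/T and C/G SNPs make silent flipping unsafe.

## Quality control

Observed panels are censored with the standard GWAS trio of filters —
minor allele frequency $\ge$ 0.01, missingness $\le$ 5%, Hardy–Weinberg
$p \ge 10^{-20}$ — each evaluated on the pre-filter table so that reports
are independent of filter order and filtering is idempotent. The HWE test
is the asymptotic 1-df chi-square: at a $10^{-20}$ threshold only gross
failures are removed, where the asymptotic and exact tests agree for any
practical sample size, so the exact test was left out. Imputed genotypes
arrive as per-cell probability triples and are hard-called when the
maximum posterior *strictly* exceeds 0.8 — the boundary is read strictly
and is configurable (`boundary = "inclusive"`) since sources differ on
it — then SNPs are re-filtered on call rate ($\ge$ 95%) and MAF
($\ge$ 1%).

## The synthetic cohort generator

Real MHC cohorts with paired SNP and HLA typing are not redistributable,
so every evaluation design runs on simulated cohorts built to exercise
exactly the property the method relies on. LD is modelled directly at the
haplotype-pool level rather than by coalescent simulation: each HLA
allele carries `tags_per_allele` core SNP haplotypes; pool haplotypes are
noisy copies of the cores (`haplotype_noise` per SNP); sampled
chromosomes may recombine with a random pool haplotype
(`recomb_rate` per adjacent pair). This gives seedable, interpretable
control over tagging fidelity — the one axis the evaluation designs vary
— with no external simulator dependency. At zero noise with one tag per
allele the generator additionally redraws cores until all unordered core
*sums* are distinct, so the HLA genotype is identifiable from the
unphased SNP genotype and perfect-tagging recovery at 100% accuracy is a
well-posed target rather than a lottery over core collisions.

Defaults reflect the evaluation designs: two-population cohorts for the
multi-ethnic experiment use 150 training samples per group (mirroring the
combined-training design), train/validate splits are half/half and
stratified by population, and the multi-ethnic comparison is read over 20
seeded replicates with a sign-count criterion because single-replicate
accuracy differences of under a point are within simulation noise.
Populations given disjoint HLA alleles and independent cores produce the
cohort-level Hardy–Weinberg violation (Wahlund excess homozygosity) that
the multi-ethnic design needs. Two cohort specifications sharing a
`pool_seed` draw independent samples from the *same* population — the
substrate of the cross-population transfer design; different `pool_seed`s
give genuinely different populations.

What the simulator does **not** emulate: realistic human MHC haplotype
maps, mutation/recombination histories, platform-specific error modes, or
an imputer's error structure (simulated posteriors are truth-peaked
Dirichlet triples with configurable sharpness). Passing tests therefore
demonstrate correctness and internal consistency of the machinery — EM
optimality, calibration of posteriors, soundness of selection, direction
of the multi-ethnic effect under conditions that force it — not
real-data accuracy levels, which depend on cohort LD that only real data
carries.

## Verification against independent oracles

The EM fit is checked against a brute-force grid search over the
haplotype-frequency simplex at step 0.01 on 30 random small instances
(one or two SNPs, two or three HLA alleles, up to 20 samples). The grid
is restricted to the *support* — haplotypes appearing in at least one
sample's compatible pair — which is sound because haplotypes outside the
support contribute nothing to any sample's likelihood, so some optimum
places zero mass on them; instances are constructed so the support has at
most four haplotypes, the largest simplex that a 0.01-step grid can
sweep exhaustively at interactive speed. Worked posterior values
(e.g. the three-haplotype model's $P\{A_{01}, A_{02}\} = 0.46875$ at SNP
genotype 0) are frozen from hand enumeration; kappa values are compared
with a direct contingency-table computation.

Problem sizes used by the test suite and the acceptance script — cohorts
of 150–2,000 samples, 5–8 SNP panels, 20-replicate sweeps — were chosen
as the smallest sizes at which the binomial/multinomial sampling noise is
comfortably below each property's acceptance margin (for example, at
$n = 2{,}000$ the haplotype-frequency standard error is below 0.008
against an RMSE bound of 0.02).

## Limitations

* The likelihood assumes unrelated individuals and within-population
  random mating; admixed cohorts violate HWE at the cohort level, and the
  multi-ethnic experiments quantify the consequences rather than model
  them away.
* Truth at intermediate resolution cannot train a high-resolution model;
  there is no partial-resolution likelihood.
* Binary PLINK, VCF and imputation-native formats are out of scope; the
  ped/map and matrix-tsv readers cover the text dialects, and monomorphic
  ped SNPs record a placeholder counted allele because the file carries
  no evidence about the unobserved allele.
* Nomenclature handling covers two- and four-digit names with separator
  tolerance, not the full modern nomenclature (expression suffixes,
  six-digit fields, G/P groups).

## Command-line interface

A thin wrapper over the package functions is installed at
`exec/hla-tools`: subcommands `simulate`, `qc`, `qc-imputed`, `train`,
`predict`, `evaluate` and `concordance` map one-to-one onto
`sample_cohort()`, `filter_snps()`, `call_imputed()`, `select_snps()`,
`predict_hla()`, `accuracy()` and `platform_concordance()`; all heavy
lifting stays in the package.
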