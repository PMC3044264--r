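---
title: "Ensemble ReliefF and TuRF filtering of SNP-SNP interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble ReliefF and TuRF filtering of SNP-SNP interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epifilter)
```

## The problem

Case-control genome-wide association studies search for SNPs associated
with disease. Complex diseases, however, are often driven by gene-gene
interactions: pairs of loci whose joint genotype carries risk while each
locus alone shows little or no marginal association. Combinatorial methods
(MDR, random-forest and Bayesian approaches) can find such pairs but scale
exponentially in the number of SNPs, so a *filtering* step must first
reduce a panel of, say, $10^5$ SNPs to a few hundred — without discarding
the interacting pair. Univariate filters (per-SNP $\chi^2$ tests, odds
ratios) are blind to purely epistatic pairs by construction. The
ReliefF family of filters is the standard multivariate alternative: it
scores each SNP by whether it separates samples from their nearest
neighbours of the opposite class, which makes it sensitive to conditional
(interaction) effects.

`epifilter` implements this filter family for categorical genotype data —
ReliefF, tuned ReliefF (TuRF), SURF and SURFTuRF — together with the
package's central contribution: their *sample-order permutation ensembles*
ReliefF-E and TuRF-E, which repair a subtle instability in the base
algorithms.

## The model and the instability

For a dataset of $M$ samples and $N$ SNPs with genotype codes
$G(g_j, s_i) \in \{0, 1, 2\}$ (minor-allele counts), ReliefF updates each
SNP weight, for every target sample $s_i$ and each of its $K$ nearest
same-class neighbours $h_k$ ("hits") and opposite-class neighbours $m_k$
("misses"):

$$W(g_j) \leftarrow W(g_j) - \frac{D(g_j, s_i, h_k)}{MK}
                          + \frac{D(g_j, s_i, m_k)}{MK},$$

where $D$ is the 0/1 genotype difference and sample distances are Hamming
distances over the current SNP set. Dividing by $MK$ (rather than $M$
alone, which suffices only for $K = 1$) keeps every weight in $[-1, 1]$;
the rescaling is rank-preserving. TuRF runs ReliefF $R$ times, discarding
the $\lfloor N/R \rfloor$ lowest-weighted SNPs after each of the first
$R - 1$ passes (distances recomputed on the survivors), which progressively
improves the signal-to-noise ratio.

The instability: distances between genotype vectors are *integers*, so for
a target sample more than $K$ candidates frequently sit at or within the
distance of its $K$-th nearest neighbour. Any rule that must pick exactly
$K$ of them — this package uses "first $K$ in presentation order", which is
deterministic given an order — picks differently when the samples are
reordered, so ReliefF and especially TuRF return different rankings for
the *same data* in a different row order. On simulated 400-sample, 1000-SNP
data, two permuted TuRF runs typically correlate at only $r \approx 0.4$–$0.5$.

## The ensemble

ReliefF-E / TuRF-E run the base filter on $L$ copies of the dataset under
independent sample-order permutations (the whole dataset each time — not
bootstrap subsets) and aggregate per-copy *ranks*:

$$W_{\mathrm{ensemble}}(g_j) = \frac{1}{L}\sum_{l=1}^{L}
  \mathrm{rank}\!\left(h_l(g_j), D_l\right),$$

with the final ranking by ascending mean rank. Ranks — not weights — are
the aggregation currency: TuRF weights from different runs live on
different surviving SNP subsets and are not commensurable. Each tied
neighbourhood contributes differently across permutations, so the ensemble
recovers the information a single forced tie-break discards. Defaults are
$K = 10$, $R = 10$, $L = 50$; stability gains plateau at around $L = 40$
(see `ensemble_size_sweep()`).

For TuRF-E the aggregation default is each run's composite final ranking.
The alternative reading — aggregating all $R \times L$ per-iteration
rankings — is exposed as `aggregate = "per_iteration"` in
`ensemble_filter()`; both are provided because the verbal description of
the procedure admits either.

### Composite TuRF ranking

TuRF's last pass scores only the surviving SNPs, but percentile-based
filtering needs a full ranking, and how the removed SNPs are ranked turns
out to matter. Two conventions are provided:

* `"blocked"` (the default everywhere): survivors first by final weight,
  then removed SNPs in blocks by removal iteration (later removal =
  better), within a block by weight at removal. Surviving longer is itself
  treated as evidence of relevance.
* `"last_estimate"`: every SNP ranked by its last computed weight — final
  weight for survivors, weight at removal otherwise.

The choice trades stability against retention, and the package's design
comparison (20 simulated 400-sample datasets, five penetrance tables,
$h^2 = 0.2$) quantifies it. For a single run the blocked composite retains
the functional pair better (ACSR 66.8 vs 61.2). Inside the ensemble,
blocked members give the most stable aggregate rankings (inter-run
$r = 0.98$ at 400 samples, $0.97$ at 800, $L = 50$) but let a minority of
unlucky member runs — those that discard a functional SNP early, sending
it to rank $\gtrsim 900$ of 1000 — drag the pair's mean rank, so the
ensemble's ACSR (63.7) does not beat single TuRF's (66.8) under this
generator's conditions. Last-estimate members penalise such runs only
mildly: ensemble ACSR rises to 69.4, above single TuRF, at the cost of
stability ($r = 0.96$ at 400, $0.94$ at 800). The default follows the
stability-first reading; `member_composite = "last_estimate"` in
`ensemble_filter()` selects the retention-oriented alternative, and
`composite` in `turf_ranking()` controls the standalone output.

Weight ties break by ascending SNP index everywhere (and, mirror-image,
removal picks the higher index first), so every ranking is a deterministic
function of the weights.

## The simulator

`make_penetrance_model()` constructs two-locus penetrance tables
$f_{ab}$ that are *purely epistatic*: with Hardy-Weinberg genotype
probabilities $\pi$, every row and column satisfies
$\sum_b \pi_b f_{ab} = K_{\mathrm{prev}}$, so neither locus has any
marginal effect, while the heritability
$h^2 = \sum_{ab} \pi_a \pi_b (f_{ab} - K_{\mathrm{prev}})^2 /
(K_{\mathrm{prev}}(1 - K_{\mathrm{prev}}))$ hits its target exactly
(random deviation tables are projected onto the marginal-effect-free space
by $\pi$-weighted double-centering, rescaled, and rejected if any
penetrance leaves $[0,1]$).

Defaults are MAF $= 0.4$ and prevalence $= 0.25$ for both functional loci.
These are design choices with a hard constraint behind them: exact vertex
enumeration of the marginal-effect-free polytope shows that at MAF $0.2$,
prevalence $0.1$ the largest attainable heritability is $\approx 0.13$, so
the standard $h^2 = 0.2$ and $0.3$ models would be unconstructible there.
At MAF $0.4$/prevalence $0.25$ the bound is $\approx 0.42$, accommodating
every standard model with room for the random search. Both parameters are
exposed and recorded in the simulator's JSON sidecars.

`simulate_dataset()` draws the functional pair ("X0", "X1") by rejection:
genotype pairs from the HWE joint distribution are accepted as cases with
probability $f_{ab}$ and as controls otherwise, until the exact quotas are
filled (retrospective sampling, matching balanced case-control designs).
Noise SNPs are HWE draws identical in both classes; SNP column order is
randomised. The generator reproduces the standard grid
(`epistasis_models()`): 1000 SNPs, 400 or 800 samples, $h^2 \in \{0.05,
0.1, 0.2, 0.3\}$.

What the simulator does *not* emulate: linkage disequilibrium, genotyping
error, missingness, covariates, or main-effect loci. Passing tests
therefore demonstrate the algorithms' behaviour under clean, purely
epistatic signal, not robustness to real-data artefacts.

## Evaluation protocol

* **Stability**: `rank_correlation()` — Pearson correlation of two runs'
  rank vectors, log10-transformed by default so agreement among top-ranked
  SNPs (the ones a filter actually keeps) dominates; raw-rank correlation
  is available because both conventions are defensible.
* **Success**: `success_rate()` — the percentage of datasets in which
  *both* functional SNPs fall inside the top $\mathrm{round}(Nq/100)$ at
  percentile $q$; retaining one member of an interacting pair is useless
  downstream, so the pair counts only as a unit. `avg_cumulative_success()`
  averages percentiles 1–50 (ACSR).
* **Tie diagnosis**: `find_tie_causing_samples()` flags samples whose
  hit- or miss-side selection is tied (more than $K$ candidates at or
  within the $K$-th neighbour distance). `remove_tie_samples()` produces a
  tie-free sample subset, on which ReliefF is *exactly* order-invariant
  (bit-identical weights, guaranteed by integer weight accumulation).
  TuRF on the same subset is only *almost* invariant
  ($r \approx 0.99$): it recomputes distances on each surviving SNP
  subset, and the reduced-subset matrices reintroduce ties that
  full-SNP-set removal cannot see. `scope = "turf"` extends the tie scan
  to the whole TuRF path, but certifying a path-tie-free subset is a hard
  combinatorial search (see below) and the budget-bounded search typically
  retains a handful of residual tied neighbourhoods on 1000-SNP panels.
  The asymmetry is itself informative: iterating ReliefF makes the tie
  pathology strictly harder to excise, which is one more reason the
  ensemble — not sample deletion — is the practical remedy.

### Numerical and algorithmic choices

* ReliefF weight numerators are accumulated as integers and divided once
  by $MK$, so tie-free permuted runs agree to the last bit rather than to
  floating-point noise.
* SURF's threshold defaults to the mean off-diagonal pairwise distance;
  hit- and miss-side updates are normalised by each sample's own side
  counts ($1/(M h_i)$ and $1/(M \mu_i)$), which preserves the $[-1,1]$
  bound and reduces exactly to the $K = 1$ ReliefF update when each side
  holds one neighbour.
* Tie removal proceeds in two phases. Blanket removal of all flagged
  samples (iterated, because removal creates new ties) suffices only when
  ties are sparse. On realistic panels ties are pervasive — at 400
  samples and 1000 SNPs most samples are tie-flagged — and the cascade
  would exhaust a class, so the procedure switches to a seeded
  simulated-annealing search for a tie-free subset with exactly $K + 1$
  samples per class. That size is structurally optimal: a class of
  $K + 1$ gives every same-class target exactly $K$ hit candidates (a
  forced, tie-free choice) and every opposite-class target $K + 1$ miss
  candidates, tied only when the two farthest are equidistant. The search
  swaps single samples, preferentially those participating in remaining
  ties, and is deterministic given its seed. The aggressiveness of the
  removal — from 400 samples down to $2(K+1) = 22$ — is itself the
  finding: restoring exact order-invariance by deleting data costs almost
  all statistical power, which is why the ensemble, not tie removal, is
  the practical remedy.
* Degenerate inputs: constant SNPs get weight exactly 0; empty SURF
  neighbourhoods contribute nothing; `N < R` and undersized classes are
  refused with informative errors.

## Worked example

```{r example, eval = FALSE}
model <- make_penetrance_model(h2 = 0.3, seed = 1)
ds <- simulate_dataset(model, n_cases = 200, n_controls = 200,
                       n_snps = 1000, seed = 2)

# single TuRF runs disagree under sample reordering ...
t1 <- turf_ranking(permute_samples(ds, 11))$ranking
t2 <- turf_ranking(permute_samples(ds, 12))$ranking
rank_correlation(t1, t2)

# ... their ensemble does not, and retains the functional pair
e1 <- ensemble_filter(ds, "turf", L = 50, master_seed = 21)
e2 <- ensemble_filter(ds, "turf", L = 50, master_seed = 22)
rank_correlation(e1$final_ranking, e2$final_ranking)
e1$final_ranking$ranks[c("X0", "X1")]
```

## Problem sizes used by the test suite

The shipped tests exercise the full standard conditions where the checked
quantity needs them (stability correlations at 400 and 800 samples with
$L = 50$ and $L = 30$; near-ceiling retention on 20 datasets of the
800-sample, $h^2 = 0.3$ model at $L = 20$) and reduced ensembles
($L = 10$) or smaller panels elsewhere, chosen so each check still probes
the property it names. The method-ordering comparison uses 10 datasets per
heritability; ACSR gaps between the filter families are tens of points, so
modest collections identify the ordering reliably.

## Known limitations

* The first-`K` tie rule reproduces one specific deterministic tie-break;
  other implementations may break ties differently, changing single-run
  rankings (though not the ensemble's behaviour, which is the point).
* The odds-ratio comparator is the allelic 2x2 odds ratio with
  Haldane-Anscombe correction, ranked by $|\ln \mathrm{OR}|$; published
  odds-ratio filters vary and none is canonical.
* `remove_tie_samples(scope = "turf")` solves a combinatorial search
  problem; its runtime is stochastic (seed-dependent) and it can fail
  within a finite move budget even when tie-free subsets exist.
* Simulated noise SNPs are independent; real panels' linkage structure
  both helps (wider distance spread) and hurts (correlated false signals)
  in ways the simulation does not capture.
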