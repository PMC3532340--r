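---
title: "Differential coexpression and regulatory impact factor analysis with dcrif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential coexpression and regulatory impact factor analysis with dcrif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcrif)
```

## The problem

In a two-group expression study (for example a small case/control
microarray comparison with half a dozen post-mortem brains per group),
genes whose *pairwise coexpression* changes between groups can carry
disease signal that ordinary differential-expression testing misses: a
gene can keep the same mean level yet switch from being strongly
positively correlated with a partner in controls to strongly negatively
correlated in cases. `dcrif` implements that analysis end to end:

1. **DCG detection** — find differentially coexpressed genes (DCGs) and
   links between the two conditions, with permutation p-values and
   Benjamini–Hochberg FDR control;
2. **pathway enrichment** — hypergeometric over-representation of the
   DCG list in gene sets (GMT);
3. **regulatory network** — overlay the DCGs on a known transcription
   factor (TF) → target map;
4. **RIF ranking** — score each TF with the regulatory impact factor and
   rank by magnitude.

A synthetic-data generator with planted, known differential structure
makes every stage testable without any external download.

## The differential coexpression model

For genes $a, b$ let $r^{(1)}_{ab}$ and $r^{(2)}_{ab}$ be their Pearson
correlations computed separately within conditions 1 and 2. Links are
pre-filtered by *half-thresholding*: a pair is retained when

$$\max(|r^{(1)}_{ab}|, |r^{(2)}_{ab}|) \;\ge\; Q_{1-q},$$

where $Q_{1-q}$ is the $(1-q)$ quantile of the pooled $|r|$ distribution
over all links in both conditions (ties retained; `q = 1` keeps every
link). The default `q = 0.25` keeps roughly the top quarter of links,
discarding pairs that are weakly correlated in *both* conditions and
therefore uninformative about coexpression change.

Each gene $g$ is scored by the root-mean-square correlation change over
its retained links:

$$dC_g = \sqrt{\frac{\sum_{b \in L(g)} \big(r^{(1)}_{gb} -
r^{(2)}_{gb}\big)^2}{|L(g)|}} \in [0, 2],$$

with $dC_g = 0$ when $L(g)$ is empty. A single link flipping from
$+0.970975$ to $-0.88501$ — the magnitude of flip this method is
designed to catch — gives $dC = 1.855985$.

**Null distribution.** Condition labels are permuted across all samples
and the *entire* statistic (correlations, filter threshold, $dC$) is
recomputed per permutation. Each gene is compared against its own
permutation distribution rather than a pooled null, because genes differ
in how many links survive the filter. The add-one estimator

$$p_g = \frac{1 + \#\{dC^{*} \ge dC_g\}}{1 + B}$$

avoids $p = 0$ and is exact under exchangeability of the labels. Raw
p-values are adjusted with the Benjamini–Hochberg step-up
(`stats::p.adjust`), and genes with **FDR < 0.25 (strict)** are called
DCGs. DC-links are the retained links with *both* endpoints DCGs. The
lenient 0.25 cutoff buys sensitivity in small designs at the price of a
sizeable admitted false-discovery fraction — roughly a quarter of calls
are expected to be false, which matters downstream (see *Limitations*).

**Numerical choices.** Pearson (not Spearman) correlation: with as few
as 6 samples per group, rank correlation takes too few distinct values
to be useful. Zero-variance genes get correlation 0 (not `NA`), with a
warning, so sums stay finite. The filter uses `>=` so that completely
tied correlation magnitudes retain all links rather than none.
Permutation counts below 100 only produce a warning, but the p-value
grid is then too coarse for FDR work.

## Pathway enrichment

With a universe of $N$ genes, a set containing $K$ of them, a DCG list
of $n$, and an overlap of $k$, the upper-tail hypergeometric probability

$$p = \sum_{x=k}^{\min(K,n)} \frac{\binom{K}{x}\binom{N-K}{n-x}}
{\binom{N}{n}}$$

is computed with `stats::phyper` (log-space internally). The universe is
**the genes present in the expression matrix** — the population the
assay could actually have called — not the union of the gene-set file.
Sets are intersected with the universe first; `significant` means raw
$p < 0.05$ (strict), with no correction across pathways, since the
pathway stage is treated as descriptive screening rather than inference.

## Regulatory network and TF classes

A known TF → target pair is kept when **at least one endpoint is a
DCG** (default). This deliberately admits non-DCG TFs whose targets are
DCGs — regulators can act at constant expression — and non-DCG targets
of DCG TFs, so the network contains both DCG and non-DCG nodes. A
stricter rule (`retention = "dc-link"`: the pair must itself be a
DC-link) is available. Each edge is labelled with the endpoint carrying
the DCG evidence; when both endpoints qualify the TF takes precedence.
TFs are classified `DCG-TF` (the TF itself is a DCG) or `TF-of-DCGs`
(only its targets are).

## The regulatory impact factor

For TF $i$ with target set of size $n_{de}$, per-condition target means
$e1_j, e2_j$ and TF–target correlations $r1_{ij}, r2_{ij}$:

$$\mathrm{RIF}_i = \frac{1}{n_{de}} \sum_{j=1}^{n_{de}}
\Big[(e1_j\, r1_{ij})^2 - (e2_j\, r2_{ij})^2\Big].$$

This is the variant of the RIF family whose inputs are exactly the five
quantities above; it weights the *squared* expression-weighted
correlation, so it responds to changes in correlation magnitude and in
target abundance, and it satisfies three exact analytic properties used
as tests: it is zero when the two conditions are identical,
antisymmetric under swapping them, and scales by $c^2$ when all
expression values are scaled by $c$. Because the correlations enter
squared, a pure sign flip at equal magnitude ($+0.9 \to -0.9$) is
invisible to RIF even though it is maximal for $dC$ — the two statistics
are intentionally complementary.

The target set of a TF is its **DCG targets in the regulatory network**
(default), or all DCGs (`targets = "all-dcg"`). TFs with no eligible
target are omitted with a warning. Ranking is by $|\mathrm{RIF}|$
descending (ties by name): the sign depends only on which group is
condition 1, which is an arbitrary orientation, so magnitude is the
meaningful quantity; signed values are still reported.

## The synthetic generator

`simulation_spec()` / `simulate_expression()` produce a gene × sample
matrix of Gaussian log-intensity-like values (default mean 8, sd 2,
i.e. a log2-microarray scale that keeps RIF magnitudes non-degenerate)
with `n_modules` planted coexpression modules. Per condition $c$ each
module has one latent standard-normal factor per sample; module gene $g$
is $s_{g,c}\sqrt{|\rho_c|}\,f + \sqrt{1 - |\rho_c|}\,\varepsilon$, so
any two module genes correlate at $\pm|\rho_c|$. Defaults emulate a
small case/control microarray design: 6 samples per condition and
within-module correlations $\rho_1 = 0.95$, $\rho_2 = -0.85$, the size
of flip the method targets.

**Sign placement.** The first gene of each module is its *anchor* — the
planted proxy TF, which always loads positively. When $\rho_c < 0$,
$\lfloor m/2 \rfloor$ of the non-anchor genes load negatively. With a
positive $\rho_1$ and negative $\rho_2$ this flips the sign of roughly
half of *every* module gene's within-module links (anchor–target links
included). The alternative of negating every non-anchor gene was
rejected: pairwise correlations between two negated genes are unchanged
($(-1)(-1)|\rho|$), so only the anchor's links would flip, the
ground-truth claim that *all* module genes are differentially
coexpressed would be false for non-anchors, and they would be
undetectable in principle. The half-and-half design makes the ground
truth honest while preserving the anchor-TF flip pattern.

`baseline_rho` (default 0) adds a weak common factor to background
genes; it must be non-negative, since a common negative pairwise
correlation across many genes is not realizable. Identical seeds give
bit-identical output.

**Fixture bundle.** `write_fixture_bundle()` emits the expression and
label TSVs, a GMT with one set per module plus size-matched decoy sets
of background genes, a TF–target file with each anchor regulating its
module plus decoy TFs, and a ground-truth table. Decoy TFs *and their
targets* are background genes: a decoy edge must carry no planted
signal by construction, mirroring the decoy gene sets.
`make_fixture()` freezes the canonical validation fixture: 200 genes, 2
modules × 10 genes, **20 samples per condition**, 20 decoy TFs × 5
targets, 5 decoy sets. Twenty samples per condition — rather than the
generator's 6-per-condition default — is the size at which the DCG stage
has adequate power for recovery studies; it is also the size used for
the parameter-recovery and null-calibration analyses (1,000
permutations there; the 50-replicate fixture study uses 200
permutations per run, which measurably gives the same recovery rates).

**What the generator does not emulate:** probe-level noise,
batch/covariate structure (e.g. post-mortem delay), heavy-tailed or
count-distributed expression, hub-structured or overlapping modules,
and realistic correlation between target means and regulator activity.
Passing the recovery tests therefore shows the pipeline's statistics
behave as designed under a clean factor model — not that effect sizes
on real arrays will match.

## Pipeline, seeds, determinism

`run_pipeline()` executes dcg → enrich → network → rif from files,
writing fixed-name TSVs (6-decimal statistics), GraphML, and a JSON
manifest recording the package version, seed, every threshold applied
and all row counts. One master seed is split per stage by hashing the
stage name, so `run_stage()` reproduces any stage independently;
identical config + seed gives byte-identical tables. A thin command-line
front-end (`inst/scripts/dcrif.R`) exposes the stages as subcommands
over a YAML config.

## Known limitations

* **Single-target TFs are noisy RIF candidates.** A TF whose eligible
  target set is one gene gets a score with the full variance of a single
  squared correlation difference. Combined with the deliberate ~25%
  false-discovery admission rate at FDR < 0.25, a decoy regulator that
  picks up one false-positive DCG target can occasionally out-rank a
  genuinely planted regulator; in the canonical 50-replicate fixture
  study the planted anchor TF is top-ranked in 84% of runs (the planted
  pathway leads the enrichment table with $p < 0.05$ in all runs).
  Requiring a minimum target-set size before ranking would mitigate
  this, at the cost of silently dropping sparse regulators.
* A correlation sign flip at equal magnitude is invisible to RIF (the
  squared form), and a magnitude change without sign change is weak for
  the link-level interpretation of $dC$; conclusions should read the two
  statistics together.
* With 6 samples per condition (the design the defaults emulate),
  per-condition correlations have standard error ≈ 0.45 under the null;
  DCG calls at that size rest heavily on the permutation machinery and
  the lenient FDR cutoff, and should be treated as screening.
* Gene identifiers are matched case-sensitively with no aliasing; the
  probe-to-gene mapping of any upstream platform is the caller's
  responsibility.
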