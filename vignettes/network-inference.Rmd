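---
title: "Inferring TF regulatory networks from accessibility and expression"
author: "gremnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring TF regulatory networks from accessibility and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gremnet)
```

## The model

gremnet treats gene expression as the product of two unobserved factors:

$$X \approx A\,W,$$

where $X$ is a samples $\times$ genes expression matrix, $A$ a samples
$\times$ TFs matrix of latent transcription-factor activities, and $W$ a TFs
$\times$ genes matrix of signed regulatory weights. Neither factor is
observed, so the decomposition is anchored on chromatin: a binary prior $P$
(TFs $\times$ genes) is built from TF binding motifs found inside accessible
peaks near gene transcription start sites. Activities are then estimated by
inverting the linear system through the prior,

$$\hat A = X\,P^{+},$$

with $P^{+}$ the Moore–Penrose pseudoinverse, and the network $W$ is
re-estimated per gene by exhaustive best-subset regression of the gene's
expression on $\hat A$. An inferred network is validated in silico: knockout
activities (the perturbed TF's column set to zero) are multiplied by the
wild-type network and the predicted expression is scored against observed
knockout expression by $R^2$. In parallel, and independently of the factor
model, genes are classified by the joint direction and significance of their
expression and accessibility changes.

The key modelling assumptions are (i) linearity of regulation on the
log-expression scale, (ii) that motif occurrence in accessible chromatin is
informative about true regulation, and (iii) that the prior has full row
rank over the genes used for inversion — each TF must be distinguishable
from every other through its target set.

## Prior construction

Motifs are position weight matrices (MEME minimal format; HOCOMOCO-style
identifiers such as `CEBPA_MOUSE.H11MO.0.A` are parsed so the TF name is the
leading token). Scanning is FIMO-like: both strands, per-position score
$\sum_i \log_2 \frac{p_i(b_i)}{q(b_i)}$ against the background $q$, with a
pseudocount of $10^{-3}$ added to the PWM probabilities and rows
renormalised, so a completely uninformative motif scores exactly zero
everywhere. `N` bases contribute zero (background behaviour). Hits can be
thresholded by score or by p-value; p-values are exact, computed by dynamic
programming over the distribution of the discretised score (bins of
$10^{-3}$) under the background model. The same integer bins are used for
hit scores and for the distribution, so threshold and p-value are mutually
consistent; the table grows with motif length times score range, and
p-value mode is limited to motifs of length $\le 20$ (far beyond typical TF
motifs).

A peak is linked to every gene whose TSS lies within `window_bp` of the peak
midpoint (inclusive, strand-agnostic, midpoint $=\lfloor(start+end)/2\rfloor$).
The default window is 50 kb, configurable up to the hundreds of kb at which
distal enhancers still act; midpoint-to-TSS distance was chosen because it
is scale-free in the peak width. The prior entry $(t, g)$ is 1 when some
peak linked to $g$ contains at least one hit of a motif mapping to $t$
(binary mode; weighted mode counts hits). The prior is binary by default
because the pseudoinverse is sensitive to row scaling and no principled
edge-weighting scheme presents itself; every edge records its supporting
(peak, motif, offset, strand) evidence. Enlarging the window can only add
edges, and the result is invariant to the input order of peaks and hits.

## Activity estimation

`estimate_tfa()` restricts $X$ and $P$ to shared genes, centers each gene
across samples (default; the model has no intercept, so centering absorbs
baseline expression — recovered activities are then defined up to their
per-TF mean), and computes $\hat A = X P^{+}$ by SVD, zeroing singular
values below `rtol` ($10^{-10}$) times the largest. SVD was chosen over the
normal equations because binary priors are routinely rank-deficient and the
minimum-norm solution must be defined rather than incidental. TFs whose
prior row is empty fall back to their own centered expression when the TF is
itself a gene in $X$ (tagged `self_expression`), else they are dropped with
a warning.

An unsigned prior carries no information about regulatory sign. When
activating and repressing edges are balanced, $\hat A = A\,(W P^{+})$ mixes
activities through a matrix with near-zero diagonal and TF activities are
not identifiable through the prior; when activation dominates, $W P^{+}$ is
diagonal-dominant and inversion works. This is why the synthetic generator
defaults to activation-dominant networks (below), and why the exactness
claims are stated in the exact-model regime.

## Best-subset network inference

For each gene, up to `n_preselect` (default 10) candidate TFs are kept:
prior-supported TFs first, each group ordered by decreasing absolute Pearson
correlation with the gene's expression, exact ties broken by TF id in byte
order; a TF whose id equals the gene id is excluded (no self-edges). All
candidate subsets up to `max_subset_size` are enumerated — at most
$2^{10} = 1024$ models per gene — and scored on centered data by

$$\mathrm{BIC}(M) = n \ln(\mathrm{RSS}_M / n) + |M| \ln n,$$

optionally minus `prior_inclusion_bonus` per prior-supported member. This
BIC enumeration with exponential model weights stands in for the Zellner
g-prior machinery of classical Bayesian best-subset regression: it is
transparent, deterministic, hyperparameter-free, and checkable against an
independent exhaustive implementation, while keeping the two places prior
knowledge can act (candidate ordering and the optional BIC bonus) explicit.
The subset enumeration runs in compiled code from precomputed Gram
matrices; the test suite holds it to $10^{-8}$ agreement with a pure-R
QR-based enumeration.

The best model minimises the (effective) BIC; enumeration order — size
first, then lexicographic — combined with strict improvement makes every
tie resolve to the smaller, then lexicographically earlier subset, so
results are bit-reproducible. Reported weights are model-averaged,
$\bar\beta = \sum_M w_M \beta_M$ with
$w_M \propto \exp(-\tfrac12(\mathrm{BIC}_M - \mathrm{BIC}_{\min}))$, over
all enumerated subsets. The confidence of a TF $t$ in the best model is
$\max(0,\, 1 - \mathrm{RSS}_{best}/\mathrm{RSS}_{best \setminus t})$, where
$best \setminus t$ is the best-scoring model among those excluding $t$;
TFs outside the best model have confidence exactly 0. Degenerate cases are
pinned down: collinear subsets fall back to ridge with $\lambda = 10^{-8}$
and are flagged; inside the BIC the RSS is floored at
$10^{-12}\sum(y-\bar y)^2$ so numerically exact fits are ranked by the
parameter penalty rather than by the logarithm of rounding noise (the raw
RSS is still reported); a zero-variance response yields an empty candidate
list and a zero column.

## Knockout simulation and $R^2$

`simulate_expression()` zeroes network edges below a confidence threshold
(default 0: the model states no cut, so all inferred edges are used) and
computes $\hat X = A_{cond} W$. `r_squared()` compares prediction to
observation after per-gene centering of the observed matrix:

$$R^2 = 1 - \frac{\sum (x - \hat x)^2}{\sum (x - \bar x_g)^2},$$

pooled over all matched entries (global mode, the headline number) or per
gene. Zero-variance genes are excluded and counted. $R^2$ never exceeds 1
and is negative for predictors worse than the per-gene mean.
`evaluate_perturbation()` additionally centers the prediction per gene,
because inferred networks are fit on centered expression and the simulated
matrix therefore lives in centered space.

## Concordance classification

Expression records are called up/down when the BH-adjusted p-value is at
most `rna_alpha` (0.05) **and** $|\log_2 FC| \ge$ `rna_lfc` (0.25);
accessibility analogously with `atac_alpha` (0.05) and `atac_lfc` (0.1).
All four comparisons are inclusive at the boundary, and a missing adjusted
p-value is never significant. When a gene has several peaks, it inherits
the record of the peak with the smallest adjusted p-value (ties: larger
$|\log_2 FC|$, then lexicographically smaller peak id) — best-peak
aggregation preserves directionality where averaging across peaks with
opposite signs would not. The label is a pure function of the two states
(concordant up/down, discordant, expression-only, accessibility-only,
neither), so the classifier is testable against a brute-force filter. The
sign orientation of both fold-change columns (KO-vs-WT or WT-vs-KO) is the
caller's responsibility and must be consistent between the two tables.

The bundled `simple_differential()` (per-gene Welch $t$ with BH adjustment,
log fold change as difference of group means on the log scale) exists so
synthetic end-to-end runs need no external differential machinery; on real
data the dedicated count-model tools should be used upstream and their
tables read with `read_diff_table()`.

## Single-cell preprocessing

`qc_filter()` applies three filters in a fixed, auditable order: cells with
fewer than 200 detected genes (count > 0), then genes detected in fewer
than 10 of the remaining cells, then cells whose mitochondrial count
fraction exceeds 0.15 (computed on the remaining genes; strictly greater
removes). A cell exactly at a threshold is retained. The report records
what each step removed. `normalize_log1p()` scales each cell to a total of
10,000 counts and applies $\ln(1+v)$. Dimensionality reduction and
clustering are deliberately out of scope — nothing downstream consumes
them.

## The synthetic generator

`generate_truth()` draws the system the analysis assumes: a network with
exactly `edges_per_gene` regulators per gene, activities per condition, and
the knockout as zeroed activity columns for the perturbed TFs against an
otherwise identical distribution — mirroring how the knockout simulation
uses knockout activities with the wild-type network. Defaults: 20 TFs, 400
genes, 300 samples per condition, 3 regulators per gene, weight magnitudes
$\sim U(0.5, 1.5)$, Gaussian $N(0,1)$ activities, additive Gaussian noise
of sd 0.25 on the latent expression, prior corruption at a 2% false-edge
and 20% missed-edge rate, one knocked-out TF. These sizes keep a full
generate–invert–infer–simulate cycle under a few seconds while leaving the
system comfortably identifiable; the full acceptance suite (including a
60-run noise sweep) completes in minutes on one CPU.

Three generator choices deserve emphasis:

* **Edge signs.** Edges are activating with probability `activation_prob`
  (default 0.8). A sign-balanced network is not identifiable through an
  unsigned prior (see above), and the generator's stated contract is to
  produce identifiable systems at its defaults; activation-dominant
  regulation is also the empirically common regime. The parameter is free,
  so sign-balanced stress tests remain available.
* **The exact-model regime.** `weight_model = "unit"` sets every weight to
  +1, making the binary prior equal to the network itself. With zero noise
  this is the regime in which pseudoinversion recovers activities exactly
  and BIC enumeration recovers the exact support — the regime the
  exactness tests run in. The default `"signed_uniform"` model is used for
  all noisy-recovery tests.
* **Activity models.** Gaussian activities are mean-zero, so a knockout
  changes covariance but not mean expression — appropriate for testing the
  factor model, useless for differential expression. The lognormal model
  (logN(0,1), positive mean) makes knockouts shift target means and is the
  regime for concordance experiments.

`generate_scaffold()` realises the prior physically: one synthetic
chromosome, genes spaced more than two windows apart (so a planted peak can
only link to its intended gene), one peak with an embedded motif occurrence
per retained true edge, decoy peaks at the false-edge rate, and optionally
actual ACGT sequences with the consensus site written in at the hit offset.
Rebuilding the prior from a zero-error scaffold reproduces the true support
exactly — a closure property the tests assert. Counts, peaks, TSSs, motifs
and hits can all be written to their standard file formats, so every stage
also runs file-in/file-out.

What the generator does **not** emulate: single-cell dropout and
overdispersion beyond the optional Poisson/negative-binomial layer,
nonlinear or combinatorial regulation, indirect (cascade) effects of a
knockout, peak-width and signal heterogeneity, and sequence composition
bias. Passing tests therefore demonstrate correctness of the machinery and
recoverability under the stated generative model — not performance on real
chromatin and expression data, where the linearity and motif-fidelity
assumptions are approximations.

## Numerical and reproducibility choices

All randomness flows through a fixed RNG (Mersenne–Twister, inversion
sampling for normals) from explicit integer seeds; condition-specific
sub-seeds are derived deterministically from the bundle seed, so a bundle
regenerates bit-identically. All string ordering uses byte (radix) order,
never the locale. Writers emit floating point at 12 significant digits with
fixed row order, so rewriting the same object is byte-identical. Internal
coordinates are 0-based half-open throughout (BED convention), including
TSS tables and motif-hit offsets. Determinism of every stage, including the
command-line wrapper, is asserted in the test suite.

## Limitations

Single-task inference only (no joint estimation across conditions, no
time-series variants, no bootstrap ensembling); no non-negative or sparse
activity decompositions; the p-value scanner's null is the single-strand
background distribution applied to the best-of-strands score; confidence
scores order edges well but are not calibrated probabilities; and the
$R^2$ of a knockout simulation on real data depends on normalisation
choices the caller controls.
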