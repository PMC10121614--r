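---
title: "perfuseq: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{perfuseq: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`perfuseq` analyses single-cell RNA-seq of donor-organ immune cells
sampled before (`T0`) and at the end (`T1`) of normothermic machine
perfusion. This vignette is the package's own account of the statistics it
implements: the models and their assumptions, every constant that matters,
what the synthetic generator does and does not emulate, and the choices we
made where the design was genuinely open.

## 1. The statistical backbone: patients are the replicates

Cells from one donor are correlated; treating them as independent
observations overstates evidence badly. Every inferential stage therefore
collapses cells to the donor level first:

* differential expression runs on **pseudo-bulk** sums per
  (cell type, patient, timepoint);
* marker calling runs on pseudo-bulk per (subcluster, patient);
* communication receptor fractions are **means of per-patient fractions**,
  never pooled cell counts.

### Pseudo-bulk construction

For each cell type, a gene is retained when it is detected (count > 0) in
at least 5 % of that type's cells. The 5 % rule is evaluated pooled over
both timepoints: the source text states only "at least 5 % of cells", and
pooling is the simplest literal reading that also keeps one gene universe
per cell type (the same universe later serves as the ORA background).
Samples with fewer than 1000 retained-gene counts or fewer than 10 cells
are discarded; "expressed" always means raw count > 0 — detection, not an
abundance threshold.

### The negative-binomial Wald test

Per gene $g$ and sample $j$:

$$K_{gj} \sim \mathrm{NB}(\mu_{gj}, \alpha_g), \qquad
\log \mu_{gj} = \log s_j + \gamma_{\mathrm{patient}(j)} + \beta_g\, t_j,$$

with median-of-ratios size factors $s_j$ (rescaled to geometric mean one)
entering as offsets, patient indicators $\gamma$ (the paired design), and
$t_j \in \{0, 1\}$ the timepoint. The reported effect is
$\beta_g / \log 2$, the Wald statistic $\beta_g / \mathrm{SE}(\beta_g)$ is
referred to a standard normal, two-sided, and BH controls the FDR over
tested genes. Genes at zero in every sample are reported with missing
statistics rather than $p = 1$, keeping the multiple-testing universe
honest.

**Pairing.** The design pairs timepoints within patient by default because
the same organs are measured at `T0` and `T1`; `paired = FALSE` is
available for unpaired cohorts.

**Dispersion — the one place we overruled the obvious estimator.** A naive
method-of-moments dispersion
($\hat\alpha = \max\{\sum[(y-\hat\mu)^2 - \hat\mu]/\sum\hat\mu^2,\,10^{-8}\}$
on Poisson-fitted means) ignores that the paired design spends ~10 of 16
degrees of freedom on the mean structure. On null simulations from our own
generator it produced raw $p<0.05$ fractions around 0.12–0.13 —
anticonservative by more than a factor of two. We therefore match the
*Pearson statistic to its residual degrees of freedom*:

$$\sum_{j} \frac{(y_j - \hat\mu_j)^2}{\hat\mu_j (1 + \alpha\,\hat\mu_j)} =
n - p,$$

solved for $\alpha$ (floor $10^{-8}$). Solved gene-wise this is still
slightly anticonservative (~0.06) because $\hat\alpha$ itself is noisy at
six residual degrees of freedom, so by default the match is **pooled
across genes within ten mean-quantile bins** (`dispersion = "pooled"`),
which removes the estimator noise; measured null fractions then sit at
0.04–0.05. `dispersion = "genewise"` remains available. The pooled
estimator assumes dispersion varies smoothly with expression level — true
by construction in the generator, an approximation on real data; with
strongly gene-specific overdispersion the gene-wise option is the safer,
more conservative choice.

**FDR weighting.** Exact independent hypothesis weighting is out of scope;
`adjust_pvalues(method = "binned")` is a budget-preserving stand-in: genes
are binned by base mean, each bin is weighted by its estimated non-null
fraction ($1-\hat\pi_0$, with $\hat\pi_0 = \min(1, 2\,\overline{[p>0.5]})$,
floored at 0.05), weights are normalized to mean one, and BH is applied to
$p_i / w_i$. Uniform weights reduce it to BH exactly.

## 2. QC, clustering, annotation

QC keeps cells with 250–8000 detected genes (inclusive), 1000–100000
transcripts (inclusive) and < 30 % mitochondrial counts (strict) — the
interval wording is read as closed, the "<" as strict. Mitochondrial genes
are symbols with a case-insensitive `MT-` prefix, overridable via the
`is_mito` gene metadata column. Cells with zero counts get `pct_mito = 0`
by convention. Doublet handling accepts external labels (the generator's
truth, mirroring a trained classifier upstream) and otherwise flags cells
above the 99.5th percentile of total counts.

HVG selection is the "seurat_v3 flavour, batch = patient" procedure: per
batch, a loess trend (span 0.3, degree 2) of $\log_{10}$ variance on
$\log_{10}$ mean of raw counts; counts standardized against the trend and
upper-clipped at $\sqrt{n}$ expected standard deviations; the variance of
the clipped standardized values is the score. Genes are ranked by how many
batches place them in the per-batch top-$N$, ties by median per-batch
rank, then stable input order. Batches with fewer than two cells are
excluded with a warning; if fewer than ten genes have positive variance the
trend cannot be fitted and raw variances are used, so fully degenerate
inputs fall back to stable gene order.

Clustering replaces the original latent-variable embedding (out of scope)
with median-depth log-normalization, per-gene standardization clipped at
±10, PCA via an exact eigendecomposition (deterministic sign convention:
the largest-magnitude loading of each component is positive), a
symmetrized kNN graph, and Leiden modularity communities under a fixed
seed. The contract is behavioural — planted partitions must be recovered
exactly and repeated runs must agree — not tied to one optimizer.

Annotation scores each cluster against each marker panel by the mean
log-normalized panel expression over member cells; the label is the
arg-max, and a non-positive or tied top score yields `"unassigned"`.

## 3. Subcluster markers

Within one cell type, pseudo-bulk is built per (subcluster, patient),
pooling timepoints (the grouping is not fully specified upstream; pooling
maximizes samples per subcluster). Profiles are normalized to
$\log_2(\mathrm{CPM} + 1)$ — the marker procedure needs a normalized
scale and CPM is the conventional choice on pseudo-bulk — and each
subcluster is compared one-vs-rest: AUROC (tie-aware Mann–Whitney,
`U/(n_g n_r)`) plus difference of mean log2-CPM. Marker gates are a
registry keyed by cell type: AUROC > 0.7 with lfc > 1 for neutrophils,
lfc > 2 for monocytes/macrophages, (0.7, 1) otherwise.

## 4. Differential cell–cell communication

The algorithm asks a direction-specific question: *given that a sender's
ligand changed between timepoints, who can hear it?* For each sender cell
type, ligands in the interaction database with DE $p_{\mathrm{adj}} \le$
`ligand_fdr` (default 0.05; the upstream cutoff is unstated, so the gate
is explicit in config and output) seed edges to every annotated cell type
— including the sender, since autocrine loops are biologically real — in
which **every receptor subunit** is detected in at least 10 % of cells.
The fraction is the unweighted mean of per-patient fractions, which is
exactly invariant to replicating any patient's cells — the property that
protects against unequal per-donor capture. A multi-subunit **ligand**
qualifies when any subunit passes the DE gate; a multi-subunit
**receptor** requires all subunits to pass the detection gate, and the
edge carries the minimum subunit fraction (a complex works only if its
scarcest part is present) and the mean over subunits of patient-averaged
mean log-normalized expression. Edges are deduplicated per
(sender, interaction, receiver), keeping the best ligand subunit, and
sorted by (sender, ligand, receiver, receptor) so output is independent of
cell and database order. Fractions are computed on cells pooled over
timepoints; a per-timepoint variant is a matter of subsetting the input.

## 5. TF activity and over-representation

TF activity fits one ordinary least-squares model of the per-gene log2
fold change on the gene × TF matrix of regulon weights (signed ±1 by
regulation mode unless a weight column is supplied; only confidence A/B
regulons by default), with an intercept, unstandardized — whether the
reference implementation standardizes its design is undocumented, so we
chose plain OLS and say so. Each TF's $t = \hat\beta/\mathrm{SE}$ with
residual degrees of freedom measures coordinated target shifts while
competing against all other regulons; rank-deficient designs drop
collinear regulons with a warning.

ORA equalizes power across cell types before testing: $N$ is the median
(lower middle value for even counts, so $N$ is always an attained count)
of per-cell-type significant-gene counts at FDR < 0.01 and |lfc| > 1;
each cell type contributes its top $N$ genes (ranked by `padj`, then
|lfc| descending, then gene name — a total order, so output is
deterministic). The universe for each cell type is exactly the genes
tested in its DE (post-5 %-filter): the selection pool and the test
universe must coincide or the hypergeometric margins are wrong. The
p-value is the upper tail $P(X \ge \mathrm{overlap})$.

## 6. The synthetic cohort: what it emulates, what it does not

`sim_config()` defaults are the stated world, fixed before any test was
run:

| parameter | default | why |
|---|---|---|
| donors × timepoints | 8 × (T0, T1) | the cohort design |
| cell types | 10, ~45 % neutrophils at 0.5× depth | unequal abundance; mean totals calibrated to ~4100 overall vs ~2050 in the low-mRNA majority |
| genes | 2000 incl. 13 `MT-` | desk-scale; mito means scaled so ~5 % of cells exceed the 30 % gate |
| NB dispersion α | 0.4 | common single-cell scale; makes the DE model's assumption literal |
| patient depth effect | lognormal, σ = 0.4 | the per-donor imbalance the mean-of-fractions rule exists to guard against |
| planted DE | 30 genes/type in 6 types, lfc ±1.5; ligands among them | recoverable but not trivial at pseudo-bulk depth |
| subcluster markers | N0–N3 at 40/30/20/10 %, 15 genes, lfc 3 | the four-subset structure marker calling must resolve |
| receptor fractions | 0.40 planted / 0.01 background | unambiguous margins around the 0.10 gate |
| doublets | 2 %, element-wise sums within a sample | position of the removal step |

Counts are gene-wise negative binomial with mean
`baseline × patient factor × cell-type multiplier × 2^lfc`; receptor-gene
means are inverted from target detection fractions
($\mu = ((1-f)^{-\alpha}-1)/\alpha$). Doublets are sums of two cells from
the same (patient, timepoint) sample. Identical config and seed give
bit-identical output; the matrix is assembled directly in compressed
column format for speed.

Deliberately **not** emulated: UMI/read-level noise, ambient RNA, batch
effects beyond donor depth, per-gene dispersion heterogeneity,
reperfusion (`T2`) biology, and any correlation structure between genes
beyond the planted blocks. A green recovery test therefore establishes
that the algorithms do what they claim under their own assumptions — not
that those assumptions hold on any particular real dataset.

## 7. Numerical conventions and degenerate inputs

* Dispersion floor $10^{-8}$; GLM convergence $10^{-10}$, 50 iterations.
* Label-swap symmetry of the DE test holds to ~$10^{-8}$ (IRLS
  tolerance); scaling one gene by a constant preserves its statistics up
  to the dispersion refit, which is $O(1/\mu)$ — a negative binomial is
  not exactly closed under scaling.
* AUROC of identical constant vectors is 0.5 (all ties count half).
* `estimate_size_factors` falls back to total-count ratios (with a
  warning) when no gene is nonzero in all samples.
* All writers use TSV (gene aliases can contain commas), MatrixMarket for
  counts; every pipeline stage writes a JSON manifest of input, parameter
  and output hashes, so reruns skip clean stages and recompute corrupted
  ones.
* Logging is one line per filter decision class with counts — never
  per-cell output.

## 8. Known limitations

* No dispersion or fold-change shrinkage: effect estimates for very low
  counts are noisier than a shrinkage estimator's would be.
* No GLM outlier handling (Cook's-style) — a single aberrant pseudo-bulk
  sample can drive a gene's statistic.
* The pooled dispersion assumes a smooth mean–dispersion relationship
  (Section 1).
* The communication stage inherits the DE stage's error rates: a
  false-positive ligand propagates to all its edges.
* The binned FDR weighting is a stand-in for IHW, not a reimplementation;
  with an uninformative covariate it can only lose a little power relative
  to BH, never control.
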