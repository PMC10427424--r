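---
title: "Methods: clonotype dynamics, immune signatures and clinical statistics"
author: "clonalrevival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonotype dynamics, immune signatures and clinical statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalrevival)
```

# Scope

`clonalrevival` implements the translational analysis pipeline of a
neoadjuvant anti-PD-L1 trial in esophageal squamous cell carcinoma:
TCR-beta repertoire metrics, tracking of intratumoral T cell clonotypes
(ITCs) through paired tumors and longitudinal blood, expression-based
immune signatures and tumor-microenvironment (TME) subtyping, neoantigen
binding-filter cascades, and the trial-level clinical statistics. Because
the patient-level data of such trials are controlled-access, the package
ships a synthetic cohort generator with planted ground truth; every
downstream stage is exercised and tested against it.

# TCR repertoire metrics

A clonotype is a unique rearranged TCR-beta identity — by default the
triple (CDR3 amino-acid sequence, V segment, J segment); nucleotide-level
keying is available via the `key = "nt"` flag on the table constructors.
Quality control retains *productive* CDR3s only: no stop (`*`) or
frameshift (`_`) symbol, length at least 5 residues, starting with `C`
and ending with `F` or `W`. (The length rule is interpreted in amino-acid
residues, since it concerns the amino-acid sequence.) Frequencies are
re-normalized over the retained records.

**Richness** is the number of unique productive clonotypes.
**Clonality** is

$$ 1 - \frac{H}{\ln R}, \qquad H = -\sum_i f_i \ln f_i , $$

with natural logarithms and normalization by $\ln R$ (richness $R$). A
value of 0 is a maximally diverse repertoire (every template its own
clonotype), 1 a monoclonal population. For $R = 1$ the ratio is
undefined; we return 1 by convention, the limit of a maximally dominated
repertoire. Whether clonality is computed before or after productive
filtering is the caller's choice; the intended workflow filters first.

# Clonal dynamics

ITCs are the clonotypes shared between a patient's pre- and
post-treatment tumor repertoires. For every clone pair the frequency
direction gives the category (expanded / contracted / unchanged; `new`
and `lost` for clones absent on one side), and a two-sided Fisher exact
test on

$$ \begin{pmatrix} c_{pre} & N_{pre}-c_{pre} \\ c_{post} & N_{post}-c_{post} \end{pmatrix} $$

flags *differential* expansion or contraction at unadjusted $p < 0.05$,
as in the trial's per-clone analysis; Benjamini–Hochberg adjustment is
available behind a flag. `new`/`lost` clones are never Fisher-tested —
the test is defined for ITCs — and ties with nonzero counts are
`unchanged`. Clonal space is the summed frequency of a clone set relative
to the whole repertoire; the denominators use productive-only totals.
Frequency decade ranks follow the seven bins $10^0, 10^{-1}, \dots,
10^{-6}$, assigning each clone the bin $10^{\lfloor \log_{10} f
\rfloor}$ clamped below at $10^{-6}$.

# Expression signatures

Input is a genes-by-samples matrix of $\log_2(\mathrm{FPKM}+1)$. The
mean-expression immune scores (CD8 lineage, exhaustion, chemokine,
HLA-II, dendritic cell) are arithmetic means over their marker genes;
the chemokine list corrects the symbol variant `CXLC9` to `CXCL9` via a
documented alias map. Cytolytic activity is the geometric mean of GZMA
and PRF1 on the linear scale.

Single-sample GSEA ranks each sample's genes by expression (ties
averaged) and accumulates, over gene positions in decreasing-expression
order, the weighted in-set empirical CDF (weights $r^{\tau}$, default
$\tau = 0.25$, normalized over set members) minus the out-of-set ECDF;
the enrichment score is the sum of that running difference. Tied
expression values are walked in a fixed gene order so results are
deterministic. Scores are normalized by the global (max − min) spread,
then the hallmark presentation z-scores each hallmark across samples and
clips to $[-2, 2]$.

The IFN/EMT signature selects candidate genes from the EMT, IFN-α and
IFN-γ sets with an absolute group-mean difference of at least 1 log2
unit (two-fold linear; boundary inclusive), then fits an elastic net of
the binary response (well = 1, poor = 0):

$$ \min_{\beta_0,\beta}\; \frac{1}{2n}\lVert y - \beta_0 - X\beta
\rVert^2 + \lambda\left[\alpha\lVert\beta\rVert_1 +
\tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\right], \qquad \alpha = 0.5,\;
\lambda = 0.24, $$

with predictors standardized to unit $1/n$ variance. The solver is
cyclic coordinate descent with exact soft-threshold updates (converged
to $10^{-12}$); this keeps the penalty exactly in the convention above —
popular implementations additionally standardize the response, which
rescales the effective $\ell_1$ penalty. Genes with nonzero coefficients
form the signature; the standardization parameters are frozen in the
model so later scoring reproduces the training-time fit. The number of
selected genes is a property of the cohort, not a target of the fit.

# TME subtypes

Samples are clustered on their scaled hallmark scores: rows z-scored,
Euclidean distance, Ward linkage on squared distances (`ward.D2`), tree
cut at $k = 3$. Clustering is agglomerative and deterministic. The
"half-supervised" step is the labeling: each cluster is named for the
hallmark group with the highest mean scaled score inside it —
immune-enriched (IFN-α/IFN-γ/inflammatory), tumor-proliferation
(E2F/MYC/DNA repair/mTORC1) or fibroblast-enriched
(EMT/TGF-β/KRAS/angiogenesis). Exact ties fall back to a fixed priority
(IE first) with a warning, and no two clusters may share a label: the
stronger cluster wins and the weaker takes its best unused group. New
samples are assigned to the nearest centroid in Euclidean distance. The
hallmark list defaults to the eleven subtype-defining hallmarks and is
fully configurable; additional feature rows can be appended by the
caller.

# Neoantigen linkage

Neoantigens inherit a persistence class from their source mutation:
*clearance* (pre-treatment only), *novel* (post-treatment only),
*persistent* (both). Binding filters are applied as printed in the
field: predicted MHC affinity strictly below 500 nM, then TCR–pMHC
percentile rank at most 2.0 (inclusive at the boundary — the strictness
is not specified, so the inclusive choice is documented and
configurable). The high-affinity ITC burden counts distinct clonotypes,
not pairs. Associations with pathological response use a two-sided
Pearson correlation with a $t$-distributed p-value on $n-2$ degrees of
freedom. TMB divides the nonsynonymous mutation count by the 33.86 Mb
assayed panel.

# Clinical statistics

Pathological response is classified by percent residual viable tumor:
pCR at 0, MPR at most 10 (pCR is a subset of MPR), pPR in (10, 33], pNR
above 33; well responders have at most 33% residual tumor. The 33%
boundary is assigned to the well-responder side, following the stricter
tabulated definition ("33% or fewer"). CPS is PD-L1-positive cells per
100 tumor cells, capped at 100 per assay convention.

Kaplan–Meier estimation and the log-rank test are implemented with
optional per-subject weights (weighted risk sets and event counts;
deaths precede censorings at tied times), since the inverse probability
of treatment weighting (IPTW) comparison needs weighted versions that
standard unweighted routines do not supply; the unweighted special cases
are verified against the standard survival routines in the tests.
Greenwood standard errors give pointwise intervals, and the fit reports
12- and 24-month survival. Propensity scores come from a multinomial
logistic model of arm on tumor site and clinical stage; weights are
$1/\hat P(\text{assigned arm}\mid \text{covariates})$, stabilized by the
marginal arm probabilities by default (the stabilized ATE estimand;
configurable). Perfect separation (a covariate level exclusive to one
arm) is reported as an error naming the level. Balance uses the
standardized mean difference with pooled-SD denominator and the
conservative 0.25 cutoff; categorical covariates expand to per-level
indicators. Hazard ratios are deliberately *not* re-implemented: a
standard proportional-hazards routine should be used and reported
pass-through.

The feasibility design is a Simon two-stage rule: 6 patients in stage 1,
continue only with 5 or more successes, success declared if more than 23
of 27 total succeed. Operating characteristics are exact binomial sums;
for example the early-stopping probability at a true success rate $p$ is
$P(\mathrm{Bin}(6, p) \le 4)$. The trial's auxiliary monitoring
probabilities are ambiguous as printed and are not implemented.

# The synthetic cohort generator

The generator's defaults are the study conditions the tests assume:

* **Repertoires.** Clone frequencies follow a truncated power law
  ($p_i \propto i^{-a}$, default $a = 1$ over 1,000 clones, top clone
  about 13%) and counts are one multinomial draw of the configured depth
  (default $10^5$ templates, matching the scale at which the recovery
  properties are stated), conditioned on every clone being observed.
  CDR3 strings are productive by construction; nonproductive spike-ins
  are explicit, labeled and used only for QC tests.
* **Paired tumors.** Half of the pre-treatment clones persist; of these
  25% are planted expanded (frequency multiplied by 5 in well
  responders, 1.5 in poor), 50% contracted (factor 0.3, echoing the
  dominance of contraction among ITCs under therapy), 25% stable. New
  clonotypes carry 25% of the post-treatment mass. Planted-stable clones
  keep their *relative* frequency exactly — the moving masses absorb the
  renormalization — so the per-clone Fisher null is true for them by
  construction, which is what makes the false-call property measurable.
  A 5-fold planted expansion realizes as a ~4.6-fold frequency ratio
  after renormalization.
* **Blood series.** A configurable subset of ITCs circulates with mass
  following per-timepoint scale factors over a power-law background.
* **Expression.** Per-gene baselines Uniform(2, 8) with within-group
  noise sd 0.5 — typical of moderately expressed genes on the log2 FPKM
  scale. Responder status shifts the planted IFN/EMT signature genes by
  2 log2 units; each sample's TME subtype shifts its defining hallmark
  gene sets by 2 log2 units.
* **Clinical.** Residual tumor is drawn consistently with the responder
  label. Survival is exponential with a stage hazard ratio of 2 and a
  configurable arm effect (default null), with stage shifting the odds
  of experimental-arm assignment by 1.5 log-odds — a planted confounder
  with closed-form truth, which is what the IPTW recovery tests need.
  Administrative censoring at 36 months.
* **Neoantigens.** Affinities log-normal around 400 nM; true-binder
  TCR pairs get ranks in (0, 2] and are Poisson-enriched in well
  responders (mean 12 vs 3 per patient).

A master seed is split deterministically into per-component streams so
modules can be regenerated independently; identical configuration and
seed give byte-identical output. Sequencing depth per sample is not
published for the motivating study, so the default is an explicit,
configurable choice.

What the generator does *not* emulate: V(D)J recombination statistics,
sequencing error, read-level data, gene–gene correlation structure,
batch effects, or informative censoring. Passing tests therefore
demonstrate correctness of the computations and recoverability of
planted effects under idealized sampling noise — not performance on real
cohorts.

# Numerical choices and degenerate inputs

* Entropy uses natural logs; clonality of a richness-1 table is 1 by
  convention; an empty table is an error.
* Fisher tests use the standard two-sided exact rule (sum of all table
  probabilities not exceeding the observed one, with a $10^{-7}$
  relative tie tolerance); the tests verify agreement with a brute-force
  hypergeometric enumeration to $10^{-10}$.
* ssGSEA tie-breaks: average ranks for weights, fixed gene order for the
  walk; a gene set covering the whole matrix is rejected because the
  out-of-set ECDF is undefined; zero-variance hallmark rows scale to
  zero with a warning.
* The elastic net drops zero-variance predictors before fitting and
  errors informatively when the penalty empties the model.
* Degenerate subtype mixes (for example all samples planted in one
  subtype) still cut three clusters; the labeling then warns about tied
  group scores rather than failing silently.
* Problem sizes in the test-suite simulations (100 seeds for the
  recovery properties, 10,000 replicates for the size calibrations,
  depth $10^5$) are the sizes at which the stated properties are
  defined.

# Known limitations

* The exact 13-hallmark panel and the published 134-candidate/12-gene
  signature membership of the motivating study are cohort-specific and
  not reproducible from public information; the package reproduces the
  *procedures*, parameterized.
* The ssGSEA normalization constant depends on the whole matrix, so
  scores are comparable within a run, not across cohorts.
* IPTW p-values ignore the uncertainty of the estimated propensity
  model (standard practice; slightly conservative in the null
  simulations).
* The log-rank statistic relies on its asymptotic chi-square
  distribution; at very small risk sets an exact or permutation approach
  would be preferable.
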