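---
title: "Methods: comparative Hi-C analysis across two species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative Hi-C analysis across two species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical methods: the
models, the tunable parameters and why their defaults are what they are,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

# The comparative problem

Two related species are assayed with Hi-C in a small balanced panel
(by default four individuals per species, balanced for sex and two
processing batches). The genomes differ by rearrangements, so bin
coordinates are not directly comparable, and per-species contact calling
has unequal power. The pipeline therefore (i) maps bins across assemblies
with a reciprocal-best-hits rule, (ii) pools contacts called in *any*
individual into one union list and extracts every individual's normalized
frequency for every union pair — so downstream comparisons do not depend
on where a contact was first detected — and (iii) models each contact's
frequency across individuals with fixed species, sex and batch effects.

# Contact calling and the distance-decay null

For one individual with library total $N$, the count of a bin pair at
genomic distance $d$ is compared against
$X \sim \mathrm{Binomial}(N,\ \lambda(d)/N)$ with upper-tail p-value
$P(X \ge k)$. $\lambda(d)$ is the mean observed count over all possible
intrachromosomal pairs at distance $d$ (zeros included), smoothed over
log-spaced distance bands holding at least 100 possible pairs, linearly
interpolated in log distance, and rescaled so the implied total equals
$N$. Assumptions: contacts are intrachromosomal and distance decay is the
dominant systematic effect. The full fragment-level bias corrections of
production Hi-C pipelines (GC, mappability, coverage balancing) are
deliberately out of scope; the expectation here is a distance-only
stand-in estimated from the data themselves.

Pairs with unadjusted $p \le 0.01$ (inclusive) are "significant"; no
multiple-testing correction is applied at this stage because the tests
are strongly spatially correlated and the retained set is only used to
seed the union list. Normalized frequency is
$\log_2\!\big((k + c)/(\lambda(d) + c)\big)$ with pseudocount
$c = 0.5$; the pseudocount keeps the ratio finite at zero counts but
shrinks log-ratios toward zero when $\lambda(d)$ is of order one, which
is why validation experiments that measure effect recovery use
configurations with tens of reads per pair.

# Orthology mapping

The orthology map is a set of equal-length alignment blocks (strand
`+`/`-`). A bin is forward-mapped, its image's start and end are rounded
independently to the nearest bin boundary (half-up ties — the tie rule is
an arbitrary choice, stated rather than silently assumed), and the
rounded bin is mapped back; acceptance requires the round trip to return
the source bin exactly. Images spanning a block edge are rejected
(`split_block`) because a liftOver-style tool's behaviour on split hits
is tool-specific; rounding happens *before* the reciprocity check, an
ordering the package fixes explicitly. Minus-strand targets are reported
in forward coordinates; strand is retained but plays no role in
frequency comparison. Domain-scale intervals are transferred piecewise:
at least 90% of the interval must be aligned, the pieces must land on one
target chromosome, and the reciprocal transfer must overlap the original
by the same fraction.

# The per-contact model

For contact frequencies $Y_{ij}$ (individual $j$, species $i$):
$$Y_{ij} = \beta_0 + \beta_{sp} s_i + \beta_{sx} x_j + \beta_{btc} b_i +
\varepsilon_{ij},$$
fitted by ordinary least squares for every contact simultaneously, with a
two-sided $t$-test on $\beta_{sp}$ and Benjamini–Hochberg adjustment
across contacts. This is a plain-OLS simplification of moderated
(empirical-Bayes) linear modelling: with eight individuals the residual
df is small and a moderated variance would be tighter, so the package's
p-values are somewhat conservative; calibration tests hold the nominal
type-I error and realized false-discovery proportion. Contacts with zero
variance get $p = 1$ rather than `NaN` so FDR vectors stay complete;
covariates perfectly confounded with species are dropped with a warning.

Before modelling, frequencies are normalized across individuals by
pairwise cyclic loess (span 0.3), iterated until the largest per-contact
adjustment falls below $10^{-3}$ or 10 cycles. The smoothing is delegated
to `limma::normalizeCyclicLoess(method = "pairs")`, wrapped in the
convergence loop. One caveat is documented and tested: when a large
fraction of the evaluated pairs carries true signal, the MA curve
absorbs part of it. The planted-effect recovery utility
(`planted_effect_estimates()`) therefore skips normalization by default —
there is no technical bias to remove in the generator — while the main
pipeline keeps it, since its evaluation sets are dominated by null pairs.

Two post-union filters mirror the comparative design: contacts
independently discovered in fewer than 4 of the 8 individuals are
removed (their across-individual frequency variance is systematically
higher, which `variance_by_discovery()` quantifies), and contacts whose
anchor-to-anchor distance differs by strictly more than 20 kb between
assemblies are removed, because read support falls with distance and a
distance mismatch masquerades as a species effect. Equality at 20 kb is
retained — the filter is a strict inequality.

# TAD and boundary conservation

Boundaries are domain edges extended 7.5 kb each way (15 kb elements,
clamped at chromosome ends). Domain conservation is assessed under two
criteria: 90% reciprocal overlap (symmetric), and an endpoint rule —
Euclidean distance between (start, end) pairs below
$\min(50\,\mathrm{kb},\ \mathrm{len}/2)$ — which is *not* symmetric when
lengths differ; the summary evaluates it from each species' side with
each domain's own size. The conserved count is the larger of the two
directional estimates (a domain with several partners counts once), and
the proportion divides by conserved plus species-specific domains from
both sets. Intervals are half-open: "any overlap" means at least one
shared base, and touching elements do not overlap. Boundary elements
from all individuals are merged by interval union before scoring, and an
element is conserved when contributors include both species. Nested
domains are kept as-is.

# Expression, linking, enrichment, mediation

Expression is reduced to $\log_2(\mathrm{RPKM} + 0.5)$; genes need
$\log_2 \mathrm{RPKM} \ge 0.4$ in at least two individuals of *each*
species. Differential expression uses the same OLS machinery with
species and sex. Each gene is represented by a single base pair at its
first-exon start, hence exactly one bin; among union contacts anchored
there the smallest species-term FDR represents the gene (ties: larger
absolute species effect, then smaller genomic distance — both
tie-breaks are package choices). The alternative combiner across all of
a bin's contacts is weighted Stouffer,
$Z = \sum w_i \Phi^{-1}(1 - p_i) / \sqrt{\sum w_i^2}$, equal weights by
default and configurable, since the exact published combination method
is not specified by a formula anywhere we could anchor to.

The DC×DE enrichment sweep cross-tabulates linked genes at every
combination of a DC FDR cutoff (by default the observed q-values in
[0.01, 0.25]) and DE FDR cutoffs {1, 2.5, 5, 7.5, 10}%, computing
Pearson's chi-squared (1 df, no continuity correction) plus the
proportion DE among DC and the all-genes baseline; cells with an empty
margin are `NA`.

Mediation treats species $X$, contact frequency $M$, expression $Y$:
$\alpha$ from $M \sim X$, $(\beta, \mathrm{direct})$ from
$Y \sim X + M$, indirect $= \alpha\beta$, and — exactly, for OLS on the
same sample — direct + indirect = the total effect from $Y \sim X$.
Significance comes from a Monte Carlo interval: 20,000 draws of
$\alpha^*\beta^*$ with the 2.5th/97.5th percentiles. The draws are
scaled-$t$ with each regression's residual df rather than plain normal:
with four individuals per species the SEs are themselves noisy, and
normal draws give the 95% interval a measured false-positive rate near
10–12% where $t$ draws restore it to nominal; with df $= \infty$ the
draws are normal, recovering the textbook form. The screen defaults to
the differentially expressed gene set; a full-set run is a caller
choice.

# Chromatin states

Per-state weights are reciprocals of each state's mean base-pair overlap
across all loci; the mean is taken over loci where the state overlaps at
all (a mean over the positive part of the distribution — including
zeros would conflate a state's segment length with its genome share).
Weights are computed on the full locus set before any subsetting, and
deduplication of loci happens before assignment; assignments are
invariant to locus order but not to the locus set, a coupling the tests
assert explicitly. Argmax ties break by larger raw overlap, then state
name. Cumulative proportion curves start at the 10 lowest-FDR loci and
add 2 at a time, within caller-supplied strata (promoter classes).
Between-class overlap comparisons use Welch's $t$-test with no
correction across class pairs, matching how such panels are usually
presented.

# The synthetic-data generator

The generator emulates the study *design*, not the data-generating
process of any real nucleus (which the source study, being
observational, never specifies). Defaults: 4 individuals per species,
sex alternating and two batches per species; 10 kb bins; intrachromosomal
pairs to 2 Mb; counts multinomial over pairs with weights
$d^{-\gamma}$ ($\gamma = 1$), so each library total equals the
configured depth exactly and marginal counts are binomial — precisely
the caller's null. (A Poisson mode exists; multinomial was chosen over
it for the exact-depth and exact-null properties.) On top of decay:

- a **loop layer** (5% of orthologous pairs, 4× enriched in both
  species). Planted differential contacts are drawn *from the loops*
  and multiplied by $2^{\pm\mathrm{effect}}$ in species B. Planting on
  arbitrary pairs would make negative effects undiscoverable (an
  average-strength pair weakened in one species is significant nowhere)
  and sever the causal chain end-to-end tests rely on; differential
  contacts in real data are, by construction, contacts.
- **TAD blocks** (2× within-domain enrichment), laid sequentially with a
  configured fraction shared between species and the rest present in
  exactly one — which makes the configured fraction the estimand of the
  conservation formula. Per-individual calls miss domains with
  probability 0.1 and jitter edges by one bin.
- **rearrangements**: inversions (minus-strand blocks) and deletions
  (unmapped in B, downstream coordinates shifted), grid-aligned and
  non-overlapping.
- **sex/batch nuisance**: per-contact $N(0, 0.1)$ log2 effects applied
  to the individuals carrying the label, so the model's covariates are
  non-degenerate without a global (and multinomially unidentifiable)
  shift.
- **expression**: baseline $\log_2$ RPKM $\sim N(3, 1)$, planted direct
  species effects on a fraction of genes, and mediation genes whose
  expression adds $\beta \times$ (their planted contact's realized
  per-individual frequency), composing the indirect effect
  $\alpha\beta$; noise SD 0.3 log2 units.
- **annotations**: exponential segment lengths (mean 5 kb) with states
  drawn at configured frequencies.

Not emulated: raw reads, restriction fragments, ligation artifacts,
trans contacts, fine breakpoint biology, GC/mappability bias. Passing
tests therefore demonstrate the *inferential machinery* — calibration,
recovery of planted effects, discrimination of causal from independent
couplings — not robustness to the technical artifacts of real libraries.

# Problem sizes and numerical choices

Validation experiments pick sizes where the estimand is measurable:
effect recovery uses a dense 2 Mb genome at depth $10^6$ (about 60 reads
per pair) because pseudocount shrinkage dominates log-ratios at O(1)
expected counts; discrimination runs use a 10 Mb genome with a 3% loop
layer so gene-level DC status does not saturate under min-FDR linking;
TAD-sharing recovery uses ten 10 Mb chromosomes (a few hundred domains)
so the planted fraction is estimable to a few percent. Degenerate inputs
are defined throughout: empty matrices error, zero-variance contacts get
$p = 1$, empty domain sets give `NA` proportions, chromosomes without
differential contacts report `NA` asymmetry, and a p-value of zero is
clipped to the machine minimum with a warning before the normal-quantile
transform.

# Known limitations

Plain OLS in place of moderated variance estimation; a distance-only
contact expectation; identity-scale block maps rather than real chain
alignments; single-mediator mediation without confounding sensitivity;
and no trans-chromosomal analysis. Each is a deliberate scope decision
aligned with the package's role: a tested, desk-scale reimplementation
of the comparative workflow.
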