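---
title: "Methods: tumor-organoid concordance and clonal dynamics with concord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-organoid concordance and clonal dynamics with concord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concord)
library(dplyr)
```

# The problem

Patient-derived organoids are only useful as cancer models to the extent
that they preserve the genome, the clonal composition, the expression
program and the drug sensitivities of the tumor they were derived from.
Testing this requires a connected chain of analyses: somatic-variant
concordance between tumor and culture, mutational-signature exposures and
subtypes, ploidy-relative copy-number and structural-variant status,
subclonal reconstruction from cancer cell fractions (CCFs) across serial
passages, patient-specific expression signatures, and dose-response
profiling. `concord` implements that chain as composable, tibble-first
functions, together with a seeded synthetic cohort generator so that every
stage can be exercised and validated against a known ground truth without
access to controlled patient sequencing data.

# The synthetic cohort and what it does (and does not) emulate

`simulate_clone_tree()` draws a rooted clone tree with one CCF per clone
per sample. The trunk is fully clonal everywhere. Children occupy random
fractions of their parent's CCF (gamma-weighted stick-breaking with a
Beta(5, 2) occupancy, so children usually occupy most but not all of the
parent), and those fractions drift between consecutive samples. The drift
magnitude is `selection_shift` at the tumor-to-first-passage transition —
the derivation bottleneck, where the strongest clonal selection acts —
and decays geometrically (factor 0.3) at later transitions, so late
passages are comparatively static.

`simulate_mutations()` assigns mutations to clones and draws each
mutation's trinucleotide channel from the exposure-weighted mixture of
catalog signatures; positions are unique over a toy genome of 22
chromosomes of 10 Mb, which keeps the chromosome-concentration QC filter
testable. `simulate_read_counts()` emulates caller-tabulated allele
counts: for purity $\rho$, locus total copy number $c$, multiplicity $m$
and clone CCF $\phi$, the expected VAF is

$$\mathrm{E}[\mathrm{VAF}] \;=\; \frac{\rho\, m\, \phi}{\rho c + 2(1-\rho)},$$

depth is Poisson around the sample mean, the alternate count is binomial,
and zero-alternate sites are emitted rather than dropped (caller-missed
sites are exactly what the pooled rescue is about). A variant counts as
*called* when it has at least 3 alternate reads at a VAF of at least 0.05;
this detection rule stands in for the caller-plus-filter stack, whose
per-call numeric behavior upstream tools do not expose.

Study conditions baked into the defaults: tumor purity defaults to 0.55
(primary resection tumors typically fall between roughly 0.3 and 0.8),
organoid passages are pure ($\rho = 1$; organoid purity estimates in
paired designs are essentially 100%), tumors are sequenced deeper than
organoids in the motivating design (50x vs 30x; the clustering benchmark
uses a uniform 100x).

The expression generator plants three programs on a lognormal baseline:
a tumor program (up in tumors and organoids versus normal squamous
tissue), a culture program (shifted in all organoids — the in vitro
environment effect the selection procedure must discard), and a patient
program per patient. Patient programs are layered **on top of** the tumor
program: a gene expressed differently in only one patient can never pass
a cohort-level normal-versus-tumor filter, so patient identity must live
in genes that are already tumor-associated, as it does in real cohorts.
Each patient contributes one tumor and three organoid passages, so the
one-versus-all organoid contrast has replication. Counts are negative
binomial with the standard mean-dependent dispersion trend
$\alpha(\mu) = 0.02 + 4/\mu$: weakly expressed genes are strongly
overdispersed while highly expressed genes approach the asymptotic
dispersion, the shape parametric fits recover from bulk RNA-seq. (A flat
dispersion of 0.1 would make the highly expressed signature genes
unrealistically noisy and starves the selection procedure of power.)

Features of real data the generator does **not** emulate: stromal and
immune contamination of the tumor expression profile beyond a purity
scalar, genomic waves / GC biases in coverage, mapping artifacts,
germline contamination, copy-number-driven expression dosage, and
subclonal copy number. Passing tests therefore demonstrate that the
implementations are correct under the stated generative model, not that
the pipeline is robust to every artifact of real sequencing.

# Variant concordance and the pooled rescue

Variants are classified per tumor-organoid pair as shared, tumor-only or
organoid-only over the union of present variants. The rescue rule
recovers variants called in only one sample when (i) the pooled call
succeeds and (ii) the variant allele is *represented* in the other
sample's alignment. Pooling is modeled at the allele-count level: the
detection rule applied to summed alternate counts and summed depths —
pooling reads raises exactly these counts, which is why subclonal
variants sitting below threshold in a low-purity tumor are recoverable.
"Represented" is read literally as at least one alternate read
(`min_rescue_alt = 1`, configurable). Enabling rescue can only move
variants into the shared class, never out of it (a tested monotonicity
invariant).

# Copy number, gene families, and structural variants

Segments are classified relative to the sample's average ploidy $p_s$:
deletion at copy number 0, amplification at $\ge 2 p_s$, gain strictly
above $1.25 p_s$, loss strictly below $0.75 p_s$, neutral otherwise. The
boundary semantics are transcribed literally (amplification inclusive,
gain/loss strict), and gain is bounded above by the amplification cutoff
so the five classes partition the copy-number axis. Gene families (e.g.
RAS summarizing HRAS, KRAS, NRAS) are classified on the arithmetic mean
of the member genes' total copy numbers. LOH requires a lost minor allele
with retained total copy — a homozygous deletion is not LOH. Genome
fractions amplified / deleted / under LOH are length-weighted over the
profiled segments. SV filtering removes calls with breakpoints in
blacklisted regions (gaps, satellites, long simple repeats, extreme-depth
regions — supplied as a file, since "extreme depth" has no portable
numeric definition), deletions under 1 kb without at least one supporting
read, and inversions under 10 kb; every call is returned with its fate
and reason.

# Signature exposures and subtype

The exposure fit models the 96-channel spectrum $c$ as a non-negative
mixture of catalog signatures $P$ (rows = signatures):

$$\hat e = \arg\min_{e \ge 0} \; \lVert P^{\top} e - c \rVert^2 ,$$

solved exactly by Lawson-Hanson active-set non-negative least squares —
the standard quadratic-programming form with non-negativity as the only
constraint. No sum-to-total equality constraint is imposed; proportions
are computed post hoc by normalization. The tests verify the solution
against two independent routes: a dense grid search over the probability
simplex (step 0.005, optimal scale per grid point in closed form) and an
off-the-shelf NNLS solver. Unweighted least squares on raw counts is
used; with 20,000-mutation genomes the multinomial noise is nearly
homoscedastic across the informative channels and recovery error is an
order of magnitude below the acceptance band, so Poisson weighting would
add machinery without measurable benefit.

Subtype assignment takes the most prevalent signature's mapped subtype,
except that the two S17-like signatures are summed and their joint
contribution counts toward the *mutagenic* subtype. Exact ties break by
catalog order with a warning. The published six-signature catalog lives
in its original supplement and is treated as an input file
(`read_signature_catalog()`); `random_signature_catalog()` provides
seeded sparse stand-ins for testing, which is also why the package's
tests are not tied to any particular catalog's numerical values.

# CCF estimation and subclone clustering

CCFs use the standard purity/copy-number estimator. With VAF $v$, purity
$\rho$, locus total copy number $c$: the read-weighted denominator is
$d = \rho c + 2(1 - \rho)$, the multiplicity is
$m = \mathrm{clamp}(\mathrm{round}(v d / \rho),\, 1,\, \max(c, 1))$, and
$\mathrm{CCF} = v d / (\rho m)$, clipped to $[0, 1.5]$ with clip events
recorded.

Clustering is a truncated stick-breaking Dirichlet-process binomial
mixture over the joint CCF space of all samples, Gibbs-sampled. Cluster
CCFs live on a discrete grid (step 0.01), so the binomial log-likelihood
of every mutation at every grid value is precomputed once per sample and
each sweep reduces to table lookups; chains are fast and bit-reproducible
under a seed. Choices that matter, each adopted after observing a
concrete failure mode of the plain sampler:

* **k-means warm start.** Random initializations routinely fail to split
  two clusters that start merged: an empty DP component must land on the
  right CCF *and* capture members within a single sweep, a vanishingly
  rare joint event. Seeded k-means on naive per-mutation CCF estimates
  starts the chain near a reasonable partition.
* **Truncation at 8 components, concentration $\alpha = 1$,** 2000
  sweeps with 500 burn-in.
* **Label handling.** Components are reordered by descending mean CCF at
  every recorded sweep; a mutation's posterior CCF per sample is the
  average over sweeps of its assigned component's CCF. The reported
  cluster CCF is the *median of its members' posterior CCFs*; `dp_ccf`
  is the component's own posterior mean, the quantity QC rule 2 compares
  against.
* **MAP refinement.** Sweep-wise relabeling can leave a shadow label
  between two real clusters; a few hard reassignment passes against the
  final centers dissolve it.
* **Post-hoc merge** of clusters whose centers sit within 0.1 of each
  other in every sample — twice the binomial standard error of a CCF
  near 0.5 at depth 100; components closer than that are not resolvable
  at realistic depths.

Cluster QC applies three filters, any of which rejects: fewer than 1% of
all clustered mutations; members' median CCF deviating from the DP CCF by
more than 0.2 in any sample; more than half the members on one
chromosome. The 1% denominator is the union of clustered mutations across
samples, and the DP reference CCF is the posterior mean (both points the
filter definitions leave open; both configurable).

**Benchmark identifiability.** The recovery benchmark (50 seeded runs,
2-4 planted clones, at least 150 mutations per clone, depth 100) plants
trees from `resolvable_clone_tree()`, which redraws until every clone
pair sits at least 3 joint per-mutation standard deviations apart *in
VAF space* given the study's purities. The purity scaling is the point:
a CCF difference of 0.17 visible only in a 0.55-purity tumor is a ~1-SD
difference per mutation — one statistical population to any CCF-based
method, so unconstrained trees make "correct cluster count" an
ill-posed target. The screen encodes the resolvability floor, not a
tuning of the method.

# Sum and crossing rules, and clone dynamics

Two clusters whose CCF ordering flips between samples (beyond a
tolerance $\tau = 0.05$, about twice the typical center standard error
at depth 100) must sit on disjoint branches (*crossing rule*). Every
other cluster starts under the trunk-most enclosing cluster; the *sum
rule* then repairs sibling sets — siblings whose CCFs sum above their
parent's in some sample cannot all be disjoint (pigeonhole), so the
smallest is re-nested under the largest sibling and flagged. Sibling
sets that violate the sum rule but cross are flagged unresolved rather
than forced. A clustering with no near-clonal cluster (CCF within 0.1 of
1 everywhere) is a structure error: every valid reconstruction needs a
trunk.

Clone dynamics over an ordered sample series classify as `stable` (no
clone moves by more than 0.1 across any transition), `rapid_then_static`
(at least 70% of the total absolute CCF change falls on the
tumor-to-first-passage transition), or `gradual` — thresholds
configurable. When passages are clustered separately, clusters are
matched across runs by member-set Jaccard at 0.5.

# Expression concordance

Counts are normalized by median-of-ratios size factors (geometric-mean
reference over genes expressed in every sample) and stabilized as
$\log_2(\mathrm{count}/s_j + 1)$ — an ordering-preserving,
variance-flattening stand-in for a model-based variance-stabilizing
transform. Expressed-variant classification requires RNA depth of at
least 4; any alternate read makes the site `alternative_expressed`,
otherwise `reference_expressed`.

The differential-expression engine is a Welch t-test on normalized
values with the log2 fold change as the difference in group means. The
three-step patient-specific selection is the scientific content, and the
engine behind it is pluggable; the Welch engine is deterministic, has
calibrated type-I error in the tests, and suffices for the planted
effect sizes. The steps: (1) keep genes differentially expressed between
normal and tumor and lower in normals ($p \le 0.01$, log2FC $\le -1$);
(2) discard genes generally different between tumors and organoids
($p \le 0.01$, $|$log2FC$| \ge 1$) — the culture effect; (3) keep genes
specific to this patient's organoids in a one-versus-all contrast
($p \le 0.05$, $|$log2FC$| \le 1$) that rank in the top 50 by base mean
among the step-1/2 survivors. The step-3 fold-change window is
implemented as quoted even though it reads oddly against "specifically
up- or downregulated" (a `strict_lfc` switch flips it to $\ge 1$); the
top-50 pool is the step-1/2 survivor set, since the procedure's scope
for "top 50" is ambiguous. One observed consequence of the modest step-3
thresholds: selected sets also pick up some *other* patients' program
genes (their modulation inflates the one-vs-all contrast occasionally);
this does not hurt pair matching because the correlation uses the union
of sets anyway, and the tests assert enrichment, not purity.

The tumor-by-organoid matrix holds Pearson correlations of normalized
values over the union of selected gene sets, with organoid passages
averaged into one profile per culture, complete-linkage/Euclidean
dendrograms on both axes, and a matched-pair flag per tumor (is the
best-correlated organoid the patient's own?).

# Drug response

Viability is the well signal over the median negative-control signal
(values above 1 retained). Curves are two-parameter logistics with
asymptotes fixed at 1 and 0 on $x = \log_{10}$ concentration — the
identifiable choice for 7-point designs — fitted by deterministic
Levenberg-Marquardt least squares initialized from the dose nearest
half-maximal viability. IC50 is $10^{x_0}$, censored at the range edge
when the midpoint falls outside the tested 1000-fold half-log ladder;
degenerate flat curves take their AUC from the trapezoid of the raw
points and censor toward whichever edge the response favors. AUC is the
mean fitted viability over the tested doses, so $1-\mathrm{AUC} \in
[0,1]$ is the sensitivity score; the Z-factor is
$1 - 3(\sigma_{+} + \sigma_{-}) / |\mu_{+} - \mu_{-}|$; replicate
concordance is Spearman over shared (organoid, compound) pairs with
censored IC50s ranked at the edge. The anchored-combination layout holds
cisplatin at 4 uM and 5-fluorouracil at 10 uM while titrating epirubicin
from 10 uM down the 7-point half-log ladder.

# Numerical choices and degenerate inputs

* Classed input errors (`concord_input_error`) for contract violations;
  structure errors for impossible tree reconstructions; undefined
  quantities (VAF at zero depth, proportions of an empty spectrum,
  Z-factor at equal control means) return `NA` or raise classed
  conditions rather than silently producing numbers.
* Strict-inequality rule boundaries carry a `1e-9` floating-point guard
  where equality is meaningful (QC rule 2 at exactly 0.2).
* All stochastic entry points run under `withr::with_seed`, so the
  caller's RNG state is never disturbed and identical seeds give
  identical output to the bit.
* Problem sizes used by the test suite and acceptance script — 50
  clustering runs of 400-800 mutations at depth 100, 100 signature
  mixtures of 20,000 mutations, a 6-patient expression cohort of 2,000
  genes, 30-pair replicate screens — are the smallest at which the
  benchmarks' statistical statements are stable, which is the package's
  own choice of desk-scale study conditions.

# Known limitations

* Subclonal copy number, mutation multiplicity beyond a supplied
  per-locus value, and whole-genome duplication are not modeled; the CCF
  estimator rounds multiplicity from the data, which is fragile exactly
  where real pipelines also struggle (high, odd copy numbers at low
  purity).
* The clustering resolves clones down to roughly the read-noise floor
  and no further; clones closer than that merge by design.
* The Welch engine is underpowered relative to count-model tests at very
  small replicate numbers; it is a pluggable default, not a claim about
  the best test.
* Dynamics classification uses fixed thresholds on aggregate CCF change;
  it is descriptive, not a model comparison.

# A worked end-to-end run

```{r end-to-end, eval = FALSE}
library(concord)
library(dplyr)

# one patient: tumor + 3 passages, known 3-clone tree
truth <- simulate_ground_truth(n_clones = 3, n_samples = 4,
                               selection_shift = 0.5, tumor_purity = 0.55,
                               mean_depth = 80, seed = 11)
sim <- simulate_patient(truth = truth, n_mutations = 900, seed = 11)

# concordance between the tumor and the first passage
trios <- build_trios(filter(sim$observations, sample == "tumor"),
                     filter(sim$observations, sample == "P1"))
summarize_concordance(trios)

# signature exposures of the tumor spectrum
fit <- fit_exposures(mutation_spectrum(sim$mutations), sim$catalog)
assign_subtype(fit, sim$catalog)

# subclones and the clone tree across all four samples
cl <- cluster_ccf(sim$observations, seed = 11)
qc <- qc_clusters(cl)
tree <- build_tree(cl)
autoplot(track_dynamics(cl, sample_order = c("tumor", "P1", "P2", "P3")))
```
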