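---
title: "Models and methods behind cladecons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cladecons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Some genomic elements are under strong purifying selection in a single
clade — birds are the motivating example — while being absent from, or
fast-evolving in, every outgroup. Such clade-specific highly conserved
elements (the avian ones are called ASHCEs) are overwhelmingly
non-coding and are candidate *cis*-regulatory drivers of clade-specific
traits. `cladecons` implements the full inference stack for finding,
classifying, annotating and dating them, together with forward
simulators that generate every required input with known ground truth,
so that each stage can be validated end to end without any external
data.

# The neutral model

All likelihoods rest on a time-reversible nucleotide substitution model
(JC69, HKY85 or GTR) with rate matrix $Q$ normalised so that
$-\sum_i \pi_i q_{ii} = 1$; branch lengths are therefore expected
substitutions per site. The neutral ("nonconserved") model is fitted by
maximum likelihood from putatively neutral columns — in practice
fourfold-degenerate third codon positions, which the caller supplies
(`fourfold_degenerate_columns()` extracts them from annotated coding
alignments). Equilibrium frequencies are estimated empirically from the
supplied columns, as is conventional for this kind of fit;
exchangeabilities and all branch lengths are then optimised jointly by
bounded quasi-Newton iteration on log-transformed parameters from two
deterministic starts. HKY85 is the default family: it captures the
transition/transversion bias that dominates vertebrate substitution
patterns with a single parameter, while GTR remains available when full
generality is wanted. Branch lengths below $10^{-8}$ are reported as 0.

Column likelihoods use Felsenstein pruning, implemented in C++ over
site patterns with per-node rescaling, so alignments of $10^6$ columns
are handled without underflow. Gaps and `N` are treated as missing data
and marginalised — standard phylogenetic practice. Under a reversible
model only the sum of the two root-adjacent branch lengths is
identifiable; tests compare those branches through their sum.

# Conserved-element calling

A two-state phylogenetic hidden Markov model scans the alignment. The
conserved state emits columns under the neutral tree with every branch
multiplied by a scale $\rho \in (0, 1]$; the nonconserved state uses the
unscaled tree. Transition probabilities $\mu$ (conserved →
nonconserved) and $\nu$ (nonconserved → conserved) imply a stationary
conserved coverage $\nu/(\mu+\nu)$ and an expected element length
$1/\mu$.

Tuning defaults are $1/\mu = 45$ columns and 5% stationary coverage,
both configurable: published conservation scans tune these to each
dataset and report no universal values, so the package exposes them
rather than hard-coding guesses. $\rho$ can be fixed or estimated by EM
(`estimate_rho()`): Baum–Welch updates for the transitions and a
golden-section maximisation of the expected complete-data log-likelihood
over $\rho$, with a guard that accepts a $\rho$ update only if the
observed-data log-likelihood does not decrease; the trace is therefore
monotone. On data without a conserved fraction the EM legitimately
drifts to a boundary (conserved occupancy below 1%, or
$\rho \to 1$) and the result carries a flag.

Elements are maximal runs of the Viterbi conserved state (a
posterior-threshold mode is available behind a flag), mapped to
reference coordinates. Columns not aligned to the reference cannot sit
inside an element and split runs, because elements are intervals on the
reference genome. Runs shorter than 20 bp are discarded — short
candidates are unreliable, and downstream analyses use the ≥ 20 bp set.
Each element carries a log-odds score, the summed per-column
log-likelihood ratio of the two states, held in nats internally and
written to BED score columns as $10 \log_{10}$ odds rounded to integer.

An important design point: element calling runs on the **ingroup
alignment and ingroup subtree only**. A conserved-state model that
scaled outgroup branches too would penalise exactly the Type II
elements the analysis is looking for (conserved in the clade, divergent
outside). Outgroups enter only at classification.

# Clade-specific classification

Each called element is tested against an outgroup scheme: an ingroup
clade plus an ordered list of outgroup sets (the default mirrors nested
outgroup sampling — nearest relative; close relatives; all outgroups).

* **Type I**: no outgroup species reaches the presence threshold
  (default 10% resolved characters per species across the element) in
  the union of all sets — the element has effectively no outgroup
  orthologue. The all-sets reading was chosen over any-set because a
  sequence visible in any outgroup is evidence of an orthologue.
* **Type II**: the element is present in at least one set and the
  outgroup-acceleration test is significant at $q < 0.01$ in **all**
  sets, with the Benjamini–Hochberg FDR computed within each set across
  elements.
* Everything else is non-specific. Elements shorter than 20 bp are
  never labelled clade-specific.

The acceleration test is a likelihood-ratio test on the fixed neutral
tree: $H_0$ fits one scale on all branches, $H_1$ fits separate scales
$\lambda_\text{in}$ (ingroup crown plus stem — conservation on the stem
is part of the clade signal) and $\lambda_\text{out}$ (the rest). The
one-sided p-value is $0.5\,P(\chi^2_1 > \Lambda)$ when
$\hat\lambda_\text{out} > \hat\lambda_\text{in}$ and 1 otherwise,
the usual one-sided treatment of a boundary-free scale contrast.
Elements shorter than 5 columns are flagged untestable and excluded
from the FDR.

# Genomic context

Annotation classes follow the five-way priority *coding > 5′/3′ 10 kb >
intronic > intergenic*, with the flanking windows anchored at the
translation start/stop, strand-aware. "Coding" means CDS overlap; UTR
exons inside the transcript span fall to the intronic class. Gene
association is nearest-gene within 10 kb of the transcript span
(transcription-anchored — deliberately a different anchor than the
class windows, matching how each is used), with deterministic
tie-breaks (distance, then gene id). Ranked gene lists take each gene's
best element log-odds score. The SNP-density contrast treats every base
as a Bernoulli trial and compares inside/outside densities with a
Pearson $\chi^2$ on the 2×2 table; the Yates correction is applied
automatically when an expected cell drops below 5 (at genome scale it
never does).

# Enrichment statistics

`permute_interval_overlap()` is a workspace-aware permutation test:
every query segment is re-placed uniformly at random within the
workspace (length preserved, segments never span workspace gaps,
mutual overlaps allowed), and the nucleotide overlap with an annotation
is recomputed; 100{,}000 simulations is the conventional production
setting, scaled down in examples. Empirical p-values use the add-one
rule $(1 + \#\{\text{sim} \ge \text{obs}\})/(n+1)$ and are never zero;
both enrichment and depletion p-values and the fold over expectation
are reported.

Categorical enrichment of gene lists against term maps uses per-term
2×2 $\chi^2$ tests with BH FDR. Stage over-representation uses
Fisher's exact test. Expression stage-specificity uses
$\tau = \sum_i (1 - x_i/\max_i x_i)/(N-1)$, with stage-specific calls
at $\tau \ge 0.8$ by default (the threshold is not canonical; it is
exposed and documented). The cross-species candidate filter keeps genes
with a strictly $>5$-fold change in the focal species (as a flagged
DEG) in at least one late-vs-phylotypic contrast whose ortholog changes
strictly $<2$-fold in the paired contrast of the comparison species;
genes without orthologs are excluded and listed separately. Boundary
values (exactly 5-fold, exactly 2-fold) are excluded by the strict
inequalities.

# Conservation-onset dating

For an element conserved in the clade, the time $T$ (Myr) at which
conservation began on the stem branch is modelled with a
piecewise-constant clock: neutral rate $r$ before $T$, conserved rate
$\rho r$ after, giving the expected element-specific stem length

$$E[b](T) = r\,(t_0 - T) + \rho\, r\,(T - t_1),$$

where $t_0$ and $t_1$ are the stem's endpoint ages. The estimator (i)
refits every branch length from the element alignment on the fixed
topology, (ii) takes $r$ from the genome-wide neutral stem length over
the stem duration, (iii) estimates $\rho$ as the ratio of element to
neutral total crown length — separate from $T$, which keeps the
inversion closed-form, (iv) inverts the display above for $T$, clamping
into $[t_1, t_0]$ with a flag, and (v) obtains a standard error by a
column bootstrap (default 200 replicates; clamped replicates are
included and their fraction reported as a quality metric). Clamping
rather than failing was chosen because sampling noise routinely pushes
short elements past the attainable range, and the clamped fraction
makes that visible.

Two outgroups at minimum (three in the shipped fixtures) are needed in
practice: with a single outgroup the stem abuts the root, where a
reversible model cannot apportion length between the root's two
children, and the stem length becomes unidentifiable.

# The simulators, and what they do not emulate

All generators are pure functions of their parameters and a seed; the
pipeline derives per-stage substreams from one global seed (order:
alignment, elements, snps, intervals, expression, onset, hmm,
enrichment), so adding a stage does not perturb the others.

`simulate_alignment()` evolves i.i.d. columns along the tree;
`plant_elements()` rewrites chosen intervals under scaled branches
(whole-row gapping of outgroups for Type I — the simplest reading of
"no outgroup sequence aligned"); `simulate_stem_onset()` realises the
piecewise clock; `simulate_snps()`, `simulate_intervals()`,
`simulate_expression()` and `simulate_cross_species_fc()` produce the
remaining inputs with recorded truth.

The simulators deliberately omit indels (other than planted whole-row
gaps), context-dependent substitution, rate variation across sites,
alignment error and assembly artefacts. Passing tests therefore
demonstrate the correctness and calibration of the inference machinery
under its own model assumptions — not robustness to the full
messiness of real whole-genome alignments.

# Problem sizes and numerical choices

The shipped experiments run at desk scale, chosen so the full suite
completes comfortably on one CPU: a 200 kb demonstration genome with 11
species and 30 planted elements; 1{,}000 null and 200 accelerated
elements for LRT calibration and power; 100 onset replicates of 300
columns with 40 bootstrap resamples inside the recovery experiment
(the function default stays at 200); 30–50 k columns for EM recovery
of $\rho$. Optimisation tolerances: convergence at a relative
log-likelihood change around $10^{-7}$; branch-length box
$[10^{-9}, 10^2]$ on the log scale; scale box $[10^{-4}, 10^3]$ for
the LRT. Ties in gene association and ranking break
deterministically (distance, then lexicographic id), so all outputs
are bit-reproducible under a fixed seed.

# Known limitations

* No rate heterogeneity across sites (no Gamma mixture) and no
  amino-acid models; topology is always fixed, never searched.
* The EM for $\rho$ estimates a single genome-wide conserved scale, not
  the per-element scales a full conservation-model fit would produce.
* The onset model allows exactly one rate change on the stem; multiple
  episodes or relaxed clocks are out of scope.
* GFF3 handling keeps one transcript per gene (longest CDS); isoform
  structure is ignored.
* The Type I / Type II decision consumes the alignment as given:
  alignability is equated with orthologue presence, as in the source
  analyses.
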