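---
title: "Inferring differential signaling-circuit activity from expression data"
author: "sigCircuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring differential signaling-circuit activity from expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigCircuits)
```

## The problem

A signaling pathway carries a stimulus from membrane receptors through
chains of activating and inhibiting proteins to effector molecules that
trigger cell responses. Differential-expression lists say which genes
changed, but not whether any *route through the pathway* gained or lost
the ability to transmit its signal: many individual gene changes cancel
out topologically, and a single deactivated protein in a serial stretch
can silence a whole response. sigCircuits addresses this by converting
expression into probabilities of protein presence and propagating them
through the pathway topology, so that the unit of inference becomes the
**stimulus–response circuit**: the set of all simple directed paths from
one receptor to one effector.

## The model

### Pathway graphs

Pathways are read from KGML documents into signed directed graphs.
Gene-type entries become nodes of interchangeable proteins (`any_of`),
group entries become protein complexes (`complex`), and relations become
edges with sign $+1$ (activation, expression, indirect effect,
phosphorylation, binding/association) or $-1$ (inhibition, repression,
dephosphorylation, dissociation). A relation carrying several subtypes is
inhibitory if any subtype is; unknown subtypes default to activation with
a warning — the model only distinguishes the two signs, and the positive
default is the conservative binarization. Compound-mediated relations are
contracted into direct protein–protein edges (sign = product of the two
hops) because the model carries no compound abundances; links to other
pathways (`map` entries) are dropped since cross-pathway signal is out of
the per-pathway model.

Receptors and effectors are not annotated in KGML, so they are identified
topologically: receptors have in-degree 0 and out-degree $\ge 1$,
effectors the reverse. This is a design decision, not pathway curation;
`identifyEndpoints()` accepts curated endpoint lists that override the
degree rule, which is also the escape hatch for graphs that are one big
cycle (those have no degree-0 node and raise a diagnostic error).
Cycles elsewhere are harmless: circuits are built from *simple* paths, so
no node is traversed twice.

### From expression to presence probabilities

Expression values are treated as proxies of protein presence. For each
probe, a two-component normal mixture is fitted on a log2-scale
**reference compendium** (hundreds of arrays spanning diverse
conditions); the component with the larger mean is "present". A probe's
activation probability in a study sample is the posterior probability of
the present component given its value:
$$
p(\text{present} \mid x) =
\frac{w_P\,\phi(x;\mu_P,\sigma_P)}
     {w_A\,\phi(x;\mu_A,\sigma_A) + w_P\,\phi(x;\mu_P,\sigma_P)}.
$$

The EM fit is deterministic: a start from the 25th/75th percentiles plus
a midpoint-threshold start, run to a $10^{-8}$ log-likelihood tolerance
(at most 500 iterations), best final likelihood wins. The second start
matters for probes whose gene is present in nearly all reference arrays:
with, say, a 95% presence rate both quartiles sit inside the present
mode, and a single quartile start can converge to a local optimum that
splits the majority mode instead of isolating the small absent one. A
fit is only accepted as a presence/absence model when it is actually
bimodal — component separation (Ashman's
$D = |\mu_P - \mu_A| / \sqrt{(\sigma_A^2 + \sigma_P^2)/2}$) of at least
2 — and non-degenerate (weights $\ge 0.01$, sds $\ge 10^{-3}$,
converged). Anything else falls back to the probe's empirical reference
distribution, used through a mid-rank ECDF
($(\#\{r < x\} + 0.5\,\#\{r = x\})/n$), which keeps every probe usable
at the cost of a rank-based rather than model-based probability.

Probes are summarized to genes with the **90th percentile** of their
probe probabilities by default (linear interpolation between order
statistics, $h = 0.9\,(n-1)$): robust to a single aberrant probe while
staying close to the strongest evidence of activity. `mean`, `median`
and `max` are available. Genes are summarized to nodes by the node
semantics: interchangeable proteins take the **highest** member
probability (they are redundant), complexes take the **lowest** (every
subunit must be present). When a platform does not cover every member
gene, a complex is summarized over its observed members with a warning
rather than forced to probability 0; a node with no observed member is
an error.

### Transmission probability of a circuit

Within a path, a node whose outgoing edge is an inhibition is
**inhibitor-role**: it lets the signal pass when the protein is absent
and contributes $1 - p_v$; all other nodes (including the effector,
which must be present to execute the response) contribute $p_v$. A
single path therefore transmits with probability
$\prod_{v \in \text{act}} p_v \prod_{v \in \text{inh}} (1 - p_v)$ —
for a linear cascade, a simple product of probabilities.

A circuit transmits when at least one of its paths does. Assuming node
states independent within a sample (implied by the product form), that
union probability is computed **exactly** by inclusion/exclusion over
path events: the joint probability of a set of paths is the product over
nodes required present times the product over nodes required absent, and
zero when some node is required both (a node may legitimately be
activator-role on one path and inhibitor-role on another; such
intersection terms simply vanish). The recursion
$P(E_1 \cup R) = P(E_1) + P(R) - P(\{E_1 \cap E_i\})$ prunes
contradictory and duplicate terms, and is exact for up to 20 paths per
circuit (the worst case is $O(2^k)$); circuits beyond the cap fall back
to seeded Monte-Carlo over node states ($10^5$ draws by default) and are
flagged as stochastic in the output. An independent brute-force oracle
(`bruteForceTransmission()`, exhaustive enumeration of all $2^n$ node
states, $n \le 20$) exists purely to validate the inclusion/exclusion
path and is used throughout the test suite.

The receptor's own probability is included in the product — a receptor
must be present to sense the stimulus. This is a modeling choice (the
alternative conditions on the stimulus being received) and changing it
rescales every sample of a circuit by the same monotone factor, so
rank-based downstream testing is largely insensitive to it.

### Differential testing

Per circuit, per-sample transmission probabilities are compared between
cases and controls with a two-sided Wilcoxon rank-sum test: the values
are bounded in $[0,1]$ and typically far from normal, so a rank test is
the defensible conventional choice (the test sits behind one function,
`circuitTest()`, and is pluggable). The exact null distribution is used
when the smaller class has at most 8 samples and there are no ties;
otherwise the normal approximation with tie and continuity correction.
Circuits constant across both classes report $p = 1$ with a degenerate
flag rather than being dropped, keeping output row-complete per pathway.
P-values are adjusted with Benjamini–Hochberg across **all circuits of
the run** (all pathways jointly — one experiment, one multiplicity
universe), and a pathway is summarized by its significant counts and a
global activity score, the signed fraction
$(n_{\text{up}} - n_{\text{down}})/n_{\text{circuits}} \in [-1, 1]$.

## The synthetic-data generator

`simulateStudy()` stands in for both the curated pathway collection and
a large reference compendium. Per sample, each gene's product is present
or absent (a Bernoulli draw at that gene's class-specific presence
probability), and each of its probes draws a log2 intensity from the
matching mixture component. This generative coupling makes the
activation module's posterior the Bayes-correct presence estimator, so
calibration is a well-posed target: the mean posterior per probe must
approach the generating presence rate.

Defaults describe a small but realistic microarray-style study: 15 cases
vs 15 controls, 3 probes per gene, a 500-array reference, mixture
components at log2 intensities 6 (absent) and 10 (present) with unit
sds — a 4-sd separation typical of the expressed-vs-background modes of
Affymetrix probe intensities — and baseline presence probabilities drawn
uniformly from $[0.6, 0.95]$, i.e. pathway genes that are usually but
not always expressed. Planted effects shift the presence log-odds of
every gene on one circuit in the case class; $-3$ log-odds turns a
$\sim 0.9$ presence into $\sim 0.25$, which collapses the circuit's
transmission. The ground-truth table evaluates each circuit's true
per-class transmission with the brute-force oracle on the generating
node probabilities.

What the generator does **not** emulate: probe-level artifacts (mismatch
probes, spatial effects), correlated expression between neighboring
genes, batch structure, and mixtures that vary per probe. Tests passing
on this generator therefore validate the probabilistic machinery and the
statistical calibration of the method, not its robustness to real
microarray pathologies — for real data the reference compendium and
platform annotation do that heavy lifting and must be supplied by the
user.

## Validation experiments and problem sizes

Two packaged experiments replicate the method's statistical behavior and
are recomputed by `scripts/acceptance.R`:

- `nullCalibrationExperiment()`: 1000 replicate null studies (10 vs 10
  samples, 8 gene-disjoint diamond circuits); the fraction of raw
  $p \le 0.05$ should sit at (slightly below, given rank-test
  discreteness) the nominal level.
- `plantedRecoveryExperiment()`: 200 replicates of a $-3$ log-odds
  planted loss on one of 4 gene-disjoint circuits (15 vs 15); reports
  the planted circuit's recovery rate at FDR $\le 0.05$ and the flag
  rate of untouched circuits.

In both, the per-probe reference model is fitted once per experiment and
reused across replicates — the reference distribution is identical across
replicates, and this mirrors the precomputed-distributions design where
reference fitting is a separate, slower step (`fit-reference` in the
CLI). Oracle-equivalence checks run 50+ fixture circuits (chains,
diamonds, inhibitor variants, random DAGs of up to 12 nodes) against 200
random probability vectors each; 12 nodes keeps the $2^n$ enumeration
instant while covering multi-branch interleavings far richer than the
closed-form cases.

## Numerical choices and degenerate inputs

- Percentile convention: linear interpolation between closest order
  statistics ($h = q(n-1)$, zero-based), fixed for bit-reproducibility.
- Posterior computed on the log scale; probabilities clamped against
  sub-$10^{-12}$ floating-point excursions outside $[0,1]$.
- Path enumeration is deterministic: lexicographic by node-id sequence;
  truncation at `maxPaths` keeps the lexicographically first paths and
  flags the circuit.
- Self-loops are dropped at parse (a self-edge has no serial
  interpretation in the transmission product); duplicate relations
  collapse to one edge.
- All randomness (Monte-Carlo fallback, generators) flows through
  explicit seeds with the caller's RNG state restored afterwards.

## Known limitations

- Node-state independence is assumed within a sample; co-regulated genes
  violate it and the transmission probability is then exact only under
  the model, not in nature.
- The degree rule for receptors/effectors mistakes any upstream-truncated
  node for a receptor; curated endpoint lists are the remedy.
- A pathway node none of whose member genes are measured stops the
  analysis rather than being imputed.
- Two classes only, no pairing or covariates; gene-level differential
  expression is deliberately out of scope.
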