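---
title: "A partitioned branch-site random-effects codon model for endogenous viral elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A partitioned branch-site random-effects codon model for endogenous viral elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the model answers

Endogenous viral elements (EVEs) are virus-derived sequences integrated in
a host nuclear genome. When a geminivirus-derived element such as an
endogenous geminiviral element (EGV) retains an intact *rep* open reading
frame long after integration, the natural question is whether the protein
was ever (or is still) under selection to remain functional. Purifying
selection leaves a signature: fewer nonsynonymous substitutions than the
synonymous background predicts, i.e. dN/dS (denoted $\omega$) below 1 on
the branches that post-date the event of interest.

`egvselect` implements this test for the typical two-element design: two
clades of homologous integrated copies (here labelled EGV1 and EGV2) plus
the single branch connecting them, which stands in for the free-living
ancestral lineage. The package also implements the upstream screening steps
that define the analysis set: detection of the replication-origin
nonanucleotide (TAATATTAC) and its GC-rich stem-loop, ORF intactness
(premature stops and frameshifts), rolling-circle-replication (RCR) motif
scans on Rep proteins, and a conservative count of genetically distinct
repeat copies.

## The model

### Codon substitution process

The instantaneous rate from sense codon $i$ to $j$ is MG94-style crossed
with a general time-reversible nucleotide model:

$$
q_{ij} = \begin{cases}
r_{ab}\, f_{p}(b)\, \omega & i \to j \text{ is a one-nucleotide nonsynonymous change } a \to b \text{ at position } p\\
r_{ab}\, f_{p}(b) & \text{same, synonymous}\\
0 & i,j \text{ differ at more than one position,}
\end{cases}
$$

with five free symmetric exchangeabilities $r_{ab}$ (GT $\equiv$ 1) and a
$3 \times 4$ positional nucleotide frequency matrix $f$. Equilibrium codon
frequencies are the CF3x4 form: positional products over the 61 sense
codons, renormalised after excluding the three stops. The product form
makes the chain exactly reversible with respect to these frequencies,
which the implementation exploits (a symmetric similarity transform turns
every matrix exponential into one symmetric eigendecomposition).

Two frequency modes are provided. The default plugs in the observed
positional proportions (fast, nearly identical in practice); the
`freqs = "mle"` mode treats the nine positional parameters as free and
maximises them jointly with everything else, which is the corrected form
of the estimator.

All rate matrices are scaled by a single constant — the mean rate of the
$\omega = 1$ matrix at equilibrium — so that branch lengths are expected
substitutions per codon site at the neutral rate *for every category*.
Sharing one constant is what makes branch lengths shareable across
partitions with different selection regimes.

### Branch-site random effects over a partitioned tree

Branches are partitioned into three groups: the two element clades and the
connecting branch. Within a partition, each site on each branch draws
$\omega$ independently from a three-category mixture

$$\omega_1 \le 1 \;(\text{weight } p_1),\qquad \omega_2 = 1 \;(p_2),\qquad \omega_3 \ge 1 \;(1 - p_1 - p_2),$$

with mixture parameters shared by all branches of the partition. Because
draws are independent across branches and sites, the per-branch transition
matrix is the weight-averaged mixture
$P(t) = p_1 P_{\omega_1}(t) + p_2 P_{\omega_2}(t) + (1 - p_1 - p_2) P_{\omega_3}(t)$,
and the site likelihood is computed by ordinary Felsenstein pruning with
these mixture matrices (compiled core; per-pattern rescaling guards
against underflow). Branch lengths, the exchangeabilities, and the
frequency parameters are shared by all partitions. Pooling evidence across
all branches of a partition is what gives the test power at the low
divergences typical of recently endogenized elements — exactly where
single-branch methods run out of signal.

### Tests

Both tests constrain only the foreground partition(s); backgrounds always
keep the full unconstrained three-category mixture so a misspecified
background cannot masquerade as foreground selection. Several partitions
can be assigned the foreground role jointly; they then share one
parameter set (a merged foreground).

* **Purifying**: null = foreground neutral-only ($\omega_2 = 1$);
  alternative adds the purifying class ($\omega_1, p_1$).
* **Positive**: null = foreground purifying + neutral; alternative adds
  the positive class ($\omega_3$ and its weight).

Each alternative has two extra parameters, so $2\Delta\ln L$ is referred
to $\chi^2_2$, whose upper tail for two degrees of freedom is exactly
$e^{-\Lambda/2}$. The null lies on the boundary of the alternative
($p_1 = 0$, or equivalently $\omega_1 = 1$), so the $\chi^2_2$ reference
is an upper bound on the p-value and the test is conservative — a
property the test suite verifies empirically on null simulations.

## Parameters that matter, and their defaults

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `omega1` | purifying dN/dS, in $[0,1]$ | estimated | the quantity of interest |
| `p1`, `p2` | weights of $\omega_1$, $\omega_2$ | estimated | proportion of constrained sites |
| `omega3` | positive dN/dS, $\ge 1$ | estimated (positive test) | boundary at 1 keeps nesting clean |
| exchangeabilities | GTR rates, GT = 1 | estimated, start 1 | standard |
| `freqs` | CF3x4 mode | `"empirical"` plug-in | ML mode available; difference is tiny at these sizes |
| `restarts` | extra random optimizer starts | 3 | the $(\omega_1, p_1)$ surface is ridged |
| `min_stem`, `max_loop`, `max_mismatch` | hairpin call | 5 / 15 / 1 | detects the canonical begomovirus v-ori stem-loop; no published thresholds exist |
| RCR motifs | protein patterns | `[FY]LTY`, `H.H`, `Y..[KR]`, `G.{4}GK[TS]` | canonical HUH-endonuclease/Walker-A literature patterns; config, not code |

Branch lengths are in expected substitutions per codon site at the
neutral rate. They are re-optimized during fitting by coordinate sweeps
between global quasi-Newton rounds unless frozen with
`optimize_branch_lengths = FALSE`.

## Numerical choices

* **Transforms.** $\omega_1$ and single weights via logit; $(p_1, p_2)$
  in the three-class case via multinomial logit; $\omega_3 = 1 + e^x$;
  exchangeabilities via log. The optimizer (PORT/`nlminb`) works
  unconstrained; convergence is declared at $|\Delta \ln L| < 10^{-6}$.
* **Starts.** One heuristic start ($\omega_1 = 0.3$, $p_1 = 0.5$,
  neutral-ish elsewhere) plus seeded random perturbations; fits are
  deterministic given the seed. Nested fits warm-start at the null
  solution, which also guarantees the likelihood ordering in practice.
* **Staged sharing.** Inside a test the exchangeabilities are estimated
  once under the null and held fixed for the alternative
  (`stage_shared = TRUE`); both fits then share identical nuisance
  parameters and the LRT compares exactly the two selection parameters
  the degrees of freedom count. Setting `stage_shared = FALSE` re-frees
  them in the alternative.
* **Degenerate statistics.** A negative LR above $-10^{-4}$ (optimizer
  noise) clamps to zero with a warning; anything below that triggers a
  refit with more restarts and errors if it persists.
* **Missing data.** Gap or ambiguous codons contribute partial likelihood
  1 over all compatible sense codons. Unambiguous in-frame stops are
  rejected with a pointer to the screening filter. Site patterns are
  compressed before pruning; this is semantics-free and tested as such.

## What the simulator emulates — and what it does not

`simulate_alignment()` draws data from exactly the generative process the
likelihood assumes: root codon from the CF3x4 equilibrium, then for every
site and branch an independent category draw from the branch partition's
mixture, then evolution under that category's transition matrix. Draw
order is fixed (sites outer, branches in preorder), so a seed fully
determines the output. The per-site per-branch category draws are
returned as ground truth.

The default desk scenario mirrors the shape of the motivating study
system: 15 + 14 taxa in two clades, 350 codons, a strongly purifying
foreground ($\omega_1 = 0.2$, $p_1 = 0.8$), shallow within-clade
divergence (exponential branch lengths, mean 0.05 substitutions per codon
site — pairwise identities in the mid-90s, as observed between cloned
repeat copies) joined by a long connecting branch (0.8), transition-biased
exchangeabilities (AG = CT = 4) and mildly AT-rich positional
frequencies. These values are the package's fixed reference conditions
for its statistical self-checks, not tuning knobs.

The simulator deliberately omits several features of real integrated
elements: no recombination, no indels inside the codon alignment, no
among-site rate variation beyond the $\omega$ mixture, no base
composition drift across the tree. Passing the simulation-based checks
therefore demonstrates correctness of the estimator under its own
assumptions — it does not certify robustness to alignment error or
recombination, which is why recombination-flagged copies are excluded
upstream (the `exclude` field of the pipeline config) rather than modelled.

At low within-clade divergence the individual $(\omega_1, p_1)$ estimates
sit on a ridge — the data constrain the mixture mean
$p_1\omega_1 + (1 - p_1)$ much better than the two coordinates — so
replicate estimates scatter, including onto the $\omega_1 = 0$ and
$p_1 = 1$ boundaries, while their means track the truth. The
parameter-recovery check is therefore stated about means over replicates,
and the likelihood-ratio tests (which depend on the fitted likelihood,
not the coordinates) are unaffected.

## Design decisions that were genuinely open

* **Exact codon-model variant.** The combination "general reversible
  nucleotide model + CF3x4" pins the family but not the target-frequency
  convention; the MG94-style positional target factor was chosen because
  it is the convention of the branch-site random-effects lineage this
  model simplifies, and it makes CF3x4 exactly stationary.
* **Selection-parameter bookkeeping.** A full partition carries four free
  selection parameters ($\omega_1, \omega_3, p_1, p_2$; $\omega_2$ fixed
  at 1). The tests' degrees of freedom (two per test) follow from the
  two parameters each alternative adds.
* **Purifying-test alternative.** The alternative allows purifying and
  neutral classes only (no $\omega_3$), matching the constraint
  description rather than retaining a third class with free weight.
* **Connecting lineage.** Modelled as a partition containing exactly one
  branch, with its mixture estimated like any other partition's. Trees
  whose two clades are not separable by a single branch are rejected.
* **Frameshift definition.** Alignment-relative: any internal gap run
  whose length is not divisible by three, with terminal overhangs
  ignored. Stops are read off reference codons carrying a full observed
  triplet. Both choices are configurable inputs to screening, not
  hard-wired biology.
* **Hairpin ranking.** Candidate stems are ranked by matched pairs, then
  fewer mismatches, then shorter loop — raw stem length would let a
  tolerated mismatch outrank a perfect stem.
* **Distinct-copy bound.** "At least $k$ distinct copies" is certified by
  a maximum set of pairwise-conflicting sequences (ambiguity codes and
  terminal gaps as wildcards) — a maximum clique of the conflict graph,
  exact to 30 sequences, greedy beyond.

## Problem sizes used by the self-checks

The statistical checks run at sizes chosen to exercise the full pipeline
while staying desk-scale: the pruning oracle compares 100 random trees of
3–5 taxa against brute-force enumeration; conservativeness uses 50 null
replicates of 8 taxa x 200 codons; recovery uses 10 replicates of the
29-taxa x 350-codon default scenario with branch lengths held at their
generating values (the quantity under test is the selection parameters,
and the generating tree is the natural reference); the screening battery
uses 1,000 fixtures. Full-scale reproduction of the published selection
table requires the deposited alignment and is wired into the acceptance
suite as an explicitly failing check until those data are supplied
locally.

## Known limitations

* No site-level identification of selected codons (no per-site posterior
  reporting), no synonymous rate variation, and no confidence intervals
  beyond the LRT.
* The $\chi^2_2$ reference is conservative at the boundary; borderline
  p-values near the threshold are best interpreted with that in mind.
* Weak identifiability of $(\omega_1, p_1)$ at very low divergence is a
  property of the data, not the optimizer; report the mixture mean when
  the ridge matters.
* The screening detectors are pattern-based; they do not fold RNA
  thermodynamically, and the RCR motif defaults are literature patterns
  that should be overridden when a curated alignment of Rep motifs is
  available.
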