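---
title: "Quantifying NAD(P)+ cofactor specificity: models, screens and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying NAD(P)+ cofactor specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofspec)
```

## The problem

NAD+ and NADP+ differ by a single chemical group, the phosphate esterified
at the 2' position of the adenosine ribose. Dehydrogenases that must keep
catabolic and anabolic redox pools apart discriminate between the two
cofactors, often through one or two positively charged side chains facing
that 2'-phosphate. `cofspec` implements the quantitative chain that turns
raw initial-rate measurements into statements about this recognition:

1. **Kinetics** — initial rates from progress curves, replicate averaging,
   and nonlinear Michaelis–Menten fits giving $K_M$, $k_{cat}$ and the
   specificity constant $k_{cat}/K_M$ with standard errors.
2. **Energetics** — the NADP+/NAD+ *specificity quotient*
   $q = (k_{cat}/K_M)^{\mathrm{NADP^+}} / (k_{cat}/K_M)^{\mathrm{NAD^+}}$,
   a three-level preference classification, transition-state binding
   energies $\Delta G = -RT\ln q$, and double-mutant-cycle coupling
   energies.
3. **Structural screens** — geometric filters on NADP+ (NAP) complexes:
   ligand completeness and extended conformation, enumeration of positive
   residues contacting the 2'-phosphate, greedy sequence-identity
   redundancy reduction, and a geometric hydrogen-bond criterion with
   per-residue backbone/side-chain occupancy over multi-model coordinate
   sets.
4. **Synthetic data** — seed-deterministic generators that produce every
   input with known ground truth, so the whole chain is testable offline.

## Kinetic model and fitting choices

Initial rates obey $v = V_{max} S/(K_M + S)$ with $k_{cat} = V_{max}/[E]$.
`fit_michaelis_menten()` minimises the unweighted residual sum of squares by
Levenberg–Marquardt, restarted from three heuristic initialisations
($K_M$ at the median, a tenth of the maximum, and the maximum substrate
concentration) with the best optimum kept; convergence is declared at a
relative SSE change of $10^{-10}$. Unweighted least squares is the default
because published kinetic tables in this field report plain hyperbolic
fits; a per-point `weights` argument is exposed for heteroscedastic data
(the test suite pins the identity "doubled weight = duplicated point").
Standard errors come from the linearised covariance at the optimum — the
same "$\pm$" convention as the published tables — not from bootstrap;
the $K_M$–$V_{max}$ covariance is retained and used when propagating into
$k_{cat}/K_M$.

`extract_initial_rate()` implements the classical early-slope rule: an
ordinary least-squares slope restricted to the points where less than 5 %
(configurable) of the limiting substrate has been consumed. Three
qualifying points are required; coarser sampling is an error rather than a
silent extrapolation. The bias of this estimator decreases monotonically as
the window fraction shrinks, which the tests verify on integrated curves.

The signal-to-concentration conversion factor has **no default**: the
extinction coefficient and path length are assay-specific, so the user
must state them. `saturation_fraction()` supports the standard design check
that the fixed co-substrate was held above 90 % saturation while the
cofactor was varied.

## Energetics: sign conventions and boundaries

Transition-state theory links a ratio of specificity constants for two
ligands differing by a single non-reacting group P to the binding energy
that P contributes to the transition-state complex. With
$q = (k_{cat}/K_M)_{\mathrm{with\,P}} / (k_{cat}/K_M)_{\mathrm{without\,P}}$,

$$\Delta G = -RT \ln q,$$

negative when P is recognised favourably. Because the literature mixes
"contribution of −3.4 kcal/mol" with "a decrease of 1.6 kcal/mol", the two
directions are separate functions with explicit semantics:
`transition_state_dg()` reports *contributions* (negative = favourable),
`side_chain_removal_dg()` reports *removal losses* (positive = the removed
side chain was favourable). $R = 1.987\times10^{-3}$ kcal mol⁻¹ K⁻¹ and
$T = 298.15$ K by default, matching assays at 25 °C and kcal/mol
reporting.

The preference classification folds the quotient to $\max(q, 1/q)$:
below 10-fold the enzyme is *dual*, between 10- and 100-fold *preferring*,
above 100-fold *specific*. The boundary values 10 and 100 are assigned to
"preferring" (the defining phrase is "between 10 and 100-fold"); the
thresholds are arguments, so other conventions are one keystroke away.
When $k_{cat}$ values are unavailable the ratio
$K_M^{\mathrm{NAD^+}}/K_M^{\mathrm{NADP^+}}$ serves as a proxy (preference
in this family is dominated by $K_M$), and the result is flagged
`basis = "km_proxy"`.

The double-mutant cycle (`build_cycle()`) takes the four specificity
constants of wild type $(i,j)$, two single alanine mutants $(0,j)$,
$(i,0)$ and the double mutant $(0,0)$, all with one cofactor. Edges are
removal losses; the coupling energy is $\Delta G_d - \Delta G_a$ and the
closure residual $\Delta G_a + \Delta G_c - \Delta G_b - \Delta G_d$ is an
algebraic identity equal to zero, asserted to machine precision (a nonzero
residual means the four constants were not a consistent quadruple).

Error propagation throughout assumes the two specificity constants of a
ratio are independent — they come from fits to disjoint datasets. This is
a stated limitation: shared systematic errors (enzyme titration, substrate
purity) are not modelled.

Two numerical notes on the packaged reference tables
(`ecoli_g6pdh_kinetics()`, `bacterial_g6pdh_kinetics()`): the printed
$k_{cat}/K_M$ column of the E. coli variant table is rounded independently
of the printed $K_M$ and $k_{cat}$, so quotients are computed from the
specificity-constant column itself (23.2/0.06 = 386.7, where recombining
174/7.5 with 288/5090 would give 410). The package always reports the
recomputed value — e.g. $-RT\ln 386.7 = -3.53$ kcal/mol — rather than any
independently rounded printed energy. For the bacterial survey table the
quotients are recomputed from the $K_M$ and $k_{cat}$ columns, which
reproduces the published per-organism quotients (415, 955, 9.4, …) at
their printed precision.

## Structural screens

The NADP+-complex survey applies three strict geometric filters, in the
order completeness → extension → contacts:

* **Completeness**: the NAP component has 48 heavy atoms; anything less
  means a partially modelled cofactor and the structure is excluded.
* **Extended conformation**: the distance between nicotinamide C2 (`C2N`)
  and adenine C6 (`C6A`) must exceed 12 Å — the Rossmann-bound pose, as
  opposed to a folded dinucleotide. The inequality is strict; 12.000 Å
  fails.
* **2'-phosphate contacts**: a positive residue counts when any of its
  charged side-chain nitrogens (Arg NE/NH1/NH2, Lys NZ, optionally His
  ND1/NE2) lies strictly closer than 4 Å to any 2'-phosphate atom. The
  2'-phosphate atom set is fixed to the NAP names `P2B`, `O1X`, `O2X`,
  `O3X` — phosphorus included, since the criterion is electrostatic
  proximity, but the set is an argument. Histidine is off by default
  because its protonation state, hence its charge, is ambiguous at
  cytoplasmic pH.

`summarize_survey()` then counts structures (not residues): how many pass
the ligand filters, how many of those have ≥ 2 positive contacts, and how
many of the latter involve an Arg + Lys pair. Redundancy reduction uses
greedy global-alignment identity clustering (`cluster_by_identity()`,
< 70 % identity, matches / alignment length with gaps in the length,
BLOSUM62 with gap penalties 10/0.5): greedy in input order because the
choice of redundancy tool is not standardised, and the ordering is then the
only tie-break needed — the result is deterministic for a given input
order. A precomputed representative list can be used instead by indexing.
The identity screen operates per supplied sequence; when a structure has
several chains the caller passes the longest protein chain
(`chain_sequences()` provides them).

PDB input/output is delegated to `bio3d` (first MODEL by default,
alternate locations collapsed to highest occupancy); `annotate_bfactor()`
writes per-residue values into the B-factor column, split
backbone/side-chain, for surface visualisation, surviving the format's
two-decimal precision.

## Hydrogen-bond criterion

A hydrogen bond is a (donor, hydrogen, acceptor) triple with donor–acceptor
distance **strictly below 3.5 Å** and donor–hydrogen–acceptor angle
**strictly above 120°**. Both boundaries are pinned by tests that set the
threshold to the exactly measured geometry of a constructed pair. Frames
are analysed independently — no temporal smoothing — and occupancy is the
fraction of frames with at least one qualifying bond per (residue, moiety,
ligand group) series, with backbone defined as atom names N, H, O, C, CA.

Hydrogens must be explicit (MD-style frames); the package does not infer
hydrogen positions, and a donor heavy atom whose dictionary hydrogen is
missing raises an error naming the atom rather than silently dropping the
donor. The donor/acceptor inventory itself is not standardised anywhere,
so it ships as an editable TSV (`inst/extdata/hbond_chemistry.tsv`)
covering the 20 amino acids plus NAP/NAD: backbone N–H donors (except
proline) and carbonyl acceptors, the usual polar side chains, adenine N6
and carboxamide N7 as ligand donors, ring nitrogens and all oxygens as
ligand acceptors. Symmetric nicotinamide N/O acceptors are included; users
who disagree edit the file or pass their own `hbond_spec()`.

## What the synthetic generators emulate — and what they do not

* `simulate_rate_dataset()` draws rates on the hyperbola with
  multiplicative Gaussian noise (constant CV), the error structure
  suggested by roughly proportional published error bars. Defaults: 5 %
  CV, 3 replicates — three independent measurements per concentration is
  the standard design.
* `simulate_progress_curve()` integrates $dS/dt = -V_{max}S/(K_M+S)$ with
  `deSolve::lsoda` at relative tolerance $10^{-9}$, with additive noise
  (absorbance noise is additive). Its output satisfies the implicit
  integrated rate law $K_M\ln(S_0/S) + (S_0-S) = V_{max}t$ to $10^{-6}$,
  which the tests assert, along with the zero-order and first-order
  closed-form limits.
* `make_toy_complex()` embeds a synthetic idealized NAP geometry
  (`nap_template()` — correct 48-atom roster and an extended conformation,
  built in code; it is *not* the crystallographic component geometry) and
  places probe nitrogens at exact planted distances from the
  2'-phosphate, plus decoys ≥ 6 Å away. Planted distances below 1.5 Å are
  rejected as steric nonsense.
* `make_hbond_frames()` realises one donor/H/acceptor triple per frame at
  exactly the scheduled distance and angle, then applies a random rigid
  motion per frame, so detection must be motion-invariant to recover the
  schedule.

All generators are seed-deterministic (identical recipe + seed gives
bit-identical output). What passing tests on these fixtures shows is that
the *computational chain* is correct: geometry is measured exactly,
estimators recover known parameters, and counts match planted truth. What
they do not show: force-field realism of toy complexes (geometry only),
real heteroscedasticity structure of plate-reader data, partial occupancy
and disorder in crystallographic ligands, or the composition of any
particular PDB snapshot — the published whole-PDB census (hundreds of
complexes, with roughly a third showing two positive charges at the
2'-phosphate) depends on the database snapshot and is deliberately not
re-derived here.

## Problem sizes and numerical defaults

The shipped tests and the acceptance script use: 200 simulated datasets of
7 concentrations × 3 replicates for the noise-recovery study (median
absolute $K_M$ bias ≈ 4 % at 5 % CV, versus a 10 % acceptance bound); 1000
random quadruples for the cycle-closure identity (residual < $10^{-12}$);
50 random ~300-atom frames checked against an exhaustive brute-force
triple enumeration; and 20 synthetic complexes with planted contact truth
for the survey statistics. These sizes give stable statistics while
keeping a full run in well under a minute per component.

Numerical choices worth knowing: the MM fit constrains both parameters to
be non-negative; grid-search cross-checks in the tests confirm the
optimiser's SSE is never beaten by an exhaustive 200 × 200 scan. All
geometric filters use strict inequalities exactly as their defining
phrases state ("more than 12 Å", "below 3.5 Å", "closer than 4 Å").
Quotients of identical constants give exactly $q = 1$ and
$\Delta G = 0$ (no catastrophic cancellation: `log(1)` is exact).

## A worked example

```{r example}
# fit synthetic wild-type-like data for both cofactors and classify
d_nadp <- simulate_rate_dataset(km = 7.5, kcat = 174, enzyme_conc = 0.01,
                                s_grid = c(1, 2, 5, 10, 20, 50, 100),
                                noise_cv = 0, seed = 1,
                                enzyme_label = "WT", cofactor_label = "NADP+")
d_nad <- simulate_rate_dataset(km = 5090, kcat = 305.4, enzyme_conc = 0.01,
                               s_grid = c(500, 1000, 2500, 5000, 10000,
                                          25000, 50000),
                               noise_cv = 0, seed = 2,
                               enzyme_label = "WT", cofactor_label = "NAD+")
f_nadp <- fit_michaelis_menten(d_nadp)
f_nad <- fit_michaelis_menten(d_nad)
q <- specificity_quotient(specificity_from_fit(f_nadp),
                          specificity_from_fit(f_nad))
q$quotient
classify_preference(q$quotient)
transition_state_dg(q$quotient, q_se = q$se)
```

## Known limitations

* Single-substrate treatment only: the co-substrate is assumed fixed near
  saturation; no bi-substrate mechanism fitting.
* Independence assumption in all error propagation.
* No hydrogen inference, no trajectory formats beyond multi-MODEL PDB,
  no mmCIF writing.
* The KM-proxy classification inherits the assumption that $k_{cat}$
  differences are secondary; it is flagged in the output so downstream
  users can treat proxy-based categories with appropriate caution.
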