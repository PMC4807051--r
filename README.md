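# cofspec

Quantitative analysis of NAD⁺/NADP⁺ cofactor specificity in
dehydrogenases: from raw initial-rate data to Michaelis–Menten constants,
specificity quotients and preference classes, transition-state binding
energies, double-mutant-cycle coupling energies, and the geometric
structural screens used to survey NADP⁺ recognition.

## Who this is for

Enzymologists and structural bioinformaticians characterising how an
enzyme discriminates between NAD⁺ and NADP⁺ — two cofactors that differ by
a single 2'-phosphate group. The package covers the full quantitative
chain used in mutant-cycle studies of cofactor preference, plus the
structure-based screens (2'-phosphate contacts, hydrogen-bond occupancy)
that rationalise the kinetics.

## The core quantities

The **specificity constant** k<sub>cat</sub>/K<sub>M</sub> is the
second-order rate constant governing competition between alternative
substrates for one site. One enzyme's preference is the **specificity
quotient**

> q = (k<sub>cat</sub>/K<sub>M</sub>)<sup>NADP⁺</sup> / (k<sub>cat</sub>/K<sub>M</sub>)<sup>NAD⁺</sup>,

classified as *dual* (q folded below 10), *preferring* (10–100-fold) or
*specific* (above 100-fold). Because the two cofactors differ only by the
2'-phosphate, transition-state theory turns the quotient into the binding
energy that the phosphate (or, comparing wild type with a deletion mutant,
a side chain) contributes to the transition-state complex:

> ΔG = −RT ln q  (kcal/mol, negative = favourable).

A 2×2 set of variants (wild type, two single alanine mutants, the double
mutant) forms a **double-mutant cycle** whose edge energies reveal whether
two side chains act additively or are energetically coupled.

On the structural side, NADP⁺ (PDB component `NAP`, 48 heavy atoms)
complexes are screened for completeness, extended conformation (C2N–C6A
distance > 12 Å), and positive residues with charged nitrogens strictly
closer than 4 Å to the 2'-phosphate; hydrogen bonds in multi-MODEL
trajectories use the geometric criterion donor–acceptor < 3.5 Å and
donor–H–acceptor angle > 120°.

## A worked example

Fit noisy synthetic wild-type-like data for both cofactors, form the
quotient, classify, and convert to an energy:

```r
library(cofspec)

d_nadp <- simulate_rate_dataset(km = 7.5, kcat = 174, enzyme_conc = 0.01,
                                s_grid = c(1, 2, 5, 10, 20, 50, 100),
                                noise_cv = 0.05, seed = 1,
                                enzyme_label = "WT", cofactor_label = "NADP+")
d_nad  <- simulate_rate_dataset(km = 5090, kcat = 305.4, enzyme_conc = 0.01,
                                s_grid = c(500, 1000, 2500, 5000, 10000,
                                           25000, 50000),
                                noise_cv = 0.05, seed = 2,
                                enzyme_label = "WT", cofactor_label = "NAD+")
f_nadp <- fit_michaelis_menten(d_nadp)
f_nadp
#> Michaelis-Menten fit: WT / NADP+
#>   KM   = 7.759 +/- 0.42 uM
#>   kcat = 178.1 +/- 2.7 1/s
#>   kcat/KM = 22.96 1/(uM s);  r = 0.9961;  n = 21

f_nad <- fit_michaelis_menten(d_nad)
q <- specificity_quotient(specificity_from_fit(f_nadp),
                          specificity_from_fit(f_nad))
classify_preference(q$quotient)
#> Cofactor preference: NADP-specific (386-fold, basis: specificity_constants)
transition_state_dg(q$quotient, q_se = q$se)
#> deltaG = -3.53 +/- 0.043 kcal/mol (T = 298.15 K)
```

The fitted KM (7.76 ± 0.42 µM) recovers the generating value 7.5 µM within
its standard error; the 386-fold quotient says this enzyme is
NADP⁺-specific, and the phosphate contributes −3.5 kcal/mol to
transition-state binding.

The packaged reference kinetics of the E. coli
glucose-6-phosphate-dehydrogenase variants drive the double-mutant cycle:

```r
cyc <- build_cycle(variant_specificity("WT", "NADP+"),
                   variant_specificity("K18A", "NADP+"),
                   variant_specificity("R50A", "NADP+"),
                   variant_specificity("K18A-R50A", "NADP+"))
cyc
#> Double-mutant cycle (NADP+)
#>   (i,j) WT --a: 1.66--> (0,j) K18A
#>   (i,j) WT --b: 2.27--> (i,0) R50A
#>   (0,j) K18A --c: 2.93--> (0,0) K18A-R50A
#>   (i,0) R50A --d: 2.32--> (0,0) K18A-R50A
#>   coupling = 0.654 kcal/mol; closure residual = -4.44e-16
```

Removing K18 costs 1.66 kcal/mol of transition-state binding while R50 is
present but 2.32 kcal/mol once R50 is gone: the two positive charges are
negatively coupled by ~0.65 kcal/mol, each damping the other's
contribution to 2'-phosphate recognition.

See `vignettes/cofactor-specificity.Rmd` for the full account of the
models, screens, numerical choices and limitations, and `run_report()` for
the one-call pipeline from a rates CSV to a JSON report.

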