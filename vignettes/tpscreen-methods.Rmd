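---
title: "Suspect screening of transformation products: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Suspect screening of transformation products: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpscreen)
```

`tpscreen` implements a suspected-target analysis for transformation
products (TPs) of small-molecule drugs observed by accurate-mass
spectrometry, with monensin — a C36 polyether ionophore measured as sodium
and ammonium adducts — as its worked case study. This vignette explains the
underlying models, the tunable parameters and the design decisions, and
states what the synthetic experiments do and do not demonstrate.

## Mass arithmetic and the adduct convention

All masses are monoisotopic, summed from the bundled isotope table
(CIAAW/IUPAC values to at least eight decimals, `element_table()`). Adduct
ions are singly charged cations; their m/z is electron-corrected,

$$m/z = \frac{M + m(\text{adduct atoms}) - m_e}{z}, \qquad z = 1,$$

with $m_e$ = 0.000549 Da. The correction matters at the reporting precision
of four decimals: for sodiated monensin A it shifts the value from 693.4190
to 693.4184. Twelve of the thirteen species in the bundled reference table
(`mon_tp_table()`) reproduce their reported m/z to within 0.0002 Da under
this convention. The exception is TP 8 (`C34H58O11Na`, reported 665.3877):
that value matches the *uncorrected* sum (665.38768) to 0.0001 Da, while
the corrected value is 665.38713. No single convention reproduces all
thirteen values to ±0.0005 Da; the package keeps the physically correct
electron-corrected convention everywhere and treats the TP 8 entry as an
inconsistency of the source data. m/z values are reported at four decimals
using round-half-even.

The [M+Na]⁺/[M+NH₄]⁺ spacing, `adduct_pair_delta("+Na", "+NH4")` = 4.9554
Da, is independent of the neutral formula — the screening stage uses it to
confirm that two features are the adduct pair of one species rather than
two different compounds.

## Isotope patterns and the sigma score

`theoretical_pattern()` convolves per-element isotope distributions
(binary exponentiation over atom counts) and aggregates by nominal mass,
i.e. integer Da offsets from the monoisotopic peak. Nominal binning is
deliberate: the TOF resolution this pipeline targets does not resolve the
fine structure within M+1 (¹³C vs ¹⁷O), so each bin is a centroid at the
abundance-weighted mean mass. Patterns are normalized to base peak 1,
pruned at `prune` (default 1e-4) and truncated at `max_peaks` (default 6).
Correctness is tested against exhaustive isotopologue enumeration for
small formulas.

The instrument software the field uses ranks formula candidates by a
proprietary "Sigma" isotope-fit value whose formula is not public. The
package defines its own documented metric with the same role:
`sigma_score()` is the root-mean-square deviation of base-peak-normalized
abundances over matched nominal-mass bins, with bins present in only one
pattern contributing their full abundance. It is deterministic,
scale-invariant, zero for a perfect fit, and symmetric when both patterns
cover the same bins. Because no acceptance threshold for the vendor metric
is documented, ranking is relative only: no candidate is ever rejected on
sigma alone.

## Formula decomposition

`decompose_mz()` enumerates every neutral formula whose adduct m/z lies
within `tol_ppm` (default 3 ppm, applied on the adduct m/z, not the neutral
mass) for each requested adduct. The search loops over the bounded
C × N × O × Na lattice and solves hydrogen by mass closure, which makes it
exhaustive yet fast (the default lattice has ~7700 points); a guard
refuses bounds admitting more than 1e8 points. Default bounds — C 0–60,
H 0–120, N 0–2, O 0–20, Na 0–1 — are the package's choice: the case study
concerns a single C36 scaffold, N and Na exist only as adduct chemistry,
and the bounds still admit plausible distractors (nine compositions match
693.4184 at 3 ppm). The RDBE filter (default on, range [0, 40], computed
as C − H/2 + N/2 + 1 on the neutral formula) removes chemically absurd
compositions; half-integer values are kept because even-electron cation
compositions legitimately produce them. Equivalence with a naive
full-lattice oracle is tested at 50 random masses below 200 Da.

Ranking (`rank_candidates()`) uses the fully specified key
(sigma ascending, |ppm| ascending, formula text ascending) so results are
reproducible to the row. `subformula_candidates()` reuses the decomposer
with per-element maxima set to the precursor counts, the generic support
for MS/MS fragment annotation; its RDBE filter is off by default because
fragment compositions may be odd-electron.

## Transformation paths and structural classes

`enumerate_paths()` searches multisets (order never matters at formula
level) of at most `max_steps` elementary reactions whose summed delta
equals the parent–product element difference. Two design rules keep the
output canonical:

- paths containing a nonempty proper sub-multiset summing to zero (no-op
  cycles like hydration + dehydration, or methylation + demethylation) are
  pruned — a strictly shorter equivalent path always exists;
- a zero element difference returns exactly the single path ISOMERIZATION,
  the formula-level representation of both diastereomerization and ring
  opening.

`max_steps` defaults to 3, the smallest value that explains every TP in
the reference table. The reference table's printed shorthand is known to
drop a dehydrogenation in two rows (TP 1, TP 3); path labels derived from
the formulas are authoritative and the shorthand is carried only as an
annotation.

`suspect_list()` applies the same multisets forward from the parents,
discards products with negative counts, deduplicates by formula keeping
the shortest path (ties go to the first-listed parent), and pairs each
suspect with each adduct. A consequence worth knowing: a product formula
reachable from both homologous parents is credited to the shorter route —
`C34H58O9` is two steps from MON B but three from MON A, so formula-level
screening reports the MON B route even though MS/MS evidence in the study
this emulates places it on MON A. Resolving that requires fragment data,
which is out of the package's scope.

`structural_classes()` groups TP records by (canonical minimal-path label
relative to the record's own parent, isomer annotation). The same
transformation on two homologues is one class; stereoisomer duplicates
(same formula, same path, different retention) collapse; formula-neutral
isomers with different chemistry (diastereomer vs ring-opened) stay
separate through their annotations. On the twelve reference TP records
this yields nine structural classes.

## Screening

`extract_features()` links peaks across scans greedily in scan order to
the nearest feature within `mz_tol_ppm` (default 4 ppm, twice the ~2 ppm
instrument accuracy) of the feature's running intensity-weighted mean m/z,
at most one peak per feature per scan, zero-filling gaps. When peaks carry
retention times (hydrolysis series measured by LC/MS), linking also
requires agreement within `rt_tol` (5 s), which is what separates
formula-neutral isomers. `min_scans` (default 3) suppresses sporadic
baseline peaks. There is no chromatographic modelling: EC ramps have no
retention dimension at all.

Trends are classified by Spearman rank correlation of intensity against
the scan axis (`classify_trend()`): ρ ≥ 0.6 product, ρ ≤ −0.6 precursor,
otherwise flat. Rank correlation is robust to the sigmoidal shape of
voltammogram traces; 0.6 keeps the false-product rate at zero in
parent-only simulations at the default noise while classifying noisy
sigmoid rises correctly in ≥ 95 of 100 replicates. Constant traces are
flat with statistic 0.

`match_suspects()` assigns product features to the nearest suspect within
`tol_ppm` (ambiguities keep the lower |ppm| and are logged), merges the
Na/NH₄ features of one formula, and classes intensity relative to the
maximum feature intensity of the first parent using the half-open bins
s ≥ 60 % > ms ≥ 30 % > w ≥ 10 % > vw. The reference-intensity choice
(feature maximum across the run, first parent) and the half-open bin
convention are package decisions — the reporting tradition prints touching
ranges without resolving boundaries or stating whether areas or heights
were used.

`occurrence_table()` declares a species present on a sampling day when any
of its features reaches `detect_threshold` (default 1 %) of the parent
intensity on the first sampled day; days missing from a series are
reported as not measured, distinct from absent.

## Synthetic data and kinetics

The generators emulate the study conditions: a 0–2.5 V ramp sampled every
0.05 V (51 scans; validation refuses ranges beyond the 3.5 V electrode
ceiling), sigmoidal precursor decay and product rise, both adducts per
species with an NH₄:Na intensity ratio of 3 (the literature states only
"more intense"; 3 is the package's configurable choice), Gaussian m/z
error of 0.7 ppm (giving ≥ 99.7 % of peaks within ±3 ppm), multiplicative
log-normal intensity noise (σ = 0.05), and five Poisson baseline peaks per
scan. All draws derive from one master seed, recorded in the manifest;
identical calls are byte-identical and the caller's RNG state is restored.

Hydrolysis follows the sequential acid-catalyzed network

$$\text{parent} \underset{k_r}{\overset{k_1}{\rightleftharpoons}}
\text{diastereomer} \xrightarrow{k_2} \text{ring-opened}
\xrightarrow{k_3} \text{dehydrated},$$

integrated with `deSolve::lsoda` at tight tolerances (mass conserved to
1e-8; the first two products share the parent's formula and are separated
by retention time, the third loses H₂O). Every rate scales as
$([\mathrm{H^+}]/[\mathrm{H^+}]_{\text{ref}})^\alpha$. The defaults —
k₁ = 0.2, k_r = 0.3, k₂ = 0.4, k₃ = 0.15 /day at the pH 3 reference,
α = 0.7 — are calibrated to the qualitative occurrence pattern of the case
study, not fitted to measured kinetics: the dehydrated product appears on
day 2 at pH 3 yet not within 30 days at pH 5, the ring-opened isomer
appears at every pH with delays growing as pH rises, and all species
persist once formed. A strictly first-order acid dependence (α = 1) cannot
reproduce that pattern at any rate set: it stretches threshold-crossing
times tenfold per pH unit, while the observed pattern requires roughly
three- to five-fold, so either the dehydrated species would leak through
at pH 5 or the diastereomer would fall below detection by day 30 at pH 3.
A sub-first-order effective acid order is also what buffered general-acid
catalysis tends to show. α is exposed and documented for users who want
the textbook law.

What passing the synthetic battery shows — and what it does not: the
pipeline recovers 100 % of seeded TP formulas with zero false formulas
across 20 seeds at the stated noise, so the feature-linking, trend and
matching logic is internally consistent with the measurement model. Real
EC/MS data additionally contain chemical background with systematic
trends, in-source fragments, isotope-feature overlap and detector
saturation, none of which the generator emulates; results on real data
therefore depend on tolerances the user must tune (`default_config()`
collects them all).

## Numerical choices and degenerate inputs

Tolerances are absolute in Da only where the physics is (adduct spacing),
ppm elsewhere. Empty decomposition results, empty path lists and empty
suspect matches are valid outcomes, not errors; the empty formula has mass
zero; constant traces classify as flat; a parent intensity of zero makes
intensity classes undefined and raises an error rather than returning
infinity. Tie-breaks are specified everywhere (ranking keys, dedup order,
alphabetical path labels) so that identical inputs, configuration and seed
give byte-identical reports, which the test suite asserts literally.

## Known limitations

- Only {C, H, N, O, Na} and singly charged cations; no average masses, no
  multiply charged ions, no isotope labelling, no fine isotopic structure.
- Parent assignment of a TP is by shortest formula path; MS/MS-level
  evidence can overrule it and is out of scope beyond generic subformula
  candidates.
- The occurrence analysis assumes monotone kinetics when interpreting
  presence; oscillating systems would need the raw traces.
- The sigma metric is this package's definition, not the vendor's; scores
  are comparable within a candidate set, not across instruments.
- The reference table reproduces reported values verbatim, including the
  TP 8 m/z inconsistency and a known caption typo ("TPs 10–13" where only
  TP 10–12 exist).
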