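---
title: "Methods: kinetic determination and QSPR modelling of antioxidant rate constants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinetic determination and QSPR modelling of antioxidant rate constants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the models behind `oxiqspr`, the assumptions they
make, the parameters that matter, and the design decisions taken where the
underlying methodology left genuine freedom.

## 1. The kinetic model

The package analyses initiated radical-chain oxidation in the kinetic
regime: an azo-initiator decomposes at constant rate, substrate peroxyl
radicals RO₂• carry the chain, and termination occurs either by peroxyl
recombination (rate constant 2k₆) or, in the presence of an inhibitor InH,
by the reaction RO₂• + InH → ROOH + In• with rate constant k₇. Under the
quasi-steady-state assumption the suppression of the initial oxygen-uptake
rate obeys

\[ F \;=\; \frac{V_0}{V} - \frac{V}{V_0} \;=\;
   \frac{f k_7\,[\mathrm{InH}]}{\sqrt{2k_6 V_i}} , \]

so a plot of F against inhibitor concentration is a straight line through
the origin. The package fits that line **through the origin**: F vanishes
identically at zero concentration, so an unconstrained intercept only
absorbs noise and biases the slope (on the bundled AO1 table the intercept
fit lowers the slope by roughly 14%). The slope times √(2k₆Vᵢ) is the
effective constant f·k₇; its standard error is the through-origin
least-squares slope error scaled the same way.

The stoichiometric coefficient f comes from induction periods:
τ = f·[InH]/Vᵢ. Induction periods are extracted by the **two-tangent
construction**: the curve is split at the interior breakpoint minimizing
the summed squared residuals of two disjoint straight-line fits, and τ is
the intersection abscissa of those lines. The extraction method is not
dictated by the theory; the two-tangent rule was chosen because it is the
standard graphical practice for induction periods, is exact on
piecewise-linear curves, and degrades gracefully under noise. A curve whose
two slopes agree within a relative tolerance (default 5%) is reported as
having no induction period (τ = 0, flagged).

Finally k₇ = f·k₇ / f, with the relative errors combined in quadrature,
and logk₇ = log₁₀ k₇. Initiation rates follow Vᵢ = 2e·kₚ[AIBN] with
log₁₀kₚ = 17.70 − 35/(4.575·10⁻³·T) (decay constant measured in
cyclohexanol; e defaults to 0.5).

Constants and units (all mol, L, s): 2k₆ = 6.67×10⁷ and k₂ = 7.9
L mol⁻¹ s⁻¹, [RH] = 11.75 mol/L, Vᵢ = 10⁻⁷ mol L⁻¹ s⁻¹, T = 348 K. k₂ and
[RH] do not enter the F analysis; they are stored for completeness and used
by the simulator only. Initial rates are least-squares slopes over an
initial window (default: the first 10% of points, minimum 3) with the
window R² reported as a linearity diagnostic — the original experimental
window is not documented, so it is a user parameter.

## 2. Molecular graphs and descriptors

Structures (SMILES or SDF V2000) are normalized by OpenBabel with explicit
hydrogens before graph extraction; the graph keeps element, formal charge
and ring membership per atom and an unordered bond list. Bond orders are
parsed but deliberately ignored downstream — the descriptor formalism does
not distinguish bond types. Ring membership means "lies on at least one
simple cycle", computed from bridge edges; ring size is not encoded.

**MNA descriptors.** The level-0 descriptor of an atom is its label; the
level-k descriptor is `label(atom)(D₁D₂…)` with the level-(k−1) neighbor
descriptors concatenated in lexicographic byte order, which makes the text
canonical. Labels are the element symbol, prefixed `-` for acyclic atoms
and suffixed with `+`/`-` repeated |charge| times. Decisions taken here:

* hydrogens are included as first-class atoms (neighborhoods are over all
  immediate neighbors, without exclusions);
* the acyclic marker is a `-` prefix, the convention of the descriptor
  family's ancestry;
* the default level is 2 (configurable 0–3): level 2 captures
  two-bond environments — enough to distinguish, e.g., ortho- from
  para-substitution patterns — while keeping vocabularies in the low
  hundreds for phenol-sized molecules.

**Whole-molecule descriptors.** Three scalars accompany the counts, all on
the hydrogen-suppressed graph: topological length = graph diameter in
bonds; topological volume = additive per-element contributions (bundled
van-der-Waals-like table); lipophilicity = additive per-atom logP
increments (bundled crude element table, hydrogens included so that a CH₂
insertion increases the value). The exact formulas behind these three
quantities in the original modelling software are not public; the additive
definitions above are this package's own, and both contribution tables are
pluggable arguments for users with better-calibrated schemes.

**Second descriptor family.** For ensemble diversity a compact numeric
family (`ana_descriptors`) of the package's own design is provided: per
element, four aggregates (atom count, total heavy-neighbor degree, ring
count, attached-hydrogen count). It is intentionally simple — its role is
to decorrelate partial models, not to be informative on its own.

Descriptor matrices fix the column order to the training vocabulary
(first-seen, then lexicographic); at prediction time unseen descriptors
are dropped and their per-compound fraction feeds the applicability
domain.

## 3. Self-consistent regression and the consensus ensemble

The variable-selection engine (`fit_scr`) is iterative ridge-stabilized
least squares with backward elimination:

1. start from all non-constant columns (with a univariate correlation
   screen to 3n columns when p > 3n);
2. fit ridge regression (λ = 10⁻³·tr(XᵀX)/p by default — small enough to
   leave well-conditioned solutions essentially unpenalized, large enough
   to stabilize collinear count columns);
3. compute t-statistics using the **effective degrees of freedom** of the
   ridge fit (trace of the hat matrix), so residual variance remains
   meaningful when p approaches n;
4. drop insignificant columns (|t| < 2) gradually — at most a quarter of
   the current columns per pass — so variables masked by collinear rivals
   can regain significance as the rivals leave; when everything is
   significant but more than `max_vars` (default 30) columns remain, drop
   the single worst;
5. refit the surviving columns by ordinary least squares. The ridge is a
   selection device only: on noise-free data the final coefficients are
   exact (recovered to ~10⁻⁶ in the tests).

The internal workings of the original selection algorithm are not public;
the procedure above is a surrogate designed to reproduce its documented
behaviour (compact significant equations, high training R², lower
cross-validated Q²), not a reconstruction.

**Radial-basis refinement** fits a Gaussian kernel interpolator over the
selected-column subspace to the linear model's residuals (kernel width
"auto" = median pairwise distance; ridge-stabilized solve, so duplicate
rows with conflicting responses do not break it). Training error never
exceeds the plain linear fit's.

**Consensus.** Each of `n_partials` partial models is fitted on a random
80% of the training rows (the 20×20% stability idea turned into ensemble
generation); presets: `mna` and `qna_like` use one descriptor family
(20 partials), `both` cycles through 16 family/level/hydrogen variants ×
20 resamples = 320 partials. The consensus prediction is the arithmetic
mean over accepted partials. Internal validation (`cross_validate_lmo`)
repeats 20 rounds of leaving out 20%, scoring 1 − PRESS/SS_tot on the
held-out fold against the training-fold mean.

**Applicability domain.** Undefined in the source methodology beyond the
notion itself; here a compound is outside the domain when its unseen
descriptor fraction exceeds 0.2, or when fewer than half the partials
accept it by leverage (x'(XᵀX)⁻¹x > 3p/n in the partial's selected-column
subspace). Out-of-domain predictions are still returned, flagged.

All randomness flows from a single mandatory seed (default 20191); the
same data and seed give byte-identical serialized models.

## 4. Splitting and validation conventions

Rank-ordered 5:1 splitting sorts records by activity (ties by id) and
transfers every 6th rank to the test set. The first selected rank is an
explicit parameter because the two published set-size pairs are mutually
inconsistent under any single convention: 148 → 123/25 requires selecting
rank 1 first, 123 → 103/20 requires rank 6 first. Both are reproduced by
`start_offset = 1` and `= 6` respectively.

Metric conventions, where names alone underdetermine the formula:

* R²₀ is the through-origin determination coefficient of the
  observed-on-predicted fit (k = Σop/Σp²), R′²₀ the swapped one; r²ₘ =
  R²(1 − √(R² − R²₀)) and its primed analogue; negative radicands
  (possible numerically) use the absolute value and set a flag.
* CCC uses population (1/n) moments — the concordance convention, which
  the hand-checkable example 2·1.25/(1.25+1.25+1) = 0.7143 pins down.
* SD is the standard deviation **of the absolute residuals**, making
  MAE + 3SD internally coherent with the published arithmetic
  (e.g. 0.0855 + 3·0.0679 = 0.2892).
* Trimming removes ⌈fraction·n⌉ worst-residual records (minimum 1 when the
  fraction is positive): 5% of 123 removes 7.
* Quality classification: "high" requires MAE ≤ 10% of the training
  activity range and MAE+3SD ≤ 10% as literally stated by the rule set
  this package follows; because the 10% bound on MAE+3SD is unusually
  strict (a common alternative is 20%), the bound is a parameter
  (`mae3sd_high_frac`). "Low" triggers on MAE > 20%, MAE+3SD > 25%,
  r²ₘ ≤ 0.5 with Δr²ₘ ≤ 0.2, or the whole R-family ≤ 0.6; otherwise
  "moderate".
* The systematic-error check is a surrogate (the referenced validation
  tool's rule set is unpublished): error is flagged when |mean residual| >
  0.5·MAE or more than 80% of residuals share a sign.

## 5. Synthetic data: what it emulates and what it does not

The kinetic generator inverts the same quasi-steady-state law the analysis
assumes: given f·k₇, each concentration yields F, and V/V₀ is the positive
quadratic root (−F + √(F²+4))/2. Curves are piecewise linear with the
corner at τ = f·[InH]/Vᵢ (optional quadratic corner smoothing; real curves
round the corner). The default concentration grid mirrors the experimental
one, (0.44–3.13)×10⁻⁶ mol/L. Because generator and analysis share the
model, round-trip tests check the estimation machinery, not the chemistry:
they cannot detect departures from quasi-steady-state kinetics, oxygen
diffusion limitation, or initiator transients — all deliberately out of
scope.

The structure–activity generator builds phenols from a combinatorial
grammar (phenol core; ortho/para substituents from alkyl, alkylthio and
chroman-like sets — echoing the chemical families the method targets) and
assigns logk₇ = offset + Σw·(MNA count) + N(0, σ), with support
descriptors of intermediate prevalence and weights scaled so the
noise-free activities span a configurable range (default 7.06 log-units,
matching the published training range; default σ = 0.3). Real
structure–activity data are of course not exactly linear in descriptor
counts; passing recovery tests therefore demonstrates correctness of
descriptors, selection, ensembling and validation plumbing — not that the
model family suffices for real antioxidant chemistry.

Problem sizes used in the tests and the acceptance script — 40–148
compounds, 10–20 partials, level-2 descriptors — were chosen as the
smallest sizes at which the consensus machinery behaves like its full-size
counterpart (stable Q², informative applicability domain).

## 6. Known limitations

* The second descriptor family is a deliberately minimal stand-in; it does
  not reproduce the quantitative atom-neighborhood descriptors of the
  original software, whose formulas are unpublished.
* Whole-molecule descriptor tables are crude element-additive defaults;
  they are pluggable and should be replaced for production use.
* The applicability-domain definition, the SCR internals and the
  systematic-error rules are surrogates chosen for transparent behaviour,
  as documented above.
* Kekulization by OpenBabel means aromatic perception differences between
  input formats can, in principle, alter hydrogen counts on exotic
  tautomers; the package does not attempt tautomer normalization.
* The AO2 rate table yields f·k₇ ≈ 1.0×10⁶ L mol⁻¹ s⁻¹ under the
  through-origin convention, somewhat below the published 1.08×10⁶ —
  consistent with unprinted digits in the underlying rates; the package
  reports what the printed table supports and does not adjust toward the
  published value.
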