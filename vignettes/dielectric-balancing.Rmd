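---
title: "Dielectric balancing: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dielectric balancing: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielbal)
```

## The model

A water-to-cyclohexane distribution coefficient is estimated from two
air-to-solvent transfer free energies,

$$\log P \;=\; \frac{\Delta G^\circ_{wat} - \Delta G^\circ_{cyh}}{2.303\,R\,T},$$

with each $\Delta G_{solv}$ assembled by thermodynamic integration as
the sum of two separated alchemical processes: growing the uncharged
solute into the solvent (nonpolar leg, $\Delta G_{solv,np}$) and then
switching on its charges (polar leg, $\Delta G_{solv,pol}$). The log P
of the single neutral species is reported as the log D estimate — no
tautomer, protonation or aggregation corrections are applied.

The workflow's distinguishing idea is *dielectric balance*: both the
solvent models and the solute force field should present static
dielectric constants close to the experimental environment. Common
fixed-charge solvents do not — TIP3P overshoots ($\epsilon(0) \approx
98$ against 78.4) and a fully nonpolar united-atom cyclohexane has
$\epsilon(0) = 1$ against 2.0 — which biases partitioning toward the
nonpolar phase for under-polarized solutes. The package therefore
carries (i) a registry of the four solvent models with these values,
(ii) an $\epsilon(0)$ estimator, and (iii) the solute modulation that
adapts a general force field to the corrected environment.

## The G-DB modulation

`apply_gdb()` magnifies every AM1-BCC partial charge by a factor 1.20
and inflates each atom's Lennard-Jones $\sigma$ by
$(5/12)\cdot|q_{new}-q_{old}|$ percent, leaving $\epsilon$, masses and
all bonded terms untouched. The inflation compensates the stronger
electrostatics so condensed-phase densities stay reasonable.

The percent-inflation rule admits two readings, and the package
implements both behind `modulation_spec(sigma_mode = ...)`:

* `per_atom_dq` (default): $|\Delta q|$ is the per-atom charge change
  in elementary-charge units. A charge moving from 0.5 to 0.6 e gives
  an inflation of $(5/12)\cdot 0.1 \approx 0.0417$ percent, i.e.
  $\sigma$ 0.3000000 → 0.3001250 nm. Per-atom inflations are tiny
  (< 0.1 %) but ordered by polarity.
* `uniform_percent`: the charge change is read as a percentage — 20 for
  the default scale — giving one multiplier
  $1 + (5/12)(0.20) \approx 1.0833$ for every atom.

We default to the literal per-atom reading because it is what the rule
states when $q$ carries its natural units; the uniform reading is kept
selectable since the printed rule does not fully determine the
convention. Whether hydrogens bonded to polar atoms should be excluded
from inflation is likewise not determinable from the protocol we
implement; we inflate every atom.

Two guard rails reflect deliberate choices. Scaling multiplies the net
charge, so non-neutral solutes are refused unless
`allow_net_charge = TRUE` — the workflow treats solutes as neutral
species. And a second `apply_gdb()` on an already-modulated topology
compounds the charge scaling to 1.44×, which is never a supported
protocol, so it warns.

### Topology handling

Only the `[atomtypes]`, `[moleculetype]` and `[atoms]` sections of the
GROMACS dialect are modeled (σ/ε in nm and kJ/mol; an optional second
stream may supply the atom types, as split GAFF topologies do). Every
other section — bonds, angles, dihedrals, pairs, exclusions — is
passed through byte-identically, which is itself the contract: the
modulation may only touch charges and σ. Charges are written with 6
decimal places and σ/ε with 7 significant figures, exceeding force
field file conventions so that a write/read round trip is the identity
within 1e-6; the write precision is a package choice, as the upstream
protocol does not state one. Because per-atom inflation can give atoms
of one atom type distinct σ values, the writer emits derived type
names (`_m1`, `_m2`, …) when needed to keep the output a legal file —
numeric fields round-trip exactly; type labels of modulated files may
gain suffixes.

## Thermodynamic integration

`integrate_ti()` applies the composite trapezoid rule over the λ
nodes. The λ grids are fixed inputs of the protocol: 17 points
(0.0 0.05 0.1 0.2 … 0.5 0.55 … 0.95 1.0) for the nonpolar leg and 6
evenly spaced points for the polar leg. The quadrature rule itself is
our choice — trapezoid is the field standard for uneven λ grids and is
exact for affine integrands on any valid schedule, which the tests
exploit as an oracle. On the 6-point polar grid a curved integrand
carries a visible discretization bias (about 2 % for a pure quadratic);
this is a property of the printed schedule, not of the implementation,
and the polar integrand is typically near-linear.

Window means come from `window_mean()`: the arithmetic mean of all
samples with a standard error from 5 contiguous block means
(`sd(blocks)/sqrt(n_blocks)`), the standard guard against serial
correlation in MD time series. Five blocks is a package default — the
upstream protocol does not state how window uncertainties were formed —
and the block stderr matches $\sigma/\sqrt{n}$ on uncorrelated data
within its own sampling noise. Window standard errors propagate
through the trapezoid weights in quadrature, legs add in quadrature,
and the two solvents' uncertainties combine in quadrature again on the
log P scale (also a package default; the submitted protocol does not
say how leg uncertainties were combined). An optional
`discard_fraction` drops a leading fraction of each window as
equilibration; it defaults to 0 because inputs are assumed
post-equilibration.

## Partition equation and its transforms

`log_partition()` uses the literal 2.303 denominator as conventionally
printed; `exact_ln10 = TRUE` switches to $\ln 10$, a 0.02 % difference
we expose rather than silently correct. The sign convention is
cyclohexane-over-water: favorable hydration gives negative log P.
Temperature defaults to 298.15 K, the protocol's thermostat setting,
with $R = 8.31446\times10^{-3}$ kJ/(mol K).

Two reference transforms support evaluation. `null_baseline()` maps
every solute to log D = 0 — the no-knowledge assumption that a solute
distributes equally between the phases. `scale_solvation(records, s)`
multiplies both phases' free energies by $s$, so log P scales exactly
by $s$; $s = 0.5$ is the retrospective "say-less" correction that
halves prediction magnitudes (useful when the experimental dynamic
range is narrowed by solvent mixing or solute-set pre-selection), and
$s = 0$ degenerates to the null baseline.

## Evaluation statistics

`evaluate()` reports MSE (signed, predicted − experimental), AUE,
RMSE, Pearson R, Kendall τ, the OLS line of predicted on experimental,
and both dynamic ranges. Choices where the convention was open:

* **Kendall variant**: τ-b (tie-corrected), since rounded log D data
  can tie; the implementation delegates to `stats::cor` and is checked
  against an independent $O(n^2)$ pair-enumeration oracle in the tests.
* **Correlation on degenerate input**: a zero-variance column (the
  null baseline) yields an explicit `NA` with a classed warning, never
  a fabricated 0.
* **Bootstrap**: case resampling of solutes with replacement, default
  10 000 resamples, reported as the standard deviation across
  resamples, fully determined by the seed. For 53 solutes with
  ~2.2-log-unit Gaussian errors this gives an MSE uncertainty near
  $2.2/\sqrt{53} \approx 0.30$ log D units, the resolution floor for
  comparing systematic biases at that set size.
* **Pearson R** is the direct sample correlation of (predicted,
  experimental), not a statistic of a fitted line's residuals.
* `error_profile()` orders by ascending experimental value with
  lexicographic solute-id tie-break for reproducible output.

## Dielectric estimation

`epsilon_from_dipoles()` uses the conducting-boundary fluctuation
formula

$$\epsilon(0) = 1 + \frac{\langle M^2\rangle - \langle M\rangle^2}
{3\,\epsilon_0 V k_B T},$$

consistent with Ewald electrostatics, with total dipoles in e·nm, the
volume in nm³ and $k_BT$ as $RT$ in kJ/mol, so $\epsilon_0$ is
expressed in $e^2\,\mathrm{mol\,kJ^{-1}\,nm^{-1}}$
(`dielbal_constants()` centralizes the conversions; 1 e·nm =
48.0321 D). The population (1/N) variance is used, matching the
ensemble-average definition. The estimate is exactly 1 for a
fluctuation-free series and never below 1. The optimization loop that
tunes a solvent model's dipole placement against ε(0), density and
$\Delta H_{vap}$ targets is deliberately not implemented — only the
property estimators such a calibration needs, including
`hvap_from_energies()` ($\Delta H_{vap} = U_{gas} - U_{liq} + RT$).

## What the synthetic generators emulate

The package is exercised entirely on synthetic data with known ground
truth: polynomial TI integrands with homoscedastic Gaussian noise,
prediction sets built as `bias + slope × experimental + noise` over
experimental values drawn uniformly on [−4, 3] (the measured spread of
the 53-compound water/cyclohexane set; the uniform shape is our choice,
as only the range is known), and isotropic Gaussian dipole series whose
per-axis variance inverts the fluctuation formula. Defaults emulate
the study conditions: 53 solutes, the printed λ schedules, 298.15 K,
and the exaggerated-slope/positive-bias error structure seen in
fixed-charge predictions.

What passing tests therefore demonstrate: the quadrature, propagation,
transfer equation, statistics and estimators are numerically correct
and internally consistent, and the pipeline recovers known answers
within its propagated uncertainties. What they cannot show: anything
about real MD gradients (serial correlation, non-Gaussian tails,
soft-core behavior near λ end points), real solute chemistry, or the
experimental error structure — reproducing the original headline
accuracies would require ~5 ns of MD per λ window for 53 solutes in
two solvents plus the external experimental log D set, none of which
desk-scale synthetic data can stand in for.

Problem sizes in the shipped tests and acceptance script are chosen to
make Monte-Carlo checks sharp but quick: 50-seed ensembles for
coverage statements (all recoveries within 4 combined σ, ≥ 80 % within
2 σ — chosen a priori from Gaussian order statistics), 10⁵ frames for
5 % dielectric recovery at both solvent targets, and a few hundred
bootstrap resamples where only the spread's scale is being verified.

## Known limitations

* The `.itp` subset is deliberately narrow: no pairs/exclusions
  semantics, virtual sites, multi-molecule system files or coordinate
  handling.
* TI only — no BAR/MBAR estimators, and no parsing of native `.xvg`
  dhdl output beyond the documented TSV layout.
* The dielectric estimator applies no finite-size or
  boundary-condition corrections beyond the stated formula, and the
  registry's model values are fixed constants, not recomputed.
* pKa/ionization and mutual-saturation corrections are out of scope;
  predictions are single-species neutral log P values.
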