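---
title: "Near-attack-conformation analysis of oxime reactivator poses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Near-attack-conformation analysis of oxime reactivator poses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nacscan)
```

## The scientific problem

Organophosphates (nerve agents, oxon pesticides such as paraoxon)
inactivate acetylcholinesterase (AChE) and butyrylcholinesterase (BChE) by
phosphylating the catalytic serine. Pyridinium aldoximes ("oximes",
e.g. pralidoxime, obidoxime, HI-6) can restore activity: their oximate
oxygen attacks the adduct phosphorus in line with the serine O-gamma,
displacing the enzyme. Whether a docking pose of an oxime is *productive*
is therefore a geometric question. A pose is called a **near attack
conformation (NAC)** when its attack distance is short enough and its
attack angle close enough to the in-line geometry:

- attack distance `d_OP` below 10 Å (strict `<`), and
- attack angle `θ_OPO` — the angle oxime-O – P – serine-O measured at the
  phosphorus — within 180° ± 60° (closed interval, i.e. θ ∈ [120°, 180°]).

For each reactivator, the fraction of *low-energy* docking poses at the
NAC (`%NAC`) is a cheap structure-derived predictor that can be compared
with the measured reactivation potency.

On the experimental side, potency is the fixed-time percent reactivation
from Ellman-assay activities,

%R = [1 − (a₀ − a_r)/(a₀ − a_i)] × 100,

with a₀ the intact activity, a_i the inhibited activity, and a_r the
activity after reactivation *minus the oximolysis control* (the oxime
itself slowly hydrolyses the thiocholine substrate, inflating a_r). The
package implements the geometric post-processing, the assay arithmetic,
and the correlation of `%NAC` with `%R`, together with synthetic-data
generators that make every stage testable with known ground truth.

## The NAC classifier and its parameters

`nac_criteria()` collects everything with a unit and a default:

| parameter | default | unit | meaning |
|---|---|---|---|
| `d_max` | 10.0 | Å | attack-distance cutoff (strict `<`) |
| `theta_center`, `theta_tol` | 180, 60 | degrees | closed angle window [120°, 180°] |
| `energy_window` | 5.0 | kcal/mol | "low-energy" = within this of the ensemble minimum; `"all"` disables |
| `distance_definition` | `p_to_serO` | — | which atom pair is `d_OP` (see below) |
| `denominator` | `low_energy` | — | `%NAC` = NAC / low-energy, or NAC∩low-energy / all |

Three of these defaults deserve comment, because the underlying
conventions are genuinely open:

**"Low-energy" poses.** Docking engines report many poses spanning a wide
energy range; restricting the NAC count to poses within a window of the
best score is standard practice, but the window width is a convention. We
default to 5 kcal/mol above the ensemble minimum, configurable, with the
sentinel `"all"`. Note the interaction with the denominator: shrinking the
window can only remove poses from both numerator and denominator, so the
reported `n_low_energy` is monotone in the window (a tested invariant).

**The distance definition.** Taken literally, `d_OP` is the distance from
the adduct phosphorus to the serine O-gamma — but in a covalent
phosphyl-serine adduct that distance is a *constant* of the receptor
(about 1.6 Å), while published per-pose values vary by several Å per
reactivator. The quantity that actually varies pose by pose is the
distance from the attacking oxime oxygen to the phosphorus. We keep the
literal definition as the package default (`p_to_serO`) and expose
`oximeO_to_p` as a configurable alternative rather than guessing intent.
The synthetic generator, which must produce per-pose distance variation to
be useful, defines its ground truth under `generator_criteria()` —
the default thresholds with `distance_definition = "oximeO_to_p"` — and
returns those criteria alongside each ensemble so downstream calls agree
with the construction.

**Boundary conventions.** The distance test is strict (`d = d_max`
fails) and the angle window closed (`θ = 120.0°` passes). Because poses
built or measured through trigonometric round-trips land within machine
precision of a boundary rather than on it, the classifier applies the
comparisons with a 1e-9 guard: a value within 1e-9 of a threshold is
treated as sitting on it. This is a numerical tie-break, not a chemistry
statement.

For bis-oximes (two oxime oxygens declared in `oxime_spec()`), the
geometry is evaluated for each oxygen and the pose record keeps the oxygen
maximizing θ among those passing the distance test (else the nearest
one). A pose is then NAC exactly when *either* oxygen qualifies, which
formalizes the intuition that a symmetric bis-oxime doubles its chances of
presenting an attack-competent oxygen — and yields the tested invariant
that the bis-oxime `%NAC` is never below either single-oxygen `%NAC`.

**Best-pose selection** uses a lexicographic rule inside the low-energy
set: minimal `d_OP`, then maximal `θ_OPO`, then minimal total energy. The
multi-criteria rule is not standardized anywhere; the down-distance /
up-angle ordering follows the reporting convention of docking tables that
annotate best poses with `↓d / ↑θ` arrows, and energy is the final
tie-break because it already gated the candidate set.

**Redocking validation** (`validate_redock()`) uses the conventional
acceptance threshold: unfitted RMSD strictly under 2.0 Å between the
crystallographic ligand and its redocked copy. The RMSD is positional
(atom *i* to atom *i*), with no superposition — docking output shares the
receptor frame — and no symmetry-equivalent atom search; for redocking the
topology is identical by construction, but users comparing chemically
symmetric ligands from different sources should be aware of the
limitation.

## The assay arithmetic

`percent_reactivation()` evaluates the %R formula exactly, after
subtracting the oximolysis control from the raw reactivated activity, and
never clamps: values below 0 or above 100 (which genuinely occur under
replicate noise when the true value is near the ends of the scale) pass
through flagged. Clamping would bias the replicate mean toward the
interior of the scale and break the unbiasedness properties the tests
rely on; the reporting layer can always clamp for display.

Replicate summaries use the arithmetic mean and the *sample* SD (n − 1),
the convention matching published triplicate tables; with one replicate
the SD is reported as 0 and flagged. Activities can be supplied directly
or as time–absorbance traces, in which case the activity is the OLS slope
over a fixed, user-configurable window (default: the whole trace) — no
automatic linear-range detection, so results are deterministic in the
input.

Inhibition timing follows pseudo-first-order kinetics:
`fit_half_life()` regresses ln(a(t)/a(0)) on t and reports
k_obs, the half-life ln 2 / k_obs, and the fit's R². `inhibition_time()`
converts a half-life into an incubation time as n × T₁/₂ with the residual
active fraction 2⁻ⁿ; with the default n = 7 a half-life of 120/7 min gives
the conventional 2-hour incubation with under 1% residual activity.

## The correlation stage

`correlate_nac_reactivation()` pairs per-oxime `%NAC` with the measured
`%R` of a chosen concentration and reports the OLS line and Pearson r.
Because a typical reactivator panel has n ≈ 6, asymptotic p-values are
meaningless; `permutation_pvalue()` tests |r| two-sided against the
permutation null, enumerating all n! pairings exactly when n! ≤ 5040
(deterministic, order-invariant) and falling back to a seeded Monte-Carlo
sample with the add-one correction beyond that. Which concentration's %R
enters the correlation defaults to the 100 µM column — the higher-signal
choice — and is configurable.

## What the synthetic generators emulate — and what they do not

The generators exist so that every pipeline stage can be tested against
ground truth known *by construction*, without docking software or
wet-lab data.

`generate_pose_ensemble()` places the adduct phosphorus at the origin and
the serine O-gamma 1.6 Å away (a covalent P–O bond length), then builds
each pose by sampling an attack distance and angle for the oxime oxygen
(random azimuth) and attaching a rigid 5-atom dummy ligand in a random
orientation. Defaults emulate one docking run: 100 poses, distances
uniform over 3–14 Å, angles uniform over 90–180°, and a *flat* energy
landscape — with equal energies every pose is low-energy, so the realized
NAC fraction is controlled purely by geometry, which is what makes exact
ground-truth injection possible. When `nac_fraction_target` is set,
`round(n × target)` poses are sampled comfortably inside the window and
the rest are placed with every ligand atom beyond the cutoff, so the
realized fraction is exact. The generator does **not** emulate: physically
realistic conformers, force-field energies, receptor flexibility, the
clustering of poses around minima, or any coupling between pose energy
and geometry. Passing tests therefore demonstrate that the *bookkeeping*
(classification, counting, selection, I/O) is correct, not that the NAC
statistic predicts reactivation for real enzymes.

`generate_assay_scenario()` inverts the %R formula: given a true %R it
sets a_i = 0.05 × a₀ (enzymes inhibited to 5% of original activity),
solves for a_r, adds the oximolysis rate back into the raw reading, and
emits per-replicate activities (or noiseless linear traces with those
slopes) under multiplicative Gaussian noise. The defaults — a₀ = 1,
inhibited fraction 0.05, oximolysis rate 0.02, noise CV 2%, 3 replicates —
reflect the small replicate SDs typical of published triplicate
reactivation tables. Because %R is a ratio of noisy quantities the
recovered mean is not exactly unbiased, but at CV 2% the bias is far
below the Monte-Carlo resolution of the tests (a 300-seed unbiasedness
check at 3× the MC standard error passes with margin).

The shipped benchmark (`reactivation_fixture_table()`, 24 rows: six
oximes × two enzymes × two concentrations) parameterizes these scenarios
with realistic potency values, including the hallmark pattern that
obidoxime far outperforms all other reactivators against
paraoxon-inhibited AChE while nothing reactivates BChE beyond ~10%.

`write_demo_inputs()` assembles a full synthetic study. The AChE-like
scenario injects `%NAC = 2 + 0.8 × %R` (a monotone map of the benchmark
potencies), while the BChE-like scenario uses fixed NAC fractions
(20, 20, 24, 17, 27, 12%) chosen in advance to have near-zero sample
correlation with its potency column. The end-to-end expectation — a
significant AChE correlation, a non-significant BChE one — therefore
holds by construction and tests the pipeline's ability to *detect* the
contrast, not any scientific claim about BChE.

## Problem sizes and reproducibility

Every generator consumes a single scenario seed from which all draws
derive, and is bit-reproducible under that seed. Exact permutation
p-values are deterministic; Monte-Carlo p-values are reproducible under a
fixed seed. The test suite uses ensembles of up to 200 poses, 100-ensemble
oracle sweeps, 300-seed unbiasedness checks, and 200-seed Monte-Carlo SE
estimates — sizes at which the Monte-Carlo error of every stochastic check
is comfortably below its tolerance while the whole suite runs in well
under a minute.

## Known limitations

- The `%NAC` statistic consumes poses; it never generates them. Scoring
  functions, search algorithms, and receptor preparation are out of scope.
- Interaction fingerprints (H-bond or π–π residue lists) are reported
  pass-through if supplied; they are never computed from coordinates.
- RMSD is positional, not symmetry-aware.
- No reactivation rate constants (k₂, K_D) are estimated — only fixed-time
  %R, which is what the correlation uses.
- The pose-PDB dialect (per-model `REMARK 250 ENERGY_*` records) is
  package-defined; standard multi-model PDB and SDF with energy tags are
  read, but arbitrary docking-engine outputs may need a sidecar energy
  CSV.
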