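---
title: "The uterosim model: pressure-tension synchronization of regional uterine contractions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The uterosim model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uterosim)
```

## The model

Labor requires a kilogram of myometrium to contract as one organ, yet no
stable pacemaker or organ-spanning action potential has ever been observed in
the human uterus. `uterosim` implements a mechanistic answer: tissue-level
action potentials recruit muscle only over a bounded distance, which
partitions the uterine wall into **regions** — patches of roughly
8 cm × 8 cm that one propagating burst can recruit completely. Regions do not
signal each other electrically. They are coupled *hydraulically*: the uterus
is a fluid-filled pressure vessel, so any regional contraction raises the
intrauterine pressure everywhere at once, and rising pressure raises wall
tension everywhere at once (Law of Laplace, $T = P\,r/w$). Tension above a
regional excitation threshold triggers a stretch-initiated action-potential
burst — the myometrial myogenic response — which contracts that region and
raises pressure further. The positive feedback recruits region after region,
independent of physical adjacency, until the organ contracts as a whole.

The simulator is a cellular automaton whose cells are these regions,
deliberately *not* neighbor-coupled: every region interacts with every other
only through the shared scalar pressure. Three rules advance the system, with
$s_{ij}$ the per-region anatomy-sensitivity factor (the local $r/w$ of the
Laplace relation), $\theta_{ij}$ the per-region action-potential threshold,
$a_{ij}(t)$ the regional contractile activity, and $N$ the number of regions:

1. **Pressure from activity.** Hydraulic equilibration is effectively
   instantaneous on the ~5 s step of the model, so
   $P(t) = \max\!\left(P_{\min},\; \tfrac{1}{N}\sum_{ij} a_{ij}(t)/s_{ij}\right)$.
   The floor $P_{\min}$ is the baseline tone the uterus never drops below.
2. **Tension from pressure.** Each region's passive tension is
   $\tau_{ij}(t) = P(t)\, s_{ij}$.
3. **Activity from tension.** Each region runs a three-phase machine.
   A quiescent region ignites when $\tau_{ij} > \theta_{ij}$ (strictly; a tie
   does not ignite). A bursting region multiplies its passive tension by the
   action-potential multiplier $m_b > 1$ and keeps bursting while its
   amplified activity stays at or above threshold, for at most the burst
   duration; it then turns refractory, multiplying passive tension by the
   refractory multiplier $m_r \in (0,1)$ for exactly the refractory duration,
   after which it is quiescent for one step before it may re-ignite.
   Activities are clipped to $[0, 10]$.

Everything the model produces — coordinated labor-like contraction trains,
shifting pacemakers, dose-dependent drug responses, region-count effects —
is emergent from these three rules plus heterogeneity in $s_{ij}$ and
$\theta_{ij}$.

## Parameters and defaults

| Parameter | Units | Default | Why |
|---|---|---|---|
| `rows`, `columns` | regions | preset-dependent, product 1–64 | the physiological estimate is ~20–30 regions for the term uterus; 1 and 2 emulate muscle-bath strips |
| `timesteps` | steps (~5 s each) | 300 | ~25 min of labor; enough for ~10 contraction cycles |
| `initial_pressure` | activity units | 0.5 | start at baseline; raising it (e.g. to 1) probes memory of prior conditions |
| `min_pressure` | activity units | 0.5 | resting intrauterine pressure is ~15 torr against a ~300 torr maximum, i.e. 1/20 of the 0–10 activity scale |
| `burst_duration` | steps | 10 | electrical bursts last 50–60 s in human myometrial strips; 10–12 steps of ~5 s |
| `refractory_duration` | steps | 20 | sets the rest interval between a region's bursts |
| `ap_multiplier` $m_b$ | — | 3 | burst force relative to passive tension; lowered to emulate nifedipine, raised for oxytocin |
| `refractory_multiplier` $m_r$ | — | 0.2 | post-burst hypo-responsiveness |
| `anatomy_weibull` | — | shape 1.8, scale 1, location 0.3 | right-skewed $s_{ij}$ concentrated near 1 and essentially confined to the anatomically motivated 1/4–3 band |
| `threshold_weibull` | — | shape 4, scale 0.6, location 0.4 | near-symmetric thresholds with mean ≈ 0.95, straddled by achievable passive tensions |
| `activity_cap` | activity units | 10 | the 0–10 activity scale; also the saturation that bounds peak pressures (see below) |

Fourteen **presets** (`preset_input_set()`, `preset_config()`) collect the
published parameterizations: the 4×4 default and its tocolytic series
(1–3), the 5×5 uterotonic dose series (4–7), a 5×5 midrange set (8),
single-strip analogs differing only in baseline pressure (9–10), paired
two-strip analogs (11–13), and a sweep template with a free grid (14).
Configurations serialize to the compact descriptor string
(`format_descriptor()` / `parse_descriptor()`), e.g.
`"1.S1000:1.8/1/0.3;S2000:4/0.6/0.4"`: preset head, anatomy seed and Weibull
triple, threshold seed and Weibull triple. A nine-value long-form head
carries arbitrary scalar settings. Seeds in 1000–1999 (anatomy) and
2000–2999 (threshold) are a bookkeeping convention; values outside warn but
are accepted.

## Design choices where the rules are underdetermined

The formal update equations are circular as stated — the burst factor at
$t{+}1$ depends on the activity at $t{+}1$, which contains that factor. The
engine resolves this by deciding phases from the *passive* tension
$P(t)\,s_{ij}$ (ignition) and the *amplified* tension $m_b\,\tau_{ij}$
(continuation), then computing activity. Other commitments, each exposed in
the documentation and frozen (no toggles):

* **Saturation.** Without a ceiling, a single bursting region's activity
  grows without bound ($m_b > 1$ feeds back through pressure). Activities are
  clipped to `[0, activity_cap]`; with the default cap of 10 this is what
  makes fully recruited contractions peak at $10 \cdot
  \overline{1/s_{ij}}$, i.e. roughly 8–12 depending on the anatomy draw.
* **Floor placement.** `min_pressure` floors the organ-level pressure after
  Rule 1, not per-region activity: baseline tone is an organ property, and
  the bistability of the single-strip experiment (below) requires the floor
  to feed back through passive tension.
* **Timing.** A completed burst lasts at most `burst_duration` steps; the
  refractory period lasts exactly `refractory_duration` steps; one quiescent
  step follows before re-ignition. A solitary self-exciting strip therefore
  fires with period `burst + refractory + 1` (31 steps for preset 9), which
  the canonical-run test pins down step by step.
* **Determinism.** Given a configuration and fields, a run is bit-identical
  on replay; all stochasticity lives in the seeded field sampling.

The single-strip presets make the floor's role exact: with anatomy ≈ 1 and
threshold 0.558, a baseline of 0.6 (passive tension 0.595 > 0.558) yields
repetitive contractions forever, while a baseline of 0.55 (passive 0.545 <
0.558) yields exactly one contraction — driven by the initial pressure of
1 — and then permanent rest. Baseline pressure, not excitability alone,
decides whether labor-like oscillations exist.

## What the heterogeneity generator emulates — and what it does not

The two per-region matrices are drawn once per run from three-parameter
Weibull distributions, `location + scale * rweibull(shape)`, filled
row-major under a locally scoped seed (`sample_weibull_matrix()`). The
anatomy distribution emulates the spread of local curvature-to-thickness
ratios of a term uterus (skewed, mostly near 1, essentially within 1/4–3);
the threshold distribution emulates unknown regional excitability. Neither
is estimated from tissue data — no such measurements exist yet — so passing
tests demonstrate behavior *under these assumed heterogeneity laws*, not
distributional realism. The seeds index this package's Mersenne-Twister
streams; matrices behind specific published figures came from a different
generator and are not bit-reproducible here. Where printed per-region values
exist (single-strip 0.991/0.558; paired strips 0.986, 0.989 / 0.428, 0.670)
they are injected directly as synthetic fixtures (`single_strip_fields()`,
`two_strip_fields()`), and `region_fields()` / `read_fields_csv()` accept
arbitrary explicit matrices.

## Trace metrics

* **Contraction detection** (`detect_contractions()`): maximal runs with
  pressure at or above `floor + 0.5 * (max − floor)`, after discarding a
  20-step transient so the initial-condition pulse never counts as a
  contraction. The relative level counts plateau-shaped contractions once
  and makes the count invariant under uniform rescaling; both knobs are
  exposed.
* **Pseudo-Montevideo units** (`pseudo_montevideo()`): mean per-event peak ×
  event count, normalized to a 300-step window. The mean-of-peaks reading
  (rather than the single global peak) is deliberate: it is robust to one
  outlier contraction; the choice is fixed and documented.
* **Pacemakers** (`identify_pacemaker()`): per contraction, the first region
  whose burst begins after the previous contraction and persists into the
  rising phase; ties go to the higher total sensitivity
  (anatomy ÷ threshold). The run-level dominant region is the one with the
  most burst onsets — the highest-frequency firing site, which is how a
  pacemaker would be sought experimentally. On midrange 5×5 settings the
  per-contraction pacemaker shifts between regions within a single run: pace
  making is emergent, not anatomically fixed.
* **Behavior classes** (`classify_behavior()`): an input-based four-class
  scheme. Class 1, post-transient pressure constant; class 2, ≥ 3
  contractions with inter-onset coefficient of variation < 5%; class 4, ≥ 3
  contractions with CV ≥ 5%; class 3, the remainder (sustained disorganized
  fluctuation — a fallback bucket: no input set producing it is known, so
  the rule is untested against any reference). The 5% CV boundary
  operationalizes "slight variation of the interval" and is a parameter.
  Physiological-relevance modifiers (normal / pathological / never observed)
  are judgement, not computation, and exist only as a free-text annotation.
* An **organ-level** contraction, where one is needed operationally (drug
  sweeps, peak-pressure summaries), is an event with peak pressure ≥ 5 —
  half the activity ceiling — or, for run gating, a step where ≥ 75% of
  regions burst simultaneously.

## Scenario studies and the problem sizes used

The test suite and `scripts/acceptance.R` re-run the in-silico experiments
at these sizes, chosen as the package's own study conditions:

* **Default labor pattern:** preset 1 over panels of 10–20 paired seeds.
  Most seeds give 7–9 contractions with interval CV well above 5%
  (class 4); organ-level peaks fall within 7–13, consistent with the 8–12
  band implied by the activity cap and the anatomy distribution.
* **Tocolytic paradox:** scanning a systematic grid of anatomy × threshold
  seed pairs (50 × 20, early-stopped) for a pair where multiplier 3 gives
  ≥ 3 organ-level contractions, 2 gives none, and 1.5 gives ≥ 2. The paradox
  is a rare-seed phenomenon under this generator — roughly 1 in 400
  independent pairs — which is why an enumerated panel of hundreds, not tens,
  is scanned. Notably, among seed pairs with equal offsets
  (1000+s, 2000+s) the multiplier-2 failures we examined are all sensitivity
  failures dead at *every* multiplier, so independent pairing matters.
* **Uterotonic dose series:** preset 4 fields, multipliers 1.5 → 2 → 4 → 8;
  force and event counts rise and then saturate.
* **Region-count sweep:** preset 14 across 23 grids spanning 4–64 regions,
  aggregated over 5 seed offsets. The mean pMV profile rises from zero
  (sensitivity failure at few regions), dips in the mid-to-high tens of
  regions (synchronization failure), and recovers toward 64 — detected as an
  interior dip at least 5% below both the preceding peak and a later
  recovery value.

## Known limitations

* **Paired-strip alternation is not reproduced.** Experimentally, two
  mechanically linked myometrial strips can contract in alternation, and the
  published two-strip scenario expects near-zero burst overlap at the
  long-refractory, low-pressure timing (preset 11) versus high overlap at
  presets 12–13. Under this engine's synchronous update the preset-11
  fixture instead phase-locks with a one-step lag (overlap ≈ 0.36): once the
  low-threshold strip bursts, pressure reaches ~1 within one step, which
  recruits the high-threshold strip whenever it is excitable — and that
  strip can never oscillate unaided at the 0.5 floor, so no sustained
  alternating orbit exists. We verified this analytically (the period-25
  orbit is exact) and under the alternative update orderings the formal
  rules admit; reproducing alternation evidently requires mechanisms beyond
  the three rules as stated (e.g. tension-release-initiated contraction or
  asynchronous updates). The corresponding acceptance expectation is left
  failing rather than redefined; presets 12–13 do show the expected strongly
  coupled, high-overlap regimes.
* The engine is unitless in time; the ~5 s step and ~25-minute horizon are
  interpretive metadata.
* No intra-regional electrophysiology: a region is all-or-none by
  construction, and propagation speed enters only through the geometry
  module's recruitment-time bound.
* The Laplace treatment is thin-walled and static; no viscoelastic
  transients during pressure equilibration.
* Class-3 behavior and the physiological-relevance modifiers are defined but
  have no computable reference.
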