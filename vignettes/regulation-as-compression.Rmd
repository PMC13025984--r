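---
title: "Regulation as compression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regulation as compression: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(algoreg)
```

This vignette explains the model behind `algoreg`, the numerical and design
choices it pins down, and what its synthetic test beds do and do not show
about real systems.

## 1. The model

A **world** and a **regulator** are deterministic causal finite transducers
that exchange symbols over interface streams for a fixed horizon `N`
(`run_episode()`). Each machine is identified with its canonical
self-delimiting binary code (`encode_program()`), whose length in bits
stands in for the length of a minimal program. The world's output stream is
the **readout**; coupling the world to the all-zero `null_regulator()`
instead gives the **OFF** baseline readout.

Regulation is scored by description length. Writing `a = K(x_on)` and
`b = K(x_off)` for the prefix complexities of the two readouts, the
regulator is *good* when the contrast gap `Δ = b − a` is positive. The
framework's central results, verified exactly by this package inside
enumerated universes, are:

1. **Posterior form.** Under the prefix prior `2^{−|p|}` with a
   deterministic likelihood, the posterior over programs that print `x` is
   exactly `2^{−|p|}/m(x)` (`posterior_given_x()`).
2. **Contrastive tilt.** Explanations `(W, R)` of a readout with gap `Δ`
   obey `posterior ≤ C · 2^{M̂} · 2^{−Δ}` where `M̂` is the pair's mutual
   algorithmic information; each bit by which `M̂` falls short of `Δ` costs
   a factor of two (`verify_theorem2()`, `posterior_envelope()`).
3. **Geometric tails.** The posterior mass of explanations longer than
   `K(x) + k` bits, and of explanations with `M̂ ≤ Δ − k`, both decay
   geometrically in `k` (`tail_curves()`).
4. **Bayes-factor identity.** The ON-vs-OFF universal evidence
   `log2 m(x_on)/m(x_off)` equals the complexity gap `K(x_off) − K(x_on)`
   up to the universe's measured coding-gap constant (`bayes_factor()`).

Because true `K` and `m` are uncomputable, every quantitative claim is made
on one of two tracks: *practical estimators* (upper-bound codelengths) for
empirical data, and *exact micro universes* in which all quantities are
computed by exhaustive enumeration with integer mass arithmetic, so the
theorems can be checked without any asymptotic hand-waving. The machine
constants (`C`, the coding gaps) are machine-dependent in the theory; the
package *measures* them for its universes rather than asserting values.

## 2. Episode semantics

The coupled dynamics are a mutual fixed point over streams; we implement
the minimal causal semantics that makes the solution exist and be unique
for every machine pair: both machines emit a declared `initial_emission` at
`t = 1`, and at each later step a machine reads its partner's previous
emission, emits `emission(state, input)`, and moves to
`transition(state, input)`. Emissions at step `t` therefore depend only on
symbols received before `t` (verified as a property test by truncation).
The `initial_emission` field resolves the bootstrapping that a synchronous
coupling otherwise leaves open.

## 3. Codelength estimators

**LZ76.** `lz76_complexity()` computes the 1976 exhaustive production
history: phrases are the shortest extensions not reproducible (as a
substring, with overlap) from the preceding history, with the terminal
phrase counted even when reproducible. The suite validates the compiled
parser against a direct quadratic implementation. The codelength charges
each phrase a pointer into the `n`-symbol window plus one literal symbol:

```
L(s) = c(s) · (log2 n + log2 A) + γ(n) + γ(A)   bits,
```

with `γ` the Elias-gamma code lengths of the header. This is the
normalisation for which `c(s)·log2 n / n` converges to the entropy rate of
a stationary ergodic source; at `n = 10^5` the measured rate sits within
0.08 bits/symbol of the fair-coin entropy and within 0.03 of the
Bernoulli(0.1) entropy. A per-phrase charge of `log2 c` instead of
`log2 n` systematically undershoots the entropy rate at these lengths
(≈0.83 bits/symbol on fair-coin data), which is why the window-pointer
form is the package's choice.

**BDM.** `bdm_codelength()` tiles a string into non-overlapping blocks and
charges `Σ_i K_CTM(b_i) + log2 m_i` over distinct blocks with
multiplicities `m_i`, with `K_CTM` looked up in an exactly enumerated
`universe_table`. The multiplicity penalty is base-2, consistent with all
other bit counts. A trailing partial block is charged literally at
`log2 A` bits per symbol plus a one-bit flag; when the string tiles
exactly, no flag is charged, so a single native-size block scores exactly
`K_CTM`. Boundary effects of the tiling are a documented estimator bias.

**Codecs.** `codec_codelength()` scores `8 ×` the compressed byte length
under a registered codec (gzip, bzip2, xz via `memCompress()`), with
symbols serialised one per byte. Whatever estimator is chosen, the same
configuration scores every condition of a contrast — the `delta_gap()` and
`scan_membranes()` interfaces make a mismatch impossible by construction.

**Quantisation.** Real-valued readouts are discretised by a fixed,
reported uniform quantiser (`quantization_spec()`): out-of-range values
clip to the extreme cells. The package default is 8 cells over [−4, 4]
signal units.

## 4. The exact universes

**String universe.** `enumerate_universe()` enumerates every program of a
three-branch codebook: a *literal* branch (any string, fixed width), a
*repeat* branch (a motif cycled to length `n`), and a *generator* branch
(a canonical transducer code free-running on zero input). Each program is
prefixed by the Elias-gamma output length and by a unary no-op prologue
`1^j 0`. The prologue deserves a note: on a genuine universal machine every
behaviour is realised by programs of every sufficiently large length, and
the geometric excess-length tail of the posterior rests on that density. A
finite transducer codebook alone has a sparse length spectrum; the
prologue restores the density while preserving each base program's total
prior mass exactly (`Σ_j 2^{−(b+1+j)} = 2^{−b}`). Masses are accumulated
as integer counts of `2^{−L}` units, so the Kraft sum and all posterior
identities are exact. With the default bound `L = 22` and output length 8,
the table covers all 510 binary strings up to length 8 — total by
construction, which is what the BDM lookup requires — with a measured
coding gap between 0.98 and 2.2 bits.

The step cap classifies any program needing more emission steps than the
budget as non-halting; enlarging the cap (or `L`) only adds programs, so
masses weakly increase and complexities weakly decrease (tested).

**Pair universe.** `build_pair_universe()` enumerates world–regulator
pairs of binary-interface transducers. The joint code is
`prologue | flag | code(W) [code(R)]`: flag 1 declares the regulator a
copy of the world, so identical pairs are describable in roughly half the
bits — the crudest shared-structure facility a code can have. In-universe
mutual information is `M̂ = |W| + |R| − K(W,R)`: `|W| − 2` for identical
pairs, `−2` (the flag-plus-prologue overhead, reported rather than
clamped) for unrelated ones. Per-pair contrast gaps use the universe's own
exact `k_exact` on the pair's ON and OFF readouts, keeping every term of
the tilt bound inside one measured machine.

The default universe uses memoryless (one-state) machines with
`L_pair = 30` and `N = 8`: 64 pairs, 14 distinct readouts. This is a
deliberate choice of the smallest closed universe in which posterior mass
is dominated by minimal explanations — the regime the theory speaks to.
Admitting two-state machines multiplies the enumeration by ~10^4 and, more
importantly, floods simple readouts with behaviourally trivial long
explanations (hundreds of distinct machines that all "do nothing"); the
coding gap then grows to several bits and the excess-length tail acquires
a flat shoulder inside the first six bits. That regime is still available
through `max_states = 2` and is scientifically interesting — it shows how
machine constants degrade with codebook redundancy — but it is not the
default verification ground.

**Tail-slope conventions.** Fitted tail slopes are least squares on
`log2 tail(k)`, `k = 0..5`. Exact zeros following positive values are
floored at half the universe's mass resolution (they witness decay *below*
the resolution); a tail that is identically zero decays faster than any
geometric rate and reports slope `−Inf` (the bound holds vacuously). These
conventions matter only because the universes are exact and small: real
tails hit true zero.

**Default readout suite.** Theorem checks run over the 12 most
compressible distinct ON readouts (ties: larger mass, then lexicographic).
The tilt results are informative exactly when the observed readout is
simple — for a complex readout the posterior constraints are weak — so the
suite deliberately samples the informative regime.

## 5. The thermostat test bed

`thermostat_episode()` simulates
`T[t+1] = T[t] + retention·(T_out[t] − T[t]) + u[t]·power` with a
bang-bang-with-hysteresis controller, heater-off null, or a
world-independent fair-coin emitter as a negative control; outdoor
temperature is a slow sinusoid plus AR(1) weather noise, shared across
modes at a given seed so contrasts are paired.

Default parameters model a well-insulated room on a fine time grid:
retention 0.001 per step (time constant ≈ 1000 steps), heater power 0.006
degrees/step (full duty lifts the room ~6 degrees above outdoor
equilibrium), setpoint 21, outdoor mean 18 with amplitude 1.0 (period 400)
and AR(0.9) noise of innovation sd 0.3, horizon 2000, sensor quantiser 8
cells over [−4, 4] degrees. The controller holds a ±0.3-degree band around
`setpoint + 0.5` — half a sensor cell above the reporting threshold — so a
functioning thermostat reports an essentially constant error symbol while
the free-running room wanders across sensor cells with the weather. Two
consequences worth making explicit:

* the ON/OFF gap is positive in every episode because the OFF readout
  inherits the weather's variability while the ON readout is clamped
  inside one cell;
* the fair-coin emitter's heat input, low-pass filtered by the slow house,
  produces sub-cell dither (sd ≈ 0.1 degrees), so its gap median stays
  within the LZ76 header slack (`lz76_header_slack()`, 28 bits at these
  settings) of zero: an unregulated but heated room is no more and no less
  compressible than an unheated one at sensor resolution.

These parameters were fixed at design time by simulating the physics, not
tuned against test outcomes; they are configurable, and the qualitative
contract (clamped ON, wandering OFF, null-like random control) is what the
tests assert.

A finite-state rendition of the same loop (`thermostat_world_spec()` and
`bang_bang_spec()`) exercises the transducer machinery: the coupled pair
settles into a limit cycle of period at least 2 ramping between the two
hysteresis thresholds.

## 6. Membrane scanning in Game of Life

`scan_membranes()` operationalises agency detection: a candidate membrane
is a rectangular window; its interface stream is the window-perimeter cell
states concatenated over time (perimeter only — the membrane's
input/output traffic, not the interior state); candidates are ranked by
the gap `Δ̂ = mean_d L(ablated_d) − L(actual)` under a fixed estimator.

The default null re-evolves the grid after a *density-preserving random
permutation* of the window's interior at `t = 0`, averaged over 8 draws
with a per-candidate RNG substream (duplicate candidates therefore tie
exactly, and a fixed seed fixes the ranking). Permutation rather than
fresh Bernoulli noise matters: it leaves an empty window's history — and
an all-dead grid — exactly unchanged, so unstructured regions score
exactly zero rather than being penalised for the null's own injected
entropy. A time-shuffle of the readout frames is available as a weaker
surrogate that needs no re-simulation.

The canonical fixture (`life_fixture_blinker_noise()`) places a small
stable colony — a blinker flanked by four still-life blocks, ~20 live
cells — in one quadrant and an i.i.d. soup block in the other. The colony
maintains a silent membrane; scattering its cells by ablation yields a
~0.23-density soup that reliably boils over the window perimeter, so the
colony window's gap is large (hundreds of bits) while the soup window —
whose interior is already unstructured — fluctuates near zero. A lone
three-cell blinker is too sparse for this contrast: its scattered cells
almost always die out, leaving a zero gap indistinguishable from noise;
the flanking still lifes are what make the ablation contrast decisive.
The ranking breaks ties toward smaller windows, then row-major position.

## 7. Inference conventions

Per-episode gaps are tested with a paired sign-flip permutation test on
the mean gap (`paired_permutation_test()`), the natural exchangeability
argument when the null is "no systematic ON/OFF asymmetry". The
Monte-Carlo p-value uses the add-one rule
`(1 + #{permuted ≥ observed}) / (n_permutations + 1)`, which is valid at
any permutation count; an exact variant enumerates all `2^n` sign
patterns. Under a symmetric null the exact p-value is (sub)uniform on its
lattice; the suite checks this by simulation.

`ncd()` follows the printed one-sided concatenation order (x then y); the
symmetrised minimum over both orders is an option, not the default.
`mutual_info_estimate()` concatenates with a reserved out-of-alphabet
separator so the joint codelength is well defined; negative estimates are
reported with a codec-imperfection flag rather than clamped, since they
diagnose estimator failure, not negative information.

## 8. Scale choices and limitations

Problem sizes used throughout (string universe `L = 22` / outputs to
length 8; pair universe 64 pairs at `N = 8`; thermostat `N = 2000` over 20
episodes; Life grids 64×64 over 128 steps; entropy-rate checks at
`n = 10^5`) are the package's desk-scale defaults: large enough for every
property the suite asserts, small enough to re-verify exhaustively.

What the synthetic beds do **not** show: the estimators' behaviour on
real, noisy, non-stationary sensor data (the worlds here are deterministic
by design, as in the underlying theory); the tilt theorems for universal
(Turing-complete) machines — the universes are finite-transducer
miniatures whose constants are measured, not the theory's `O(1)`s; and any
claim that a positive membrane gap detects "true agency" — it detects
compressible structure maintained behind a boundary, nothing more.
Codelength gaps are upper-bound surrogates: a positive `Δ̂` is evidence,
but a zero `Δ̂` under one estimator never proves the absence of structure
another code could expose.
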