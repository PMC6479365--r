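---
title: "Membrane-computing edge detection: model, semantics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane-computing edge detection: model, semantics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edenp)
```

## 1. The computational model

An enzymatic numerical P system (ENPS) is a cell-like membrane system
`Π = (m, H, μ, Var_1, E_1, Pr_1, Var_1(0), …)`: a rooted tree of membranes
(`μ`, with the *skin* at the root), per-membrane sets of real-valued
variables with initial values, a subset of variables flagged as *enzymes*,
and per-membrane programs. A program

```
F(y1, …, yk) |e  →  c1|v1 + c2|v2 + … + cn|vn
```

evaluates its **production function** `F` on the current values and
distributes the result among the targets `v` in proportion to the
non-negative **repartition coefficients**: `v_k` receives `F · c_k / Σc`.
The enzyme `e`, when present, gates the rule: it may fire only if the value
of `e` compares favourably with `min(y1, …, yk)`. All applicable programs
of the active membranes fire in the same step, reading the pre-step
configuration simultaneously.

The engine (`enps_system()`, `enps_step()`, `enps_run()`) implements
exactly this, plus the policy switches described next.

## 2. Semantic choices the formal definition leaves open

The formal model under-determines several points; the engine makes each of
them an explicit, testable policy. These are the package's own readings,
chosen so that the staged edge-detection construction behaves as described
in Section 4.

**Enzyme comparison: `>` or `≥`.** The textbook definition of the gating
condition is strict (`e > min(y)`), but the edge-detection construction
only works with the non-strict form: the decision rule for pixel `(i, j)`
must fire when `E_ij = d_ij = 0`, because a difference of exactly zero is
defined to be an edge. The comparison is therefore a per-program setting
(`comparison = "ge"` or `"gt"`), defaulting to non-strict.

**Operand-free productions.** A constant production (e.g. the
border-zeroing rules `0 |e1_1 → 1|gx_1_j`) has no operands, so
`min(y)` is undefined. The engine takes the operand minimum to be 0, which
makes such rules applicable exactly when the enzyme is non-negative — and
in particular makes all gradient rules fire at step 1 under the seed
enzyme value 256.

**Assignment vs accumulation.** Classical numerical P systems *add*
repartition increments to targets. The edge-detection narrative, however,
treats the difference rule's targets as *set equal to* the production
share. The engine uses a single convention that reproduces both: at the
start of each step, every repartition target of a fired rule is reset to
0, then receives the summed increments of all rules that target it (in
declaration order); variables not targeted by any fired rule are
untouched. With this convention the decision pair for one pixel
(`Pr32` contributing 1 when `d ≥ 0`, its always-on sibling `Pr33`
contributing 0) leaves `edg_ij` at exactly the 0/1 indicator.

**Operand consumption.** Classical numerical P systems zero the variables a
production consumed. Here the pixel variables are read by up to a dozen
overlapping gradient windows in the same step and must survive, so the
default policy is *non-consuming*; the classical behaviour remains
available (`consumption = "consuming"`) for the general engine and is
covered by the brute-force one-step oracle tests.

**Scheduling.** Under true all-parallel semantics the magnitude and
difference rules would fire already at step 1 on zero-initialised
gradients, because the seed enzyme 256 gates nothing at that point. The
five-step behaviour only emerges if the membranes act in stages, which is
how the construction's execution is described: gradients, magnitudes,
differences, decisions, halt. The engine therefore has a `staged` mode
driven by an explicit schedule (`edenp_schedule()` returns the five
entries, selecting rule groups), alongside the `parallel` mode with
halting variable, silence, fixed-point and `max_steps` termination. Note
the two decision families (`Pr32`/`Pr33`) run in their own macro-step
after the difference step, matching the published step count of 5.

**Halting.** The halting rule has no enforceable enzyme condition as
written. In staged mode it simply occupies schedule entry 5 and sets
`ED = 1`; `enps_run()` also accepts `halt_variable = "ED"` with threshold
1, which is how the runs in this package detect completion.

## 3. Parameters and their defaults

| parameter | default | units/scale | why |
|---|---|---|---|
| `theta` | 0.2 | unit intensity scale | the conventional experimental threshold; only meaningful after normalisation |
| `normalize` | `TRUE` | — | divides 8-bit input by 255 so that `theta = 0.2` has its intended meaning |
| `enzyme_seed` (`e1_1`) | 256 | raw intensity | must strictly exceed every admissible pixel value (max 255), so the gradient and magnitude rules are always applicable |
| `ed1, ed2, ed3` | 0, 1, −256 | — | `min(ed1, ed2) = 0` makes the positive decision rule fire iff `d ≥ 0`; `min(ed1, ed3) = −256` keeps the zero-contribution sibling always applicable (any `d > −256`) |
| `mask` | `"sobel"` | — | the construction's worked operator; Prewitt and Roberts use the same machinery |

The compiler rejects inputs that would silently disable rules (any
intensity `≥ enzyme_seed`) or that cannot host a mask window (images
smaller than 3×3).

## 4. Numerical choices

Both engines are required to produce **bit-identical** edge maps, which
forces attention to floating-point evaluation order:

* Gradient productions are built in mask row-major term order, and the
  serial detector accumulates its correlation in the same order, so the
  two pipelines perform the identical sequence of IEEE additions.
* The difference rule's production is `2·(g − theta)` split evenly over
  two targets; multiplying by 2 and halving are exact in binary floating
  point, so each target holds exactly `g − theta`.
* The decision step works on integers (0, 1, 2), which are exact.
* Increments from multiple rules to one target are summed in rule
  declaration order, fixed at build time, so traces are bit-reproducible
  (`enps_run()` twice gives `identical()` traces).
* A repartition with zero coefficient sum is legal only for a zero
  production value (the border rules); a non-zero value raises an error
  naming the rule.
* `sqrt` of a negative intermediate raises an error; it cannot occur in
  the edge-detection system, whose radicand is a sum of squares.

## 5. Index conventions

The gradient of pixel `(i, j)` is computed from the 3×3 window *centred*
on it, for `2 ≤ i, j ≤ n−1`, with all four image borders zeroed by
explicit rules — the self-consistent reading of the construction (the
printed per-rule index ranges contain an off-by-one that would leave row
and column `n−1` uncovered). The 2×2 Roberts masks have no centre; they
are anchored at the top-left of the window, the output is assigned to the
anchor pixel, and only the last row/column are zeroed. The serial detector
mirrors both conventions, so equivalence is exact by construction.
Rectangular `h × w` images are supported throughout; the closed-form
resource counts are reported for square images only.

## 6. Resource accounting and the rule-count gap

For an `n × n` image the construction's published accounting lists 1 cell,
`2n² + 2` enzymatic variables, `5n² + 4` numerical variables, `6n² + 4`
rules, 5 execution steps and `13n² + 10` molecules. The variable counts
pin the variable set exactly and are reproduced by the compiled system
(`edenp_instance_counts()` equals the closed forms). The explicit rule
families, however, enumerate to `6n² + 1`: `2n²` gradient rules (interior
plus border-zeroing, covering every pixel exactly once per direction),
`n²` magnitude, `n²` difference, `2n²` decision, and one halting rule. No
faithful decomposition we could construct yields the published `6n² + 4`
without introducing machinery that would also break the variable counts.
`edenp_resources()` therefore reports the published closed forms as the
reference accounting, `edenp_instance_counts()` reports the instantiated
truth, and the acceptance test that asserts the published rule count
against the instantiated system fails by exactly 3 — deliberately left
visible rather than papered over.

## 7. What the synthetic generator does and does not establish

`synth_image()` produces seeded 8-bit images: two-level geometric patterns
(steps, squares, disks, checkerboards) whose discontinuity locus is known
by construction, smooth ramps, uniform noise fields, and optional additive
Gaussian noise / salt-and-pepper corruption truncated to the valid range.
The noiseless two-level patterns carry a `"discontinuity"` annotation (the
pixels whose 3×3 neighbourhood sees both levels), which is the analytic
edge band a mask detector must light up at a suitably small threshold.

This emulates the *structure* real test imagery probes — localized
intensity discontinuities at known positions, texture-free and
texture-rich regions — but not its *statistics*: no real sensor noise
model, no natural-image gradients, no licensed toolbox images. A green
equivalence suite therefore establishes that the membrane system computes
exactly the same function as the serial detector on the full input space
sampled (the equivalence is bit-exact and structural, not statistical),
and that the detector recovers known loci on idealized patterns; it does
not establish perceptual edge quality on natural images, which the
original evaluation measured with an externally defined confidence metric
on licensed images and which this package does not reproduce.

## 8. Known limitations

* The simulator interprets rules one by one on a serial machine; the
  five-step claim is about the model's parallel time, not wall-clock time.
  Compilation and execution are `O(n²)` in memory and time (about 24,600
  programs at `n = 64`).
* Only the two scheduling policies described are provided; stochastic and
  one-rule-per-membrane numerical P system variants, membrane
  creation/dissolution and P-Lingua compatibility are out of scope.
* Edge maps are raw thresholded gradients: no non-maximum suppression or
  hysteresis, matching the simplified model.
* Color images are not supported; PGM and delimited-text grayscale are the
  on-disk formats (PGM is always written with maxval 255).
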