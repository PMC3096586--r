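---
title: "Probabilistic timebox queries: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic timebox queries: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptbox)
```

## The problem

A timebox query asks whether a time course stays inside a rectangle drawn in
(time, value) space. For a set of `N` courses measured at `T` shared time
points, the deterministic semantics admit a course into the result iff, for
every box, the value at every integer time point inside the box's span is
present and lies in the closed band `[x_lo, x_hi]`; a multi-box query is the
intersection of the per-box results. This is easy to draw and easy to
reason about, but a single outlier, one missing measurement, a delayed onset
(phase shift) or a stretched response (speed variation) — all routine in
expression time courses, which are short, noisy and unevenly sampled —
ejects an otherwise matching gene with no notion of "almost".

`ptbox` keeps the rectangle as the query vocabulary but reads it
statistically, as one state of a linear hidden Markov model, and turns the
binary membership question into a ranking by likelihood.

## The model

An ordered set of `q` time-disjoint boxes compiles to a left-to-right chain
of `K >= q` states. From state `k` the only transitions are the
self-transition, with probability `p_k`, and the advance to `k + 1`, with
probability `1 - p_k`; paths start in state 1 and a course's score is the
forward probability mass occupying the final state at the last time point.
The per-state parameters come from box geometry:

* **Emission (value axis).** A box becomes a normal emission with
  `mu = (x_lo + x_hi)/2` and `sigma = (x_hi - x_lo)/4`, i.e. the box band is
  `mu +/- 2*sigma` and holds `2*pnorm(2) - 1` (about 95.5%) of the density.
  Excursions outside the band are allowed but priced; the further out, the
  cheaper it is for a competing course to win the slot.
* **Duration (time axis).** Self-transitions make state occupancy geometric:
  staying exactly `n` steps has probability `p^(n-1) * (1 - p)`, with mean
  `1/(1 - p)`. Setting `p = 1 - 1/d`, where `d = t_hi - t_lo` is the box
  width, makes the box width the *expected* duration rather than a hard
  window, which is what absorbs phase shifts and speed changes.
* **Waiting states.** Wherever the query leaves time uncovered — before the
  first box (if `t_lo > 1`), between boxes with a positive gap, after the
  last box (if `t_hi < T`) — a state with uniform emission over the data's
  observed value range `[x_min, x_max]` is inserted automatically, with the
  gap length as its expected duration. While waiting, any observed value is
  equally likely, so these ranges neither help nor hurt a course beyond the
  time they consume.
* **Duration normalization.** Expected durations are rescaled by a common
  factor to sum to `T`, with a floor of 1.0 per state (a state emits at
  least once); any duration clamped at the floor is frozen and the remainder
  is redistributed over the others, iterated to a fixpoint. The floor
  exists because the data carry no interpolation model — expecting behavior
  to last less than one sampling unit is overfitting in time.

Scoring uses the forward recursion entirely in log space with log-sum-exp,
`O(K*T)` per course; `-Inf` is a legal score meaning "no path explains this
course" (it arises only for courses scored against a model compiled from
*other* data whose range they exceed — on the compile-time set the uniform
support covers everything — or for courses shorter than the chain).
A probabilistic query returns the `m` top-ranked courses; ties break by
input order, so results are deterministic and top-`m` results are nested
in `m`.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| box width `t_hi - t_lo` | time steps | user-drawn, >= 1 | expected state duration; the 1.0 floor avoids forcing `p -> 0` |
| box height `x_hi - x_lo` | expression | user-drawn, > 0 | `4*sigma` of the emission; ~95.5% of mass stays in-band |
| stringency `m` | courses | required | result-set size; `m = N` returns everything, `m = 1` the argmax |
| `support_pad` | expression | 0 | widens the uniform support when scoring data other than the compile set |
| `max_missing_fraction` | proportion | 0.25 | pre-query filter; conventional, not calibrated to any dataset |
| `min_range` | expression | 1.0 | drops near-constant courses (log-scale data); same caveat |

Time labels (e.g. `0, 0.5, 2, 5, 7, 9, 11` hours) are carried as metadata
only; all arithmetic uses integer indices `1..T`. This is deliberate: with
no interpolation model, the sampling grid is the only clock the data
provide. Box coordinates are continuous (a box may start at `t = 1.5`)
because durations are real-valued, but emissions are only evaluated at
integer indices; the deterministic engine reads a box as constraining the
integer points in `[ceiling(t_lo), floor(t_hi)]`.

## What the synthetic generator emulates — and what it does not

`generator_config()` states a small two-population world: *signal* courses
follow a piecewise-constant template distorted by per-course phase shift
(<= `max_shift` steps), per-segment length jitter (<= `speed_jitter`),
i.i.d. Gaussian measurement noise, and sporadic single-point outliers;
*background* courses are pure measurement noise around the template's
global mean. Piecewise-constant templates are the matched generator for
this model class, which itself holds levels for geometric durations.

Defaults describe a plausible small log2-ratio experiment, chosen once on
domain grounds and not revisited: `T = 10`; levels `+1.5` then `-1.5`
(strong up/down regulation is 1–2 log2 units); `noise_sd = 0.5` (typical
replicate noise, and half the default `box_halfheight` so the matched query
has `sigma = noise_sd`); `outlier_prob = 0.05` per measurement with
`outlier_magnitude = 2.0` — a clear 4-measurement-sd spike, large enough
that a single one vetoes a course deterministically; shifts and jitter of
at most one sampling step; 30 signal among 120 background courses.

What a green recovery test establishes: under *matched* piecewise-constant
signal with sporadic outliers, ranking by forward likelihood recovers the
planted courses where the deterministic intersection collapses. What it
does not establish: performance on smoothly varying trajectories (ramps are
approximated, not modeled), on correlated noise, on heavy-tailed noise, or
on real sporulation-style data whose preprocessing this package does not
attempt to reproduce. Note also an information-theoretic boundary the test
suite respects: if *every* point is an outlier the template is gone and no
likelihood model can prefer signal to background — the robustness claim is
about sporadic corruption.

## Numerical and design choices

* **Quarter-height is the standard deviation, not the variance.** A
  quarter-height *variance* would contradict the 95.5% in-band mass that
  calibrates the emission; the package fixes `sigma = height/4` and tests
  the mass analytically.
* **Termination is strict final-state mass.** The chain has unique start and
  end states; we read "end" as "the forward mass in state K at time T",
  with no additional exit factor. For a single state spanning `[1, T]` the
  likelihood is then exactly the product of emissions times `p^(T-1)`,
  which the suite checks in closed form. Summing over all states at `T`
  instead would leniently admit courses that never reach the final box.
* **Abutting boxes are legal** (`t_hi = next t_lo`): disjoint interiors are
  what the no-overlap rule protects; abutment produces no waiting state.
* **Boundary waiting durations** are the uncovered lengths `t_lo(b_1) - 1`
  and `T - t_hi(b_q)`, by analogy with inter-box gaps; a positive duration
  below 1 is clamped to the floor before normalization.
* **Missing values are marginalized** (emission factor 1), the standard HMM
  treatment; imputation would manufacture evidence. For the deterministic
  engine the opposite convention is correct: a value that is absent cannot
  be shown to lie in the band, so it fails the box — this asymmetry is the
  point of the comparison.
* **Ties and `-Inf`.** Ties break by input order (stable); `-Inf`-scored
  courses are appended only to fill `m` and flagged in an `impossible`
  column.
* **`m > N`** returns all `N` courses with a warning rather than an error:
  over-asking is a user exploring, not a contract violation.
* **No re-estimation.** Queries are specifications, not models to fit: no
  Baum–Welch, no duration distributions beyond geometric, no cyclic
  topology.

## Known limitations

Deterministic queries expressible as "drop by 50% within a window" or
"fluctuate by at most x somewhere" have no probabilistic counterpart here;
conversely the probabilistic engine cannot be made exactly deterministic
(peaked boxes overfit in time by design). The duration normalization couples
all states: adding a box changes every state's `p_k` slightly, so
log-likelihoods are comparable within a query, not across queries. All
courses must share the same T; ragged input is rejected at I/O. The
fraction-of-points-inside relaxation of deterministic boxes is deliberately
not implemented — it trades one arbitrary threshold for another.

## A compiled example

```{r}
tcs <- time_course_set(matrix(rnorm(5 * 7), 5, 7))
spec <- query_spec(timebox(3, 5, -1, 1), mode = "probabilistic", m = 3)
compile_hmm(spec, tcs)
```

One box at `[3, 5]` over `T = 7` compiles to waiting / box / waiting with
raw durations 2, 2, 2, rescaled to sum to 7. The emission `sigma` is 0.5 —
a quarter of the box height — and every self-transition probability is
`1 - 1/duration`.
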