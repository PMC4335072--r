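---
title: "Pattern regeneration from cell memory: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern regeneration from cell memory: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memregen)
```

## The model

`memregen` simulates regeneration of two-dimensional cell structures
driven by a remembered signal distribution — a quantitative
target-morphology mechanism. Cells are mathematical points at the nodes
of the unit square lattice. Every cell emits the same signal, whose
intensity decays with the straight-line Euclidean distance $d$ as a
kernel $f(d)$, either polynomial $f(d) = d^{-n}$ or exponential
$f(d) = e^{-nd}$, $n > 0$. The total signal received by cell $i$ from a
source set $I$ is

$$u_i = \sum_{j \in I,\, j \ne i} f(d_{ij}).$$

This distribution encodes the geometry of the structure: boundary cells
receive less than interior cells, corners least of all.

After an amputation, the surviving **control cells** hold two numbers:
the **old signal** $u_i^*$ they received from the complete structure
(their memory), and the **current signal** $u_i(t)$ they receive from
the cells present at discrete time $t$. The difference drives
regeneration. One cell is added per time step, subject to:

1. **Continuity** — a new cell must be 8-adjacent (Moore neighborhood)
   to the **blastema** (control cells bordering the removed region) or
   to an earlier new cell.
2. **No overshoot** — after the tentative placement every control cell
   must satisfy $(u_i - u_i^*)/u_i^* < \epsilon$. The same check runs
   after each placement; if it fails there, the run stops with status
   `violation`.
3. **Greedy choice** among admissible candidates, by one of two rules:
   * **3a** maximizes the total signal the candidate adds to the
     control cells (equivalently, minimizes $S^* - S(t)$ where
     $S = \sum_{i} u_i$);
   * **3b** maximizes the deficit-weighted signal the candidate
     *receives* from the control cells,
     $z_k = \sum_{i} f(d_{ik}) (u_i^* - u_i(t))$ — the more
     biologically plausible reading, where each control cell emits a
     repair signal proportional to what it misses.

Growth stops when the current signal coincides with the remembered one;
the regenerated structure is then the original one. The same engine
runs a **morphogenesis** mode: an organizing center whose cells carry a
*prescribed* $u_i^*$ (standing for a distribution laid down during
embryogenesis) grows new tissue around itself until the prescription is
met (`grow_from_organizer()`).

## Parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `n` | kernel decay rate (dimensionless; distances in lattice units) | 2 | polynomial decay near $n = 2$ regenerates the largest domains; exponential kernels need much larger $n$ (around 11) to localize comparably |
| `epsilon` | relative overshoot tolerance of condition 2 | `1e-14` | the only numerical parameter of the model proper |
| `stop_deficit` | relative undershoot at which the signals are declared coincident | `1e-9` | a float-equality surrogate; exact equality is unattainable. Kept separate from `epsilon`, which the model treats as physically meaningful |
| `max_steps` | placement budget | `10000` | runs that overgrow without converging end as `step_limit` |
| `search_margin` | extent of the candidate window beyond the original bounding box | 5 | must be positive so wrong cells *can* appear outside the original shape; 5 lattice units exceeds every distance at which a misplaced cell remains admissible in our fixtures |
| tie-break | order among equal-scoring candidates | (y, then x) | any fixed order works; this one makes runs reproducible bit for bit |

Signal units are arbitrary: every decision in the algorithm compares
signals relatively, so rescaling $f$ changes nothing.

## What the generators emulate

`make_rectangle()`, `make_ellipse()` and `make_glyph()` produce the
fixture families used throughout: filled convex domains, and nonconvex
letter-like and multi-armed composites (a trunk with two heads,
mirroring the ability of one trunk to carry several remembered
morphologies). They are deterministic coordinate constructions — no
randomness, no font rasterization — so every test input is exactly
reproducible. Amputation masks are predicates or node lists;
`amputate()` labels roles and the blastema follows as the control cells
8-adjacent to removed ones.

What these fixtures do **not** emulate: cells as extended objects,
differentiation into types, signal transport along curved tissue paths
(distances always cut across empty space, which is read biologically as
other tissues transmitting but not regenerating), stochastic cell
behavior, and 3D anatomy. A green round-trip test therefore establishes
that the *algorithm* restores the *geometry* under the model's
assumptions — not that real tissue does.

## Validity range, and what stays red

The model restores a cut exactly only within a validity range, and the
package's fixtures are chosen inside it deliberately:

* **Shallow or enclosed cuts regenerate exactly** — straight cuts up to
  about two rows, notches, single side columns, ellipse caps, and
  arm-end cuts of thick-stroked glyphs, all verified under both rules
  with $n = 2$, $\epsilon = 10^{-14}$.
* **Deep open cuts fail**: once the local deficit next to the stump's
  lateral corner exceeds $f(1) = 1$, a cell hugging the outside of the
  boundary becomes admissible *and* outscores the correct distant
  cells, under rule 3a and 3b alike; the run stalls off-shape. This is
  the same wrong-cell mechanism that makes nonconvex domains fragile
  (a nearby control cell would veto the wrong cell; when the nearest
  control is far, its inequality is satisfied and the wrong cell
  enters). We verified the effect is not an artifact of the candidate
  rule: restricting candidates to former tissue nodes, or to
  common-side adjacency, shifts but does not remove it.
* **Thin structures amplify it**: strokes thinner than ~4 cells rarely
  regrow a cut arm; the glyph fixtures use 4-5 cell strokes.

Where the decay rate is too small ($n = 1$) the boundary is not sharply
encoded and even small cuts overgrow; near $n = 2$ the regenerable
domain is largest. With exponential kernels the window between "too
flat" and "numerically invisible" is narrow: at $n = 5$ a deep cut's
outcome flips from exact to unbounded wandering purely on $\epsilon$
(tight tolerances veto the first misstep; loose ones let the structure
overshoot cell by cell).

## Numerical choices

* Fields are plain double-precision sums; admissibility of candidate
  $k$ is evaluated as $f(d_{ik}) < u_i^*(1+\epsilon) - u_i(t)$,
  vectorized over candidates and controls.
* $u(t)$ is updated incrementally after each placement (one kernel
  column), which matches full recomputation to ~1e-16 relative — far
  below the default $\epsilon$.
* Exact score ties occur on symmetric fixtures; they are broken by the
  fixed (y, x) order. Symmetric inputs may still regenerate through
  asymmetric intermediate states — the model does not promise symmetry
  preservation, only the exact final set when it converges.
* A run that stalls after placing exactly the removed node set is
  reported `exact`: the remaining candidates are all vetoed by
  condition 2, which is precisely the stopping signal.
* Circle intersection in `restore_single_cell()` classifies tangency at
  relative tolerance `1e-9`; with three or more controls the common
  intersection keeps points lying on every circle within the same
  tolerance.
* `ode_residual()` evaluates the diffusion operator with the closed
  form's exact derivatives, so the correct constant $c$ yields residual
  at rounding level (< 1e-10 over $(0, 10]$) while a 10% perturbation
  of $c$ fails by orders of magnitude.

## Design choices on open points

* **Candidate window**: the original bounding box plus
  `search_margin`; unbounded search would make each step's cost grow
  without changing outcomes (admissibility vetoes distant cells long
  before the window does).
* **Organizer blastema**: growth from an organizing center may start at
  any boundary cell of the organizer (any cell with an empty
  8-neighbor); the source text does not pin this down, and boundary
  seeding reduces exactly to regeneration when the prescribed field
  comes from an enclosing shape (verified for a 6×6 target around a
  4×4 organizer; more distant targets hit the validity limit at the
  corners, like deep cuts do).
* **New cells never join the control set**: every condition ranges over
  the original control cells only, matching the formulas' index sets;
  new cells influence the run only as signal sources.
* **Undershoot vs overshoot tolerances are distinct** (`stop_deficit`
  vs `epsilon`): collapsing them would make "success" depend on the
  physically meaningful overshoot parameter.

## Known limitations

Path distances along tissue, differentiation, long-distance signals,
cell death, batch placement, and membrane-level signal bookkeeping are
out of scope. The exact-regeneration guarantee is empirical and
fixture-bounded, not a theorem: the package's own acceptance suite
documents both the green region (12 shape/cut combinations, both rules)
and the red one (deep cuts, thin arms, $n$ far from 2).
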