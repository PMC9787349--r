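---
title: "Feasibility-seeking inverse planning with dose-volume constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feasibility-seeking inverse planning with dose-volume constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The planning problem

Fully discretized inverse radiotherapy planning seeks a nonnegative beamlet
intensity vector $x \in \mathbb{R}^n_+$ such that the dose $d = Ax$ it
deposits satisfies a physician's prescription. The dose-influence matrix
$A$ is precomputed; its rows are grouped into blocks $A_\ell$, one per
anatomical structure (avoidance organs and target volumes). The
prescription supplies two kinds of rules per structure:

* **Hard dose constraints (HDCs)** — every voxel's dose is bounded above
  (Dmax, avoidance and target) or below (Dmin, target).
* **Dose-volume constraints (DVCs)** — written $D_{V\%} \le b$ or
  $D_{V\%} \ge c$: a fraction of the structure may exceed (fall short of) a
  base bound, by a bounded amount.

`sacq` treats a DVC as a *percentage-violation constraint* with two
parameters per block: $\alpha_\ell \in [0,1]$, the fraction of the block's
$m_\ell$ voxels allowed to violate the base bound, and
$\beta_\ell \in [0,1)$, the relative amount by which violators may
overshoot. The per-voxel (convex) constraints become relaxed half-spaces

$$C_{\ell i} = \{x : \langle a_{\ell i}, x\rangle \le (1+\beta_\ell)\,b_{\ell i}\}
\quad\text{or}\quad
\{x : \langle a_{\ell i}, x\rangle \ge (1-\beta_\ell)\,c_{\ell i}\},$$

while the counting part becomes a *nonconvex* constraint on the dose
vector: at most $\lfloor \alpha_\ell m_\ell \rfloor$ components of
$A_\ell x$ may lie beyond the base bound,

$$Q_\ell = \{v \in \mathbb{R}^{m_\ell} :
  \lVert (v - b_\ell)^+ \rVert_0 \le \alpha_\ell m_\ell\}.$$

This split — convex constraints in intensity space, sparsity-type
constraints in dose space — is a split feasibility problem, and the method
operates by projections only.

### From a prescription to block parameters

`prescription_to_blocks()` converts structure-level rules. For an upper DVC
$D_{V\%} \le b$ with hard bound Dmax, the base bound is $b$,
$\beta$ solves $(1+\beta)\,b = \mathrm{Dmax}$ (so the *relaxed* half-space
is exactly the hard bound) and $\alpha = V/100$. For a lower DVC
$D_{V\%} \ge c$ with Dmin, $\beta$ solves $(1-\beta)\,c = \mathrm{Dmin}$
and $\alpha = 1 - V/100$: the rule "90% of the target receives at least
65" leaves a 10% shortfall budget. (The alternative reading
$\alpha = V/100$ for lower DVCs would hand the target a 90% shortfall
budget, which contradicts the DVH meaning of $D_{90\%} \ge 65$; the
package adopts the self-consistent convention throughout.) A structure
with both Dmin and Dmax contributes two blocks over the same rows; hard
bounds without a DVC yield plain blocks with $\beta = 0$ and no counting
constraint.

## Operators

**Relaxed half-space projection** (`project_halfspace`): if the effective
bound is violated, move along the constraint normal by $\lambda$ times the
metric-projection step, $\lambda \in (0,2)$; $\lambda = 1$ lands on the
bounding hyperplane.

**Sparsity-set projection** (`project_sparsity_set`): a Euclidean nearest
point onto $\{z : \lVert z^+\rVert_0 \le \text{budget}\}$ is obtained by
zeroing the smallest positive components. The projection is not unique
when positive values tie; the package zeroes the lowest index first, making
every run deterministic. `project_dvc` shifts a dose vector into
excess/deficit coordinates, applies the sparsity projection and shifts
back; zeroed components land exactly on the base bound and untouched
components are returned bit-identically.

Two removal counts are offered. The `"member"` rule (default) removes
$\lVert y^+\rVert_0 - \lfloor\alpha m\rfloor$ positives, so the output is
always a member of the set — required for the fixed-point reasoning the
solver relies on. The `"literal"` rule removes
$\lfloor \lVert y^+\rVert_0 - \alpha m\rfloor$, which for fractional
$\alpha m$ leaves $\lceil\alpha m\rceil$ positives (one too many for
membership). Both are exposed because the literal placement of the floor
is a defensible alternative reading; nothing else in the package depends
on the choice.

**Landweber-type block operator** (`landweber_step`):
$V_\ell = \mathrm{Id} - \gamma_\ell A_\ell^T(\mathrm{Id} - P_{Q_\ell})A_\ell$
pulls $A_\ell x$ toward $Q_\ell$ without ever forming a pseudo-inverse.
Its fixed points are exactly the preimages $A_\ell^{-1}(Q_\ell)$, and for
convex $Q$ with $\gamma_\ell < 1/\lVert A_\ell\rVert^2$ it is a cutter;
both properties are exercised as randomized tests.

**Step size $\gamma_\ell$.** The theory wants
$\gamma_\ell \in (0, 1/L_\ell)$ with $L_\ell = \lVert A_\ell \rVert^2$.
The packaged default (`gamma_mode = "midrange"`) uses $1/L_\ell$, the
customary practical value at the interval's endpoint; `"strict"` uses
$1/(2L_\ell)$, the midpoint of the open interval. The distinction matters
only in principle — the endpoint has never misbehaved on these problems —
but both are selectable so the theoretically safe choice is one switch
away. $L_\ell$ itself is computed by power iteration on
$A_\ell^T A_\ell$ with a deterministic all-ones start, tolerance
$10^{-8}$, capped at $10^4$ iterations: reproducible without a seed, and
checked against a dense SVD in the tests.

## The string-averaging iteration

Each block owns the composition $R_\ell = U_\ell V_\ell$, with $V_\ell$
(the dose-space step, skipped for blocks without a DVC) applied first and
$U_\ell$ — a sequential sweep of the block's relaxed half-space
projections, ascending voxel order by default — applied second. The
rightmost-first convention follows the operator-composition definition of
$R_\ell$; because the reference pseudo-code interleaving is not fully
specified, `dvc_first = FALSE` swaps the factors.

A *string* is an index vector $t = (t_1,\dots,t_q)$ over blocks; the
string operator applies $R_{t_1}$ first. A *plan* $(\Theta, w)$ is a set
of strings with convex weights; it is admissible when it is *fit* (every
block appears in some string), weights stay above a floor $\Delta$ and
lengths below a cap $\bar q$. One iteration (`sa_iterate`) evaluates all
strings independently from the current iterate and returns the weighted
average of their end points — order-independent by construction, with
compensated summation so evaluation order cannot leak into the result even
at the $10^{-12}$ level. `run_dynamic_sa` iterates plans from a schedule
that may change per cycle; `run_sequential_rttp` is the fully sequential
special case (single full-length string, unit weight) packaged as the
default planning loop. Nonnegativity of $x$ is enforced by clamping
negative entries once per cycle, after all projections — not inside each
projection.

Stopping is a fixed cycle count (default 40) with an optional
stop-when-zero-violations rule; per-cycle violation counts, by category,
are recorded in the returned history and written as CSV by the I/O layer.

## The synthetic phantom

The generator emulates a two-dimensional planning exercise: a
$512 \times 512$ pixel grid; 1156 isotropic Gaussian pseudo-dose kernels
($\sigma = 20$ px) on a uniform $34 \times 34$ lattice, one per beamlet;
a single common amplitude calibrated so the superimposed map has mean 50
intensity units (the calibration is linear, so the match is exact to
rounding); and three disjoint square structures. Kernels are truncated at
$4\sigma$ — a relative amplitude of $e^{-8} \approx 3\times 10^{-4}$ —
which keeps the assembled dose-influence matrix (262,144 rows by 1156
columns) sparse; a dense no-truncation mode exists for oracle comparison.
Columns are row-major flattenings of the per-kernel pixel maps; structure
rectangles use 0-based, half-open pixel ranges.

The packaged prescription: Avoidance A, Dmax 25 with $D_{10\%} \le 20$;
Avoidance B, Dmax 40 with $D_{25\%} \le 30$; Target, Dmin 60, Dmax 70 with
$D_{90\%} \ge 65$ — four hard bounds and three DVCs, yielding four blocks
(the target contributes a lower and an upper block over the same rows).

**Geometry.** The reference experiment defines its three squares only
pictorially, so the rectangles here are package choices: 96 px squares at
mid-height, columns 32–128, 208–304 and 384–480. The $4\sigma$
edge-to-edge separation makes the structures dosimetrically decoupled
(cross-talk at the $e^{-8}$ level), which keeps the planning difficulty in
the dose-volume machinery rather than in structure overlap. The published
step sizes imply the original structures were larger and unequal; since
they are unrecoverable, the package documents its own geometry and treats
step sizes as derived quantities, never as inputs.

**Quarter-scale variant.** `phantom_small()` divides every spatial length
by four — $128 \times 128$ grid, $\sigma = 5$, 24 px squares — with a
$17 \times 17$ kernel lattice and the same calibration and prescription.
Scaling $\sigma$ with the geometry (rather than with the kernel lattice)
keeps the phantom a true miniature: kernel overlap relative to structure
size, and hence the character of the planning problem, is preserved. The
summed map remains homogeneous (interior coefficient of variation well
under 1%), which the tests assert at both scales.

**What the phantom does not emulate:** physically realistic beamlet
kernels (pencil beams, Monte-Carlo dose), three-dimensional voxel
geometries, heterogeneous tissue, or clinical DICOM-RT data. Passing tests
demonstrate the algorithmic machinery on a controlled linear model, not
clinical plan quality.

## Evaluation conventions

The cumulative DVH reports, per threshold $d$, the percentage of a
structure receiving at least $d$. $D_{V\%}$ uses the order-statistic
convention: the $\lceil V m/100\rceil$-th largest dose, no interpolation,
so $D_{100\%}$ is the minimum dose. This convention makes
"$D_{V\%} \le b$" *imply* the counting budget
$\#\{d_i > b\} \le \lfloor Vm/100\rfloor$, with exact equivalence whenever
$Vm/100$ is fractional; when $Vm/100$ is an integer the order statistic
sits one voxel deeper than the budget, a boundary case the tests document
explicitly. Constraint satisfaction is always decided on the counting
form, never on a discretized DVH curve.

Violation counting separates four categories — voxels above a hard Dmax,
below a hard Dmin, and per-DVC-block the *excess* of base-bound violations
over the allowed budget, by sense. Raw beyond-base counts are logged
alongside, since a "total violations" curve can reasonably mean either.
Percentages are normalized per category population. Residual comparisons
use an absolute tolerance of $10^{-9}$ so that doses landing on a bounding
hyperplane to rounding error do not count as violations.

## Numerical choices and degenerate inputs

* All spaces are finite-dimensional real coordinate spaces with the
  standard dot product.
* Zero coefficient vectors, all-zero matrices, empty blocks, budgets
  outside $[0, m]$ and relaxations outside their intervals are rejected
  with specific errors rather than propagated as NaN.
* Ties in the sparsity projection: lowest index zeroed first.
* `sa_iterate` uses Kahan-compensated summation for the convex
  combination; a single string bypasses the combination entirely, making
  the sequential solver bit-identical to the single-string average.
* Randomized orders (block/voxel permutations) draw from a private seed
  and restore the caller's RNG state afterwards; identical configuration
  and seed give bit-identical logs.

## Behavior under the default cycle budget

With the default 40 cycles, unit initial intensities and $\lambda = 1$,
the packaged runs drive the total violation count down by roughly two
orders of magnitude and meet the hard bounds to within small residuals,
while the dose-volume budgets are typically approached but not exactly
met — the per-cycle log shows the DVC-excess counts still decreasing when
the cycle cap fires. Longer runs (`stop_on_zero = TRUE`) continue the
decrease; convergence theory covers the convex constraints, whereas for
the nonconvex dose-volume sets the iteration is a well-behaved heuristic
whose analysis remains open. The test suite therefore asserts strict
violation *decrease* over the default run and exact solution of convex
feasibility problems (max residual below $10^{-6}$ with Fejér-monotone
iterates), but full DVC-budget satisfaction inside 40 cycles is not a
property this method has on these phantoms.

Problem sizes used by the test suite were chosen to keep a full run
comfortably interactive: the exhaustive projection oracles enumerate
vectors of length at most 8 (1,000 randomized cases), operator properties
use $3$–$5$-dimensional instances (1,000 cases), convex convergence uses a
seeded $50 \times 10$ system, and the end-to-end planning checks run the
quarter-scale phantom; the full $512 \times 512$ assembly and its
calibration are verified once per run.

## Limitations

* The dose-volume projection is a nearest point onto a nonconvex set;
  string averaging over such sets has no convergence guarantee, and the
  package makes no stronger claim.
* The adaptive re-weighting of $\lambda$, $\gamma$ across cycles is
  exposed as plumbing (per-block parameters may vary by cycle) but no
  adaptive policy is packaged.
* The phantom's structures are axis-aligned rectangles; arbitrary masks
  can be supplied through the file interface (row-index sets), not through
  the generator.
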