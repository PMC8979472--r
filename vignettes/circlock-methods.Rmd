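---
title: "Models and methods behind circlock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind circlock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circlock)
```

# The model family

`circlock` simulates and analyses a family of dimensionless models of the
mammalian circadian clock in which the nonlinearity driving oscillations is
*protein sequestration*: the repressor (PER:CRY, state variable `P`) binds
the transcriptional activator (BMAL1:CLOCK) stoichiometrically with
dissociation constant $K_d$, rather than binding DNA cooperatively as in
the classical Goodwin oscillator. Concentrations are measured in units of
$K_d$ and time in units of the common first-order decay rate
$\hat\beta$, so the binding equilibrium fixes the free activator to

$$A_{free}(A_T, P) = \tfrac12\left[A_T - P - 1 +
\sqrt{(A_T - P - 1)^2 + 4A_T}\right],$$

a root that responds ultrasensitively to `P` when $A_T \gg 1$.

The core negative-feedback loop is a chain of length $N$: *Per* mRNA `M`,
intermediates `P1 ... PJ` ($J = N - 2$, standing for mRNA processing,
export, translation, multi-site phosphorylation and nuclear import), and
nuclear PER `P`:

$$\frac{dM}{dt} = \alpha F(A_{free}) - M,\qquad
\frac{dP_1}{dt} = M - P_1,\qquad
\frac{dP_j}{dt} = P_{j-1} - P_j,\qquad
\frac{dP}{dt} = P_J - G(P).$$

Two transcription laws are supported, $F = A_{free}/A_T$ (law 0, activator
assumed to saturate the E-boxes) and $F = A_{free}/(K_A + A_T)$ (law 1,
with an explicit activator–E-box dissociation constant; $K_A = 0$ recovers
law 0), and two degradation laws, $G(P) = P$ (linear) and
$G(P) = \beta_{max} P/(K_m + P)$ (Michaelis–Menten, saturating). The
shorthand `SNF(0L3)`, `SNF(1M8)` etc. encodes (transcription law,
degradation law, loop length).

Two extensions make total activator dynamic with relaxation rate
$\delta$: `NNF` adds REV-ERB (`V`) repressing *Bmal1*
($dA_T/dt = \delta[A_{MAX}/(V+1) - A_T]$, $dV/dt = \delta[V_{MAX} F - V]$)
and `PNF` adds ROR (`R`) activating *Bmal1*
($dA_T/dt = \delta[A_{MAX}(\varepsilon+R)/(R+1) - A_T]$,
$dR/dt = \delta[R_{MAX} F - R]$, with basal expression fraction
$\varepsilon$). The transcription input $F$ of the auxiliary gene shares
$K_A$ with the *Per* gene: the E-boxes of the two promoters are treated as
equivalent, which is the simplest reading of a shared rate law; a
promoter-specific constant would be a one-line generalisation.

# Hopf loci and the secant condition

For linear degradation the Hopf bifurcation locus in the $(\alpha, A_T)$
plane is the root set of $\Phi\alpha^2 - \Psi(A_T)\alpha + \Omega(A_T) = 0$
with $\Phi = (S_N-1)^2$, $\Psi = S_N[(A_T+1)^2 - 4S_N A_T]$,
$\Omega = S_N^2 A_T (A_T+1)^2$ (law 0; law 1 multiplies $\Psi$ by
$(A_T+K_A)/A_T$ and $\Omega$ by $(A_T+K_A)^2/A_T^2$), where
$S_N = \sec(\pi/N)^N$ is the secant factor: the minimal loop gain for a
length-$N$ chain of equal first-order stages to oscillate ($S_3 = 8$,
$S_4 = 4$, decreasing to 1). Oscillations live strictly between the two
roots. The smaller root is evaluated as $2\Omega/(\Psi+\sqrt{\Delta})$ to
avoid cancellation; a negative discriminant is reported as "no Hopf at
this $A_T$" (`NA`), not as `NaN`.

Every analytic branch is verifiable against an independent oracle: the
leading eigenvalue of the analytic Jacobian at the steady state, whose
real part must change sign across the root. The package assembles the
Jacobian from the chain structure plus the sequestration partials
$\partial A_{free}/\partial P = -A_{free}/s$ and
$\partial A_{free}/\partial A_T = (A_{free}+1)/s$ with
$s = \sqrt{(A_T-P-1)^2+4A_T}$.

Steady states use the closed form for `SNF(0LN)`; other SNF variants
reduce to a monotone scalar balance solved with `uniroot`. For NNF and
especially PNF the activator arm feeds back on itself, the algebraic
system can be multi-branched, and nested scalar root-finding fails (the
outer balance becomes discontinuous where the inner branch jumps); the
package therefore uses damped Newton iteration on the full algebraic
system from a grid of starts, de-duplicates the converged roots, and
warns if more than one equilibrium is found.

# Simulation and cycle statistics

Integration uses `deSolve::lsoda` with the right-hand sides compiled in C.
Default tolerances are `rtol = 1e-8`, `atol = 1e-10`; the tight absolute
tolerance matters for PNF, whose trajectories spend half of each cycle on
near-zero plateaus. The default run integrates to `t_end = 600`
dimensionless units with 24 000 output intervals and discards the first
60% as transient.

The period is the mean spacing of upward mean-crossings of `P` (linearly
interpolated), requiring at least five full cycles. A run counts as
oscillatory when the relative amplitude of `P` exceeds `1e-3`, the
crossing spacings are stable to 0.1%, and the per-cycle amplitude
envelope is flat (last cycle within 2% of the first). A drifting
envelope in either direction means the attractor has not been reached —
the cycle may be approached from inside *or outside* — so such runs are
inconclusive and automatically re-integrated with doubled `t_end` up to
three times; slowly damped spirals keep shrinking until they fall below
the amplitude floor and classify as non-oscillatory, while limit cycles
settle to a flat envelope. Convergence is slow near Hopf boundaries. Peak total PER
`max_P_tot` sums `P` and all chain intermediates (mRNA `M` excluded); the
protein-only variant additionally drops the first `n_mrna` chain species
(default 2 for $N \ge 8$ loops, 0 otherwise — the chain does not label
which intermediates are mRNA-like, so this discount is a convention, and
quantities derived from it are approximate). `avg_A_T` is averaged over
exactly one period, since a window-dependent average would be
meaningless.

Bulk measurements over unsynchronised cells are emulated by
`population_average()`: the limit cycle is resampled on a 2048-point
phase grid and averaged over `n_cells` copies shifted by
$\mathcal{N}(0, \sigma_{phase})$ draws with periodic wrap-around. The
number of cells in the corresponding published figure is not stated;
the default `n_cells = 100` makes the averaging noise comfortably smaller
than the tolerance used in its test. Dephasing attenuates the $k$-th
harmonic by $e^{-k^2\sigma^2\omega^2/2}$, so asymmetric waveforms average
toward sinusoids — the third standardised moment of *Per* mRNA drops from
0.455 on a single cycle to about 0.17–0.2 at $\sigma_{phase} = 0.5$.
(Skewness must be computed over an integer number of periods on a uniform
grid; partial cycles bias it appreciably.)

# Classification, scans and areas

Linear-degradation SNF models are classified by the eigenvalue sign —
fast and exact. Michaelian, NNF and PNF models are classified by
simulation with the amplitude rule above, reflecting that their domains
have no closed form. Two-parameter scans record the classification and
the period on a grid; mask transitions can be refined by bisection
(12 halvings per edge, about 1% of a cell). The robustness-area
computation uses 32-point-per-axis grids and a cheaper solver profile
(`t_end = 300`, `rtol = 1e-6`); eigenvalue/simulation agreement is
spot-checked at 60 random parameter points — problem sizes chosen so the
whole analysis stays interactive while boundary placement stays well
within the tolerances asserted.

The circadian-robustness area integrates the indicator of "period between
22 and 26 h" (the published descriptions use both 22–25 h and 23–26 h
windows; 22–26 h covers both and the window is configurable) over the
rectangle $[0.25, 4]^2$ in fold-changes of the wild-type point,
trapezoidally on 32-point grids. The published comparison states no scan
bounds, so a convention is required; the quarter- to four-fold WT
neighbourhood is the expression range the five-point robustness
criterion itself declares biologically relevant, and it is the one
rectangle with an a-priori justification. A caveat discovered while
validating the convention: the circadian domains are not all contained
in any finite rectangle (the NNF model keeps genuine circadian cells,
confirmed at strict solver tolerances, at arbitrarily small activator
expression), so "the" area is only defined relative to a stated
rectangle. Under this convention the computed NNF area is essentially
equal to the SNF area rather than two-thirds larger; the corresponding
check is asserted at the published ratio and documents the disagreement
by failing, while the PNF and SNF entries agree with the published
comparison. The conversion to hours divides the dimensionless period by
$\hat\beta$ (per-model values documented with the presets).

The five-point criterion — wild type plus halved/doubled $\alpha$ and
halved/doubled $A_T$ (or $A_{MAX}$) all oscillatory — uses Hopf-band
membership for linear models and sustained simulated oscillation
otherwise; the two notions agree except on a measure-zero neighbourhood
of the boundary.

# Unit calibration

All physical estimates flow through one constant: a budget of
$3\times10^4$ PER molecules in a nucleus of 500 fL is
$3\times10^4/(500 \cdot 0.602) \approx 99.7$ nM (quoted as 100 nM at the
precision these estimates carry). Because concentrations are scaled by
$K_d$, the dimensionless peak of total PER fixes
$\hat K_d \approx 100\,\mathrm{nM} / \max_t P_{tot}(t)$: a model that
needs a peak of 2500 forces $\hat K_d \approx 0.04$ nM (biophysically
implausible — protein–protein $K_d$ values below 1 nM would require
unrealistically fast association), while a peak near 50 allows
$\hat K_d \approx 2$ nM. Reports offer both the total and the
protein-discounted estimate. $\hat\beta$ is calibrated as
$\tau/24\,\mathrm{h}$ unless supplied.

# Constrained annealing search

`anneal()` minimises `max P_tot` (maximises the permissible $K_d$) over
log-scaled boxes (five decades per parameter) with hard constraints:
sustained oscillation, relative amplitude of $P_{tot}$ above 0.5, and for
the extended families amplitude of $A_T$ above 0.2 and caps
$\max V < 10$ / $\max R < 5$ derived from molecule-count ceilings.
Violations enter the cost as the exact penalty
$10^3 \cdot \mathrm{violation}$; the linear form is essential — a
quadratic penalty has zero gradient at zero violation, so its penalised
optimum sits strictly on the infeasible side of the amplitude threshold
and converged runs would systematically stall at relative amplitudes just
below 0.5. The soft preference for $\max A_T \approx \max P_{tot}$ enters
as $10^3 \log^2(\mathrm{ratio})$. The exact cost function of the original
search is not published, so batch statistics carry wide tolerances.
Proposals are multiplicative (Gaussian in $\log_{10}$), shrinking from
0.25 to 0.0125 decades over a run so late iterations refine; the
temperature cools geometrically (0.95 per 50 accepted moves). A
non-oscillatory candidate costs $10^4$ plus a term decreasing in its
residual ring-down amplitude, which gives the walk a slope toward the
oscillatory domain. Each restart reports the best *feasible* candidate it
visited (not its final state — the minimiser of the penalised cost often
sits just below the amplitude threshold, and keeping the feasible best
matches a search whose accepted solutions must satisfy the constraints
exactly), then refines it with a few hundred greedy feasible-only steps.
Each walk starts from an oscillatory point when rejection sampling finds
one quickly, since the search is only meaningful inside the oscillatory
domain. Candidate evaluations use the cheap solver profile; batch runs of
20 restarts x 600 iterations plus polish take a few minutes per family.
The five-point criterion is applied as a post-filter on candidates, not
inside the objective.

# Degenerate inputs and numerical corner cases

* `A_free` switches to the rationalised root form when $P + 1 > A_T$;
  the textbook form loses all precision exactly where oscillations drive
  `P` far above `A_T`.
* Rate law 0 is undefined at $A_T = 0$ (a genuine defect of that law —
  the motivation for law 1); the package raises a domain error rather
  than returning `Inf`.
* Constant trajectories are reported non-oscillatory with zero relative
  amplitude; series with zero variance make skewness an error, not `NaN`.
* Initial conditions default to the origin (activator at $A_{MAX}/2$ for
  NNF/PNF); any positive start reaches the same attractor, and a fixed
  choice keeps runs byte-reproducible. All chain stages share unit rates;
  there is deliberately no per-stage rate customisation.

# What the built-in presets do and do not show

The six presets reproduce documented operating points and are the basis
of the package's acceptance checks (periods and peaks to 5%). They are
dimensionless idealisations: equal decay rates everywhere, no explicit
CRY/CLOCK species, no stochasticity, no light input, no compartment
volumes. Passing checks demonstrate internal consistency of the model
family and its analysis, not fidelity to any particular mammalian
dataset.

# Known limitations

* No numerical continuation beyond Hopf (no fold or period-doubling
  tracking); scans plus bisection stand in for a continuation code.
* The mRNA-discount convention (`n_mrna`) is a heuristic; published
  discounted peaks do not follow a single reproducible rule.
* The annealing batch statistics depend on an unpublished cost function;
  they are reproduced only within generous stochastic bands.
* SBML export is not provided; trajectory CSV and JSON summaries are the
  interchange formats.
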