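---
title: "Designing coherent ensemble oscillations for master-equation systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing coherent ensemble oscillations for master-equation systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MarkovRhythm)
```

## The model

A mass-action reaction network with N species and R reactions
$\sum_i s_{ij} X_i \to \sum_i r_{ij} X_i$ defines a continuous-time Markov
chain on copy-number states $n$. Its law evolves by the chemical master
equation $\partial P/\partial t = M P$, where the generator $M$ has
off-diagonal entries $M_{\beta\alpha} = k_{\alpha\to\beta} \ge 0$, diagonal
entries equal to minus the escape rates, and zero column sums. The package
uses the combinatorial mass-action propensity
$a_j(n) = c_j \Omega^{w_j} \prod_i n_i (n_i-1)\cdots(n_i - s_{ij} + 1)$,
with the system-size exponent $w_j$ declared per reaction in the model
file, because no single $\Omega$-scaling convention fits all reactions (a
trimolecular autocatalytic step scales as $\Omega^{-2}$ while a reservoir
influx scales as $\Omega^{+1}$).

Zero column sums force every nonzero eigenvalue of $M$ to have a strictly
negative real part (a Gershgorin-plus-irreducibility argument;
`spectralSummary()` flags any numerical violation as an internal
inconsistency rather than reporting it). The consequence is the package's
starting point: ensemble averages of any observable relax — coherent
ensemble oscillation is impossible for an isolated Markovian chemical
system, however its rate constants are chosen.

Two finite state-space constructions realize $M$ as a matrix:

* **closed-conserved** — all states compatible with declared conservation
  groups (the trimolecular cycle with total $T$ has
  $(T+1)(T+2)/2$ states);
* **truncated-box** — all states within per-species bounds, with
  *reflecting truncation*: jumps that would leave the box are removed from
  both the flux and the escape rate, which keeps $M$ a proper generator
  (the alternative, absorbing truncation, destroys the zero column sums
  and with them every spectral statement above).

States are enumerated lexicographically so that indices, and hence Schur
forms, are reproducible run to run.

## Moment closures and what they miss

Raw-moment derivatives follow exactly from the master equation,
$d\langle n^m\rangle/dt = \sum_j \langle a_j(n)\,[(n+S_j)^m - n^m]\rangle$,
which `deriveMoments()` expands symbolically with an internal
exponent-matrix polynomial engine (exact expansion; no truncation happens
at this stage). For mass action up to trimolecular steps, the derivative of
an order-$|m|$ moment involves raw moments of order at most $|m|+2$, so the
hierarchy never closes on its own. `closeSystem()` applies
*central-moment neglect* at order $q$: central moments above $q$ are set to
zero and the higher raw moments re-expressed through tracked ones. Order
$q=1$ reproduces the classical rate equations — propensities evaluated at
the means — which is why rate-equation limit cycles and master-equation
decay can coexist: the closure discards exactly the fluctuation couplings
that dephase the ensemble.

Frequencies and decay rates of a closure are read off the leading complex
eigenvalue pair of the numerically evaluated Jacobian at a fixed point
(found by damped Newton iteration seeded from the time average of an
integrated trajectory, with a pseudo-inverse step when conservation makes
the Jacobian singular). A curve-fit of the integrated moments is used as a
cross-check in the tests, not as the primary definition: the Jacobian route
is deterministic and has no window-choice ambiguity. For closed
autocatalytic systems, closures above first order routinely produce
moment trajectories that blow up in finite time; the workflow records these
as non-converged rather than treating them as errors, since the breakdown
is itself the phenomenon (probability mass concentrates on absorbing
states, which no low-order moment ansatz represents).

## Stochastic simulation and coherence metrics

`gillespieRun()` implements the direct method exactly: exponential waiting
times with rate $\sum_j a_j$, categorical reaction choice, termination at
the horizon or in a zero-propensity (absorbing) state. Ensembles derive
per-trajectory seeds from one base seed, so results are bit-reproducible
independent of execution order, and sample paths onto a uniform grid by
right-continuous step lookup (jump-process semantics).

Coherence is quantified three ways, deliberately redundant:

* a damped-sinusoid least-squares fit
  $A_0 e^{-\gamma t}\cos(\omega t + \phi) + c$ of the ensemble mean
  (`fitDampedOscillation()`), giving the ensemble frequency and decay;
* normalized autocorrelation (biased $1/L$ estimator, hence bounded in
  $[-1,1]$ and exactly 1 at lag zero), per-trajectory-averaged or on the
  mean signal — the two modes answer different questions and both are
  provided; for closed systems the per-trajectory estimator uses each
  trajectory's pre-absorption segment, because post-absorption constants
  are degenerate;
* per-trajectory sustained-amplitude ratios (late window over early
  window, half peak-to-peak), which separate the two decay mechanisms:
  ratios near 1 with a decaying mean signal dephasing (open systems),
  ratios near 0 signal genuine loss of individual oscillation (closed,
  absorbing systems). Trajectories flat in both windows have no defined
  ratio and are reported as NA with a count.

The fit needs care, not cleverness: the frequency is initialized from the
discrete-spectrum peak *and* its neighbours (spectral leakage makes any
single bin unreliable), the decay from the log-envelope slope snapped to
zero below $10^{-8}$ (tiny nonzero starts defeat the optimizer's parameter
scaling), time is shifted to start at zero before fitting (a far origin
makes the amplitude/decay and phase/frequency gradient columns collinear),
and the best of the multi-start fits by residual is returned with a
convergence flag — non-convergence is reported, never thrown.

## The coupling design

The design couples $M$ to an $l$-dimensional input $x$:
$\dot P = MP + B_1 x$, $\dot x = B_2 P + C x$, with $B_1$'s columns summing
to zero so that $\mathbf{1}^\top P$ stays 1. The analysis happens in
ordered real Schur coordinates $M = Q D_1 Q^\top$. LAPACK's Schur
reordering is not exposed in R, so the ordering is obtained by deflation:
$\mathbf{1}$ is a left null vector of $M$, hence its orthogonal complement
is an invariant subspace; Schur-factorizing the restriction and appending
$\mathbf{1}/\sqrt n$ as the last Schur vector puts the conservation zero
mode last *exactly*. Every other Schur vector is then orthogonal to
$\mathbf{1}$, so couplings built from those vectors conserve probability by
construction — this is how the zero-column-sum requirement on $B_1$ is
satisfied, not checked after the fact. Residual zero modes from absorbing
states remain inside the quasi-triangular block and are excluded from
targeting by a $10^{-8}$ magnitude filter.

**Real (direct-decay) modes.** Coupling a scalar mode $\sigma^{(1)} < 0$
through its Schur vector with $l = 1$ modifies only that mode's
characteristic factor,
$(\sigma^{(1)}-\lambda)(\sigma^{(2)}-\lambda) - q^{(1)}q^{(2)}$ — removing
the targeted row and column from a quasi-triangular matrix leaves the other
blocks' determinant product intact, so the rest of the spectrum is
preserved exactly (numerically: to the eigenvalue conditioning of the
non-normal $M$, about $10^{-5}$ on desk-scale examples). Purely imaginary
roots at a chosen $\omega^*$ require $\sigma^{(2)} = -\sigma^{(1)}$ and
$q^{(1)}q^{(2)} = \sigma^{(1)}\sigma^{(2)} - \omega^{*2}$, which is always
negative: the input must be unstable and the feedback negative. The product
is split antisymmetrically, $q^{(1)} = -q^{(2)} = \sqrt{-q^{(1)}q^{(2)}}$,
a conditioning choice — only the product is constrained. The design is
verified against the full spectrum of the assembled $A$ and fails loudly if
the leading real part exceeds $10^{-8}$; the leading eigenvalue is selected
with a $10^{-9}$ real-part tie tolerance so the designed pair beats the
exact zero modes that share $\mathrm{Re}\,\lambda = 0$.

**Complex (oscillatory-decay) modes.** For a $2\times2$ block, a
two-dimensional input with the second direction weakly coupled
($q_\beta^{(1)} = 0$) reduces the quartic factor to the cubic
$\lambda^3 + b\lambda^2 + c\lambda + d$ of the $3\times3$ system
$[[d_{\alpha\alpha}, d_{\alpha\beta}, q^{(1)}],
[d_{\beta\alpha}, d_{\beta\beta}, 0], [q^{(2)}, 0, \sigma^{(2)}]]$. The
purely-imaginary-pair criterion $bc = ad$, $b > 0$, $c > 0$ (equivalent to
the factorization $(\lambda + b)(\lambda^2 + c)$) is solved for the
coupling product by bracketed root search; since $b$ is constant and $c, d$
are affine in the product, the condition is affine and the bracket
collapses in one step — the search degenerates to a linear solve, except
when $\sigma^{(2)} = -d_{\alpha\alpha}$ makes the slope vanish, which is
reported as infeasible together with violations of $b, c > 0$. Feasibility
requires $\sigma^{(2)} < -\mathrm{tr}(\mathrm{block})$. A *positive*
product moves the targeted pair toward and onto the real axis instead:
oscillatory-mode suppression, reported with the achieved roots either way.

**Regimes and scaling.** The scalar-mode $2\times2$ reduction with trace
$\tau$ and determinant $\Delta$ classifies into oscillatory
($\tau^2 < 4\Delta$) versus not, stable versus not, with the coherent
boundary at $|\tau| \le 10^{-10}$ and $\Delta > 0$; boundary cells are
labelled "coherent" and excluded from open-region counts. The phase-diagram
frequency column reports $\sqrt\Delta$, exact on the coherent line (the
interface contract); off the line the oscillation frequency is
$\sqrt{4\Delta - \tau^2}/2$. On the zero-trace line the frequency at
distance $\epsilon$ below the critical product is exactly
$\sqrt\epsilon$, and the scaling fit returns the log-log slope over
user-chosen offsets.

## Coupled dynamics and its verification

Linear coupled systems with $n + l \le 500$ are propagated by
matrix-exponential stepping on the assembled $A$ (one `expm` of $hA$, then
matrix-vector recursion — exact on the grid to machine precision); larger
systems fall back to adaptive `lsoda`. Probability components can go
transiently negative under linear coupling — with a point-mass start and a
strongly excited design, substantially so. This is the linearized model's
honest behaviour; trajectories report it and nothing is clamped.

The convolution identity
$x(t) = e^{tC}x_0 + e^{tC}\int_0^t e^{-sC} B_2 P(s)\,ds$ serves as an
independent cross-check of the ODE route. Evaluated literally it is
numerically explosive whenever $C$ is unstable — which every coherent
design makes it — because the outer $e^{tC}$ multiplies quadrature residue
by $e^{\sigma^{(2)} t}$. `xIntegralSolution()` therefore evaluates the same
integral stepwise through the semigroup property, with fourth-order
(cubic-interpolant) Newton–Cotes per step and one-sided rules at the ends.
Early errors are still amplified by $e^{\sigma^{(2)}(t - s)}$ — that is a
property of the reconstruction problem, not of the scheme — so agreement at
the $10^{-6}$ level is asserted on horizons with
$\sigma^{(2)} T \lesssim 11$ and a few thousand grid points; the tests
state the sizes they use.

The tracked observable for design verification is a *state probability*
(the state carrying the targeted Schur vector's largest weight), not a
species expectation: for the trimolecular system the copy-number vector
$n_A$ is numerically orthogonal to the targeted mode's Schur vector, so the
designed oscillation is invisible in the species means — a useful reminder
that coherence lives in the full distribution. The sustained-amplitude
statistic compares the last two designed periods with the first two after a
transient exclusion of 20% of the horizon for the designed run; the
isolated reference is measured from $t = 0$ without exclusion, because its
entire signal *is* the transient (after the exclusion window it is flat to
roundoff and any ratio would be noise over noise). The initial input value
$x_0 = 0$ and a point mass at the nominal initial state are used; neither
is dictated by the design, which fixes eigenvalues, not initial
conditions.

With the cubic extension $\dot x = B_2 P + Cx - \kappa x^3$ and a design
tuned slightly into the growing regime, the amplitude saturates at a value
independent of the initial amplitude — the limit-cycle stabilization must
come from the non-Markovian side, since the Markovian side is intrinsically
linear.

## Fixtures, defaults, and what they do and do not show

No rate constants are inherited from outside the package; all fixture
constants are package defaults, chosen once:

* **trimolecular** ($A+B\to2A$, $B+C\to2B$, $C+A\to2C$): unit rates
  $\alpha=\beta=\gamma=1$, start $(10, 5, 5)$, conserved total 20. Unit
  rates are the symmetric point of the cyclic competition; the rate
  equations then orbit a center (frequency $\approx T\sqrt3/3$) while the
  master equation drains into the three absorbing single-species states.
* **Brusselator** ($2X+Y\to3X$ at $c_1/\Omega^2$, $X\to Y$ at $c_2$,
  reservoir $\rightleftharpoons X$ at $c_3\Omega$, $c_4$): $c = (1,3,1,1)$,
  the classical reduced parameters $a=1$, $b=3$, safely past the
  oscillatory onset ($b > 1 + a^2$), start $(1,1)$. $\Omega = 10$: at much
  smaller system sizes the combinatorial corrections
  ($x(x-1)$ versus $x^2$) push the rate-equation fixed point from a focus
  to a node, leaving the oscillatory-rate-equation premise of the whole
  comparison unsatisfied.
* **birth-death** and **two-state**: linear test networks whose moments
  and spectra are known in closed form.

SSA ensembles emulate intrinsic (copy-number) noise only, under constant
rate constants on a finite (conserved or truncated) state space. They do
not emulate extrinsic parameter fluctuations, time-varying environments,
spatial structure, or non-exponential waiting times; passing tests
demonstrate internal consistency of the simulator, the generator and the
closures under these idealizations, not fidelity to any particular
experimental system. Headline problem sizes — 1000-trajectory ensembles in
the figure-style workflows, 2000 trajectories for the simulator-versus-
exponential cross-check at total 6, conserved total 20 (231 states) for
the design — are the package's own desk-scale choices and are recorded in
each workflow's configuration.

## Known limitations

* Designs place eigenvalues; they do not shape amplitudes or initial
  conditions, and a targeted mode that the initial condition barely
  excites yields a correct but small oscillation.
* The linearized coupled model allows negative transient probabilities; a
  jump-process realization of the coupled system (rates modulated by $x$,
  which linear feedback can drive negative) is out of scope.
* Moment closures above order 1 can diverge for closed autocatalytic
  systems; this is reported, not repaired.
* Exact stationary distributions of open networks, time-dependent rates,
  and non-mass-action kinetics are out of scope.
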