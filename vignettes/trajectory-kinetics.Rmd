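---
title: "Quantifying ion-release kinetics from trajectory ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ion-release kinetics from trajectory ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msmflux)
```

## The analysis problem

Neurotransmitter transporters of the LeuT fold couple substrate transport to
sodium gradients; release of the Na$^+$ ion from the second sodium site
(Na2) into the cytoplasm is the committed first step of the transport cycle.
Ensemble molecular dynamics — dozens of independent trajectories of order a
microsecond each — can observe this release spontaneously, but a single
trajectory says little: the kinetics and the release *routes* must be
estimated from the whole ensemble. msmflux implements that estimation chain:

1. **Structural observables** — residue contact maps ("closest heavy atom"
   minimum distances), ensemble-averaged *interaction strengths* between
   charged residue groups, salt-bridge gate distances with broken fractions,
   and an ion-release distance coordinate.
2. **Thermodynamic projections** — population free-energy profiles
   $\Delta G = -RT\,\ln(\mathrm{population})$ with block-bootstrap errors.
3. **Kinetics** — tICA reduction to the slowest linear coordinates, k-means
   microstates, a Markov state model (MSM) validated by implied timescales,
   PCCA+ macrostates, and transition-path-theory (TPT) committors, fluxes
   and ranked release pathways.

Because real trajectory data of this size cannot ship with a package, the
`synthetic_data` generators produce ensembles with *known* kinetic ground
truth emulating the study design (50 trajectories, $\sim$1 µs each), so
every stage can be verified end to end.

## Interaction strengths and gates

The interaction strength between two charged-residue groups counts, per
frame, residue pairs whose *head-group atoms* — NZ for Lys, CZ for Arg, CD
for Glu, CG for Asp — lie within a cutoff of **7 Å** (inclusive at the
boundary; the boundary convention is ours, the cutoff is the field's).
Counts are summed over the analysis window, by default the **500–940 ns**
interval of each trajectory so that every trajectory contributes equally
after discarding equilibration, and the total is divided by the number of
trajectories. The error bar is the *population* standard deviation of the
per-trajectory totals — the spread "across the 50 trajectories", not a
standard error of the mean.

Gate status uses the same geometry: a salt bridge (e.g. R60–D436,
E428–R445, K66–D345) is "broken" when its head-group distance exceeds the
same 7 Å. The broken fraction is the per-trajectory fraction of frames
averaged over trajectories; its confidence interval resamples whole
trajectories with replacement (1000 iterations by default), because frames
within a trajectory are strongly correlated and only the trajectory level is
exchangeable.

```{r gates}
syn <- releaseSystem(syntheticSpec(nTrajectories = 10, nFrames = 500,
                                   seed = 1))
gs <- newGateSeries(lapply(trajectories(syn$features),
                           function(m) m[, "R60-D436"]),
                    thresholdA = 7, name = "R60-D436")
bf <- brokenFraction(gs, nBoot = 500, seed = 2)
round(c(fraction = bf$fraction, bf$ci), 1)
```

## Free-energy projections

Populations on a binned coordinate are converted with
$\Delta G = -RT \ln p$ at $T = 310$ K using
$R = 0.0019872$ kcal mol$^{-1}$ K$^{-1}$, shifted so the occupied minimum
is 0. Empty bins are *flagged*, never assigned a finite energy. Errors come
from a block bootstrap: each replicate concatenates 100 contiguous blocks of
160 ns drawn from random positions in random trajectories, and the per-bin
spread across replicates is reported. Blocks of 160 ns are long relative to
the fast gate dynamics, so the replicates approximate independent draws of
the slow content of the data; with the default 0.8 ns frame interval a
block is exactly 200 frames.

## tICA

With mean-free features $X_t$, the covariance $C$ and time-lagged
covariance $C_{TL}$ (lag 16 ns by default) define the generalized
eigenproblem $C_{TL} V = C V \Lambda$; the leading eigenvectors are the
slowest linearly decorrelating coordinates. Estimator choices:

* lagged pairs are pooled within trajectories only — mixing across
  trajectory boundaries would fabricate transitions;
* $C_{TL}$ is symmetrized, $(C_{TL}+C_{TL}^{T})/2$, so the spectrum is
  real — the non-symmetric estimator is noisy and can go complex;
* $C$ gets a ridge $\epsilon = 10^{-10}\,\mathrm{tr}(C)/d$ by default, and a
  singular $C$ without regularization is an error, not a silent
  pseudo-inverse;
* eigenvectors are $C$-orthonormal, sorted by descending eigenvalue, and
  sign-fixed so each vector's largest-magnitude component is positive
  (signs of eigenvectors are otherwise arbitrary);
* no kinetic-map rescaling of the projections: components are raw
  eigenvector projections.

Trajectories shorter than the lag are excluded with a warning rather than
an error — a deliberately permissive choice for ragged real ensembles.

## Markov state model

The reduced coordinates are discretized by k-means (k-means++ seeding, Lloyd
iterations, default 100 microstates; final assignment is nearest-centre
with ties to the lowest index so a fixed seed is fully reproducible).
Transitions are counted with a *sliding window* — every frame pair
$(t, t+\tau')$ — and restricted to the largest strongly connected component
before row-normalizing into the transition probability matrix (TPM).
Estimation is deliberately **non-reversible**: plain row normalization, no
detailed-balance maximum likelihood (a symmetrized option exists but is off
by default). Validation uses the implied-timescale relation

$$\tau_i = -\frac{\tau'}{\ln \lambda_i},$$

computed across a ladder of lag times; the model is accepted at the
smallest lag from which the slowest timescale is lag-independent within a
relative tolerance (default 10%), requiring at least two supporting lags —
the last lag alone is never evidence of a plateau. Eigenvalues at 1 give an
infinite timescale, non-positive real eigenvalues are reported as
undefined, and complex pairs (possible for non-reversible estimators) use
the modulus. The sign structure of the second right eigenvector labels the
two sides of the slowest relaxation (e.g. ion bound vs released), with the
global sign fixed so the largest-magnitude entry is positive.

## PCCA+ and transition-path theory

Macrostates come from PCCA+ on the leading right eigenvectors: rows of the
eigenvector matrix are mapped onto the simplex spanned by the most
spread-out rows (inner-simplex vertex search) giving fuzzy memberships that
sum to 1 by construction; crisp states are the argmax. We use the
inner-simplex variant without the subsequent membership optimization — for
metastable spectra it already reproduces block structure exactly, which the
test suite checks for 2–5 blocks at coupling $10^{-3}$. The macrostate TPM
aggregates the microstate TPM with stationary weights over the crisp
lumping.

TPT between a bound set $A$ and a released set $B$ (defined by which side
of the release threshold a macrostate's mean ion distance falls) computes
forward/backward committors by direct linear solves, gross fluxes
$f_{ij} = \pi_i q^-_i T_{ij} q^+_j$, net fluxes
$f^+_{ij} = \max(0, f_{ij}-f_{ji})$, and decomposes the net flux network
into ranked pathways by iterative bottleneck removal: repeatedly take the
widest (maximin-capacity) $A\to B$ path and subtract its bottleneck flux.
Ties are broken by fewest hops, then the lexicographically smallest state
sequence — implemented as a binary search for the bottleneck width followed
by a breadth-first search, so the tie-break applies to the *final*
bottleneck, not greedily per node. Pathway fractions are relative to the
total $A\to B$ flux, and `pathwayGrouping()` lets the analyst sum fractions
by declared gate-status annotations instead of the package guessing
structural categories.

## The synthetic release system

`releaseSystem()` emulates the statistical structure of the study design,
not its chemistry:

* **Ion coordinate**: a hidden two-state Markov chain (bound → released at
  0.004/frame, released → bound at 0.0004/frame) with Gaussian distance
  emissions, bound $3.0 \pm 0.3$ Å and released $12.0 \pm 1.0$ Å. The mean
  first-passage time is exactly $1/k_{\mathrm{off}} = 250$ frames and the
  two-state relaxation time $-1/\ln(1-k_{\mathrm{off}}-k_{\mathrm{on}})
  \approx 227$ frames (182 ns at the 0.8 ns frame interval) — both recorded
  in the returned ground truth together with per-frame basin labels.
* **Gates**: three independent telegraph processes at faster rates with
  closed/open emissions $4.0 \pm 0.25$ / $9.5 \pm 0.5$ Å, started from
  their stationary distributions so broken fractions are unbiased.
* **Beads**: a labelled bead model (57-residue N-terminal tail, the six
  gate partner residues with proper head-group atom names, two sodium
  beads) whose scheduled head-group distances reproduce the gate and ion
  coordinates exactly, so contact-based scoring can be verified against the
  feature-level ground truth.

A hidden-chain construction was chosen over a Langevin double well for the
flagship generator because it makes the kinetic ground truth *analytic*;
continuous metastable dynamics are available separately via
`brownianWells()` (Euler–Maruyama, with a hard stability guard on the time
step). Defaults mirror the emulated design: 50 trajectories × 1000 frames ×
0.8 ns. The frame interval is a convention (the source ensembles' stride is
not public knowledge); 0.8 ns was fixed once so that 160-ns bootstrap
blocks and 16-ns tICA lags are integer frame counts.

What passing tests on these fixtures do **not** show: real all-atom
ensembles have non-Gaussian emissions, correlated gates and ion dynamics,
many irrelevant fast degrees of freedom, and non-Markovian memory at short
lags. The generators probe the estimators, not the force field; conclusions
about a real transporter still require the implied-timescale plateau and
committor sanity checks on the real data.

## Randomness and reproducibility

Every stochastic operation takes an explicit seed; generators derive
per-trajectory child seeds as $(m \cdot 10007 + i) \bmod (2^{31}-1)$ from
the master seed $m$, so trajectory $i$ is independently regenerable.
Identical spec + seed reproduces ensembles bit for bit, and
`runPipeline()` refuses configurations that leave any stochastic stage
without a seed.

## Problem sizes

The test suite and the verification script run the flagship end-to-end
analysis at the emulated study size (50 × 1000 frames, 100 microstates) and
exercise the statistical checks at sizes chosen for tight sampling bounds:
$2\times10^5$-step chains for frequency recovery, $10^6$ pooled frames for
tICA closed forms, 100 random ≤6-state networks against brute-force TPT
references, and 100 repeated bootstrap-coverage experiments of 50
trajectories each. These sizes make the stated tolerances (10% kinetic
recovery, 5% tICA eigenvalues, $10^{-9}$ TPT oracle agreement) comfortable
rather than marginal.

## Known limitations

* Linear tICA only; no kernel or deep variants, no VAMP scoring.
* Non-reversible MSM estimation follows the row-normalization definition;
  Bayesian error bars and hidden Markov MSMs are out of scope.
* PCCA+ without membership optimization can mis-assign states in weakly
  metastable spectra; the macrostate count should not exceed the count of
  eigenvalues with positive real part (enforced).
* The neutral container stores coordinates as text at 32-bit precision;
  it trades compactness for portability and diffability.
* No trajectory alignment or periodic-boundary imaging: structural inputs
  are assumed pre-imaged.
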