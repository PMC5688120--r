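---
title: "Markov state modelling of kinase conformational ensembles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov state modelling of kinase conformational ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinemsm)
```

# The problem

Protein kinases such as Bruton's tyrosine kinase (BTK) interconvert between
an active conformation and several inactive ones (a Src-like state with a
folded activation loop, a DFG-out state that opens an allosteric drug
pocket) on microsecond-to-millisecond timescales.  Unbiased molecular
dynamics reaches those timescales only as swarms of much shorter
trajectories, so the field's standard inference chain is: turn coordinates
into internal-coordinate features, find the slowest collective coordinates
(tICA), discretize them (K-means), estimate a reversible Markov state model
(MSM) at a fixed lag, and read thermodynamics and kinetics off the
transition matrix's spectrum.  `kinemsm` implements that chain end to end,
together with kinetic Monte Carlo (KMC) synthesis, mean first passage times
(MFPT), trajectory-level bootstrap uncertainty, and — crucially — a
synthetic-data module with *known* thermodynamics and kinetics so that every
stage can be validated by parameter recovery rather than by eyeballing.

# The model chain

## Markov state model

A MSM propagates state probabilities at a lag $\tau$:
$p(t+\tau) = p(t)\,T(\tau)$.  We estimate $T(\tau)$ from sliding-window
transition counts $C_{ij}$ (every frame pair $(t, t+\tau)$ within a
trajectory; pairs never cross trajectories), restricted to the largest
strongly connected component ("ergodic trim"), by maximum likelihood under
detailed balance $\pi_i T_{ij} = \pi_j T_{ji}$.  The constrained MLE uses
the classical self-consistent iteration on symmetric edge weights
$x_{ij}$,

$$x_{ij} \leftarrow \frac{C_{ij} + C_{ji}}{c_i/x_i + c_j/x_j},
\qquad T_{ij} = x_{ij}/x_i, \qquad \pi_i = x_i / \textstyle\sum_k x_k,$$

iterated until the log-likelihood moves by less than `tol` (default
`1e-10`; the iteration is deterministic, so reruns are bit-identical).
When the count matrix is symmetric the fixed point is plain row
normalization, which the tests exploit as a closed form.  Relaxation
timescales come from the spectrum via $t_i = -\tau / \ln \mu_{i+1}$,
computed on the $\pi$-symmetrized matrix
$D^{1/2} T D^{-1/2}$ so the spectrum is real by construction; a
symmetrization residual above $10^{-6}$ signals broken reversibility and is
an error, not a warning.

## tICA

Slow coordinates are linear combinations $\nu^\top X$ maximizing lagged
autocorrelation, obtained from the generalized eigenproblem
$C(\tau)\,\nu = \lambda\,\Sigma\,\nu$ with
$\Sigma_{ij} = \mathrm{E}[X_i(t) X_j(t)]$ and
$C(\tau)_{ij} = \mathrm{E}[X_i(t) X_j(t+\tau)]$, both mean-free and pooled
across trajectories.  Design choices the problem statement leaves open:

* **Symmetrization.** $C(\tau)$ is symmetrized as $(C + C^\top)/2$ before
  solving — the standard reversible estimator; the eigenproblem presumes a
  symmetric pencil.
* **Regularization.** $\Sigma$ is replaced by
  $(1-\gamma)\Sigma + \gamma\,\mathrm{diag}(\Sigma)$ with $\gamma = 10^{-8}$
  by default.  High-dimensional MD feature sets are rank-deficient at finite
  samples; the shrinkage makes the Cholesky reduction well-posed while
  perturbing eigenvalues at the $10^{-8}$ level (the duplicated-feature test
  exercises exactly this failure mode).
* **Sign convention.** Each eigenvector's largest-magnitude loading is made
  positive, so projections are reproducible across platforms.
* **Kinetic mapping.** With the flag on (the default, matching the selected
  model hyperparameters), component $i$ is scaled by $\lambda_i$, so
  Euclidean distances in tIC space approximate kinetic distances; component
  variances then equal $\lambda_i^2$ instead of 1.
* **Lags.** tICA and MSM lags are expressed in ns in configuration and
  converted through the frame interval `dt`; they must be positive integer
  multiples of `dt` (validated before any compute).  The package defaults
  carry the selected hyperparameters of the BTK study (tICA lag 208 ns,
  3 components, kinetic mapping, 190 clusters, 80 ns Markov lag); fixture
  runs use 240 ns, the nearest multiple of the fixture's 80 ns frame
  interval.

Only dense tICA is implemented; the sparse variant used for
interpretability in the original study is a different algorithm and out of
scope here.

## Discretization and macrostates

K-means uses k-means++ seeding at a fixed seed plus Lloyd refinement, best
of 10 restarts.  The seeding matters scientifically: a 1%-population
metastable state is a small, distant blob in tIC space, and uniform random
starts essentially never grant it a center, silently deleting the state
from the model.  D²-weighted seeding finds it reliably, and the
lowest-inertia restart keeps it.

Microstates are lumped to macrostates either by explicit user predicates
over cluster centers (which must partition the centers — unmatched or
doubly matched centers are an error listing the offenders), or, on
synthetic data, by majority vote against the generator's labels.  No
automated lumping (PCCA-style) is attempted: the four-state definition
(active / intermediate / Src-like / DFG-out) is an input, not an output.

Macrostate populations are sums of $\pi$; free energies are
$G_i = -k_\mathrm{B}T \ln(p_i/p_\mathrm{ref})$, with the reference
defaulting to the highest-populated state and, for cross-ensemble
comparisons, pinned to the *reference ensemble's* top state so that
$\Delta\Delta G$ values are directly comparable.  All temperatures default
to 300 K ($k_\mathrm{B}T = 0.596$ kcal/mol); the analysis temperature is a
parameter everywhere.

## Kinetics and uncertainty

KMC trajectories are sequential categorical draws from the rows of
$T(\tau)$ (compiled code; a 10,000-frame trajectory at the 80 ns lag spans
800 μs).  MFPTs solve $m_i = \tau + \sum_j T_{ij} m_j$ off the sink set
with $m = 0$ on it; a source *set* is summarized by the stationary-weighted
average over its members (weights renormalized within the set).  The DFG-in
source set pools all three DFG-in macrostates — the source weighting is not
specified in the study being emulated, and this is the documented choice.

Bootstrap uncertainty resamples **whole trajectories** with replacement
(respecting autocorrelation), re-runs counting → trimming → reversible MLE
per round on the fixed discretization, and reports the median with the
2.5/97.5 percentile interval (the sub/superscript convention of the
reported numbers).  The discretization itself (tICA + K-means) is fit once:
the state definitions are shared across rounds exactly as they are shared
across ensembles, and re-fitting them 200 times would change the question
being asked, not just the cost.  Rounds whose resample disconnects a needed
state are skipped and counted, never imputed.

## Cross-validation

Hyperparameters are compared by trajectory-level k-fold cross-validation
with a variational score (GMRQ style): the training model's leading
$m$ eigenvectors are evaluated under the test fold's overlap and lagged
correlation matrices, giving a generalized Rayleigh-quotient trace that
equals the sum of the top $m$ eigenvalues on-sample and penalizes overfit
state definitions out of sample.  The exact scoring function of the
original study is in supplementary material that is not available; the
GMRQ-style score is the published method its references point to and is the
documented stand-in.

# The synthetic ground truth

`build_kinase_chain()` turns per-state free energies $G_i$ and symmetric
barrier heights $B_{ij}$ into a discrete-time transition matrix with
Metropolis-like rates $T_{ij} = c\,\exp(-(B_{ij}-G_i)/k_\mathrm{B}T)$.
Because $\pi_i T_{ij} \propto e^{-B_{ij}/k_\mathrm{B}T}$ is symmetric,
detailed balance and the Boltzmann stationary distribution hold *by
construction*, to floating-point accuracy — the generator is the oracle.

`calibrate_btk_chains()` builds the two packaged four-state fixtures on the
hub topology (the intermediate connects to active, Src-like and DFG-out; no
other edges):

* free energies from Boltzmann inversion of the target populations —
  ASP (deprotonated): active 7%, intermediate 40%, Src-like 52%, DFG-out 1%;
  ASH (protonated): 6% / 38% / 47% / 9%;
* the intermediate–DFG-out barrier tuned by 1-D root finding so the
  DFG-in → DFG-out MFPT equals 1.2 ms (ASP) and 300 μs (ASH) at the 80 ns
  lag.

Two consequences are then *derived*, not imposed: protonation stabilizes
DFG-out by $-k_\mathrm{B}T\ln(9/1) \approx -1.31$ kcal/mol, and the reverse
(DFG-out → DFG-in) MFPTs come out at 12 μs (ASP) and 29 μs (ASH).  On a
4-state hub the forward/reverse MFPT ratio is pinned near
$\pi_\mathrm{DFG\text{-}in}/\pi_\mathrm{DFG\text{-}out}$, so the reverse
times are fully determined once populations and forward targets are set;
both land inside the reported 95% intervals (10–40 μs and 20–40 μs), which
is the property the tests assert.

`expand_chain()` splits each macrostate into 3 fast-exchanging microstates
(12 in total): populations split exactly ($G + k_\mathrm{B}T\ln 3$), and
cross-macrostate barriers are offset by $k_\mathrm{B}T\ln 9$ so the 9
microstate pairs carry the same total flux as the parent edge — the macro
kinetics of the calibrated chain are preserved while clustering and lumping
stay non-trivial.

## Emissions, and what the defaults mean

`default_emission_spec()` emits isotropic Gaussian features: the four
macrostate means sit on a tetrahedron in the first three of $d = 20$ signal
dimensions, microstates are offset within later dimensions, and 30
pure-noise dimensions are appended, so tICA must find exactly three slow
directions among distractors.

The macrostate separation default is **16 emission standard deviations**,
and this number is load-bearing.  For a state of population $p$ at mean
distance $d$ from the rest, the best linear projection's autocorrelation is
attenuated by $B/(B+\sigma^2)$ with $B = p(1-p)d^2$: at $p = 0.01$ and
$d = 6\sigma$ that is a factor 0.26, the DFG-out process drops out of the
tICA spectrum, and K-means deletes the state — no downstream estimator can
recover information the featurization has destroyed.  At $d = 16\sigma$ the
attenuation is mild and recovery is unbiased.  The large separation is also
the physically realistic regime: structural order parameters such as the
DFG RMSD move by 5–8 Å between metastable states against sub-Ångström
in-state fluctuations.

What the generator does *not* emulate: continuous within-state dynamics
(emissions are i.i.d. given the state, plus a separate AR(1) module used as
the tICA closed-form oracle), non-Gaussian feature distributions,
state-dependent noise, and the microstate heterogeneity of a real 190-state
model.  Passing recovery tests therefore demonstrates estimator
correctness, not that real MD data are this easy.

# Featurization

Coordinate trajectories carry an explicit topology (author residue
numbering; 539 is the DFG aspartate in the BTK convention).  Implemented
order parameters follow the standard switch definitions: A-loop RMSD
(heavy atoms 539–559), DFG RMSD (539–541), P-loop RMSD (410–415), R-spine
RMSD (residues 540, 449, 519, 460), and the two C-helix salt bridges
(Glu439 Cδ–Arg468 Cζ, Glu445 Cδ–Lys430 Nζ), all RMSDs to a supplied
double-helical inactive reference after Kabsch superposition.  Open choices
and their resolutions:

* RMSD superposition fits on the measured motif by default; fitting on all
  heavy atoms is available (`fit = "all"`), since the original figure
  caption does not state the fit set.
* The moving average is trailing over 10 frames (the caption says only
  "across 10 frames"); the first $w-1$ entries average the available
  prefix.
* Dihedrals are emitted as $(\sin, \cos)$ pairs (continuous across the
  periodic boundary) with the IUPAC sign convention, cross-checked against
  an independent normal-vector formula and `bio3d::torsion.xyz`.
* The original 5,532-long feature vector depends on unspecified atom
  selections and cannot be reproduced exactly; feature selection is
  configurable and this limitation is documented rather than papered over.

# Numerical choices and degenerate inputs

* Zero-variance features are scaled by 1 and flagged, never divided by.
* Zero populations map to $G = \infty$, not an error.
* tICA eigenvalues $\le 0$ have no timescale and map to `NaN`; eigenvalues
  $\ge 1$ map to `Inf`.
* Ties in the ergodic trim (equal component sizes) break toward the
  component with more counts.
* `mle_reversible` caps at $10^6$ sweeps and reports the last delta on
  non-convergence; all fixtures converge in far fewer.
* Every stochastic step (sampling, emission, seeding, restarts, bootstrap)
  takes an explicit seed; identical seeds give bit-identical results, which
  the pipeline tests assert literally.

# Problem sizes

The validation suite runs the full pipeline at 100 trajectories × 5,000
steps (5 × 10⁵ frames, 50 features) with 200 bootstrap rounds, the KMC
first-hit oracle at 10⁵ walkers, and the AR(1) tICA oracle at 10⁶ frames —
sizes chosen so the whole suite completes in minutes on one CPU while
leaving the rare-state (1%) observables enough events (~30 independent
DFG-out episodes) for their confidence intervals to be meaningful.  At that
scale the DFG-out population CI is wide (roughly ±40% relative), which is a
property of the study conditions, not of the estimator: each trajectory is
3.75 times shorter than the forward DFG MFPT, exactly the regime MSMs exist
for.

# Worked example

```{r example, eval = FALSE}
chains <- calibrate_btk_chains()
micro  <- expand_chain(chains$asp)
labs   <- sample_discrete(micro, n_steps = 5000, n_trajs = 100, seed = 1)
feats  <- emit_features(labs, default_emission_spec(micro), seed = 2)

cfg <- pipeline_config(tica_lag_ns = 240, n_components = 3, n_clusters = 12,
                       msm_lag_ns = 80, bootstrap_rounds = 200)
res <- run_pipeline(feats, cfg,
                    ref_labels = lapply(labs, function(s) micro$macro_labels[s]))
res$bootstrap

mfpt(chains$ash, c("active", "intermediate", "src_like"), "dfg_out") / 1e3
```

# Known limitations

* No sparse tICA, PCCA lumping, transition-path theory, Bayesian MSM
  posteriors, or hidden Markov models.
* The generator's discrete-state + Gaussian emission world is far kinder
  than MD data; see the emissions section for what that implies.
* `compare_ensembles` assumes both ensembles are featurized identically and
  that the shared discretization is meaningful for both; an ensemble losing
  a macrostate after trimming yields `NA` for that state's
  $\Delta\Delta G$ rather than a guess.
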