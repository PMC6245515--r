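---
title: "Coevolution-guided coarse-grained folding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coevolution-guided coarse-grained folding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(defold)
```

`defold` implements a template-free protein structure prediction pipeline:
evolutionary couplings inferred from a family alignment and torsion angles
predicted from sequence features are converted into restraint potentials
that drive a coarse-grained Monte Carlo sampler, and the resulting ensemble
is clustered to select blind-prediction models. This vignette documents the
models, their assumptions, the tunable parameters, and the design choices
made where the method left them open.

## Alignment filtering and reweighting

The input is a multiple sequence alignment of the query's family (FASTA,
A3M, or Stockholm; A3M insert states are removed so all rows align to query
columns). Two trimming rules are applied, by default columns first:

* **Columns** whose gap count strictly exceeds 50% of the rows are removed
  (`filter_columns`, `max_gap_fraction = 0.5`). A column at exactly the
  threshold is kept — the rule is "more than".
* **Sequences** whose gap fraction over the query's non-gap columns
  strictly exceeds 30% are removed (`filter_sequences`,
  `max_gap_fraction = 0.3`). The published wording is ambiguous between
  ">30% gaps" and "<30% aligned coverage"; we adopt the former, symmetric
  with the strictly-greater column rule, and keep boundary cases. Both
  readings are reachable through the threshold knob. The query row is never
  deleted.

Redundancy is then down-weighted at 80% identity: each row's weight is the
reciprocal of its neighborhood size, and the effective depth `m_eff` is the
weight sum (`compute_weights`). The source protocol does not state a
reweighting step, but direct-coupling estimates degrade badly on redundant
alignments, so it is on by default and can be disabled
(`identity_threshold = NULL`).

Throughout, the gap is a 21st state (`q = 21`), which keeps the empirical
marginals normalized on gapped columns.

## Coupling inference

The sequence family is modelled by the pairwise maximum-entropy (Potts)
distribution

$$P(A_1,\dots,A_L) = \frac{1}{Z}\exp\Big(\sum_{i<j} e_{ij}(A_i,A_j)
 + \sum_i h_i(A_i)\Big),$$

fit by pseudo-likelihood maximization (`fit_plm`): the sum of weighted
per-site conditional log-likelihoods is maximized with L-BFGS
(`stats::optim`), starting from zero parameters, with L2 penalties
$\lambda_h = 0.01$ on fields and $\lambda_e = 0.01\,(L-1)$ on couplings.
The method statement itself names no regularization, but the unpenalized
finite-sample optimum diverges on columns with unobserved states, so a
small ridge is required; the $(L-1)$ scaling keeps the per-conditional
penalty balanced as chains grow. The fit is returned in the zero-sum gauge
(all coupling blocks have zero row/column means, fields have zero mean),
which fixes the model's gauge redundancy without changing the distribution.

Pairs are scored by **direct information**,

$$DI_{ij} = \sum_{A,B} P^{dir}_{ij}(A,B)\,
 \ln\frac{P^{dir}_{ij}(A,B)}{f_i(A)f_j(B)},$$

where $P^{dir}_{ij}(A,B) \propto e^{e_{ij}(A,B)}\,\mu_i(A)\,\mu_j(B)$ and
the auxiliary factors $\mu$ are fixed-point iterated (tolerance $10^{-6}$,
at most 500 iterations) until the two-site marginals match the empirical
single-site frequencies. DI is gauge-invariant and non-negative. An
APC-corrected Frobenius norm of the coupling blocks is available as an
alternative ranking (`apc_frobenius`); DI is the default. A small
pseudocount (`lambda = 0.01`) on the marginals keeps the fixed point
well-behaved on sparse columns.

The top $2L$ pairs with sequence separation $|i-j| \ge 5$ become contact
restraints. The separation floor is not stated in the protocol; without it,
trivially coupled near-diagonal pairs crowd out tertiary contacts. It is
configurable (`min_separation`), and the synthetic-recovery checks use 2,
matching their planted-pair constraint $|i-j|\ge 2$.

## Torsion-angle prediction

Each residue is described by 24 features in $[0,1]$ (20 position-specific
scores, 3 secondary-structure probabilities, 1 solvent accessibility);
these are *inputs* — the external predictors that generate them are not
run here. A window of 17 residues on each side of the target yields the
$35 \times 24$ input patch, zero-padded off-chain (zero is the
normalization floor).

The predictor is a small 1-D convolutional network: 16 width-5 filters
sliding along the window rows, max-pool of width 2, then two further
convolutional layers (width-3 filters, 32 and 64 channels, each pooled),
then two fully-connected layers ending in four linear outputs
$(\sin\phi, \cos\phi, \sin\psi, \cos\psi)$. The sin/cos encoding removes
the angular discontinuity; predictions are decoded with the quadrant-aware
arctangent after renormalizing each pair to the unit circle. The channel
counts and pooling of the deeper layers are our choice — the published
figure fixes only the first layer — and are recorded in the network
configuration.

Weights are initialized from a zero-centered Gaussian with standard
deviation $5/N$ ($N$ = layer fan-in), the stated rule taken literally;
because $\sqrt{5/N}$ is the more conventional scaling and may have been
intended, it is available as `init = "sqrt5/N"`. Both are seeded. Training
(`train_torsion_net`) minimizes the mean squared error of the raw sin/cos
4-vector with full-batch Adam; the loss construction is ours (the protocol
does not state one), and angles are decoded only for evaluation. Since no
neural-network library is available to R here, the forward pass, analytic
backpropagation, and Adam are implemented in the package in batched base-R
array algebra; the architecture is small enough that this is fast.

Accuracy is summarized by the mean absolute error
$\mathrm{MAE} = \frac{1}{N}\sum_i |P_i - E_i|$ with terminal residues
excluded by the caller (their dihedrals are undefined). By default the
difference is the minimal circular one (170° vs −170° scores 20°); the
literal non-periodic form is available with `periodic = FALSE`.

## Restraints

Predicted torsions become flat-bottom wells: zero penalty inside
$[\hat\alpha_i - 20°, \hat\alpha_i + 20°]$ (circularly wrapped) and a
quadratic wall $k_{tor}\,\Delta^2$ outside, with
$k_{tor} = 0.05$ energy/deg². The protocol gives only the ranges; the
smooth wall is our choice of penalty, guiding the sampler toward the
intended Ramachandran region without hard rejection.

Pairwise interactions use the two-sigmoid potential

$$V(r) = \frac{e_{in}}{1+\exp((r-r_{in})/w_{in})}
 + \frac{e_{out}}{1+\exp((r-r_{out})/w_{out})}.$$

Two profiles carry the printed constants: side chains
($e_{in}=3$, $w_{in}=0.2$, $e_{out}$ = pair attraction from the contact
energy table, $r_{out}=6.5$ Å, $w_{out}=0.2$) acting between virtual
Cβ atoms, and backbone hydrogen bonds
($e_{in}=6$, $r_{in}=1.4$, $w_{in}=0.1$, $e_{out}=-4$, $r_{out}=2.5$,
$w_{out}=0.125$) acting between amide H and carbonyl O. The side-chain
$r_{in}$ ("the distance between pairwise amino acids") is read as a
residue-pair contact radius and defaulted to a uniform 6.0 Å; a per-pair
table can be supplied. The repulsive inner sigmoid doubles as the excluded
volume — there is no hard-sphere check.

The packaged 20×20 pair-attraction table is a **synthetic stand-in**
derived from Kyte–Doolittle hydrophobicity (more hydrophobic pairs more
attractive, range −0.5 to −2.4, with a Cys–Cys bonus), shipped as
`contact_energies_synthetic.tsv`. It plays the role of the
Miyazawa–Jernigan statistical potential in the published force field;
users with the published table can pass it via `energy_table`.

Each inferred contact adds a single stabilizing sigmoid well
$V(r) = -\,depth/(1+\exp((r-7.5)/width))$ on the Cβ–Cβ distance: strongly
negative at or below the 7.5 Å contact radius, vanishing above it
(defaults: depth 2.0, width 0.5 Å). The published supplementary form of
this restraint is unavailable; this well is the documented stand-in and
reproduces the stated behavior (stronger stabilization at ≤ 7.5 Å, weaker
beyond).

## Coarse-grained sampler

The chain is represented by backbone N, Cα, C per residue with ideal bond
lengths and angles and a trans peptide bond; only the torsions
$(\phi_i, \psi_i)$ are degrees of freedom. Carbonyl O, amide H, and a
virtual Cβ are derived from the backbone frame (the Cβ construction is
applied to glycine too, so burial and contacts are defined uniformly).

The energy is additive:

$$V = V_{torsion} + \sum_{|i-j|\ge 3} V_{ij}^{sc} + \sum_{|i-j|\ge 3}
V_{ij}^{hb} + \sum_i w_{env}(a_i)\,N_i + V_{contact}.$$

The burial count $N_i$ smoothly counts Cβ neighbors within ~8 Å of residue
$i$, weighted toward the hemisphere above its Cα→Cβ axis:
$N_i = \sum_{|i-j|>2} S(d_{ij}-8\,\text{Å},1\,\text{Å}) \cdot
S(-\cos\theta_{ij}+0.1,\,1)$ with $S(x,w)=1/(1+e^{x/w})$. Relative to the
published form this collapses the side-chain rotamer average to the single
ideal Cβ direction with unit probability — the central simplification of
the representation — and chooses the hemisphere sign so that partners on
the side-chain side count more. The environment energy is linear,
$w_{env}(a_i)\,N_i$ (the published functional form of the environment term
is not given); the per-residue weights take the sign of Kyte–Doolittle
hydrophobicity (burial favorable for hydrophobics) with magnitude 0.1,
switchable off. Four opaque simulator constants printed in the protocol
(−4.0, 0.2, 0.65, 3.0) are carried verbatim in the configuration and not
otherwise interpreted.

Sampling replaces the original molecular-dynamics engine with
**torsion-space Metropolis Monte Carlo**: each step perturbs one randomly
chosen angle by a Gaussian proposal (σ = 5°), rebuilds the chain by
forward kinematics, and accepts with probability
$\min(1, e^{-\Delta V/T})$. This preserves the Boltzmann target and the
restraint semantics without reimplementing the integrator, and is the
package's central dynamical simplification; bond geometry is exact by
construction, and runs are bit-reproducible per seed. The default
temperature is 1.0 in the (dimensionless) energy units of the restraints,
and the published "duration time of 500,000" is mapped to Monte Carlo
steps. The energy of a stored conformation is evaluated from its
coordinates, so it is invariant under rigid motions.

The full protocol launches 500 trajectories from the same extended state
(φ = ψ = 180°), capturing a frame every 500 steps; the desk-scale preset
used by the tests runs 8 trajectories of 2,000 steps. Trajectories are
independent chains, so results do not depend on execution order.

## Model selection

The last 50 frames of each trajectory are pooled (500 × 50 = 25,000 at
full scale), and the pool is clustered on the pairwise Cα-RMSD matrix by
greedy neighbor-count clustering at a 3.5 Å cutoff: repeatedly take the
structure with the most neighbors within the cutoff as a cluster center,
assign its neighbors, remove them, and iterate. The published work names
external clustering software without parameters; this greedy scheme is the
deterministic standard for simulation ensembles. Clusters are ordered by
size with ties broken by lower centroid energy; a cluster's centroid is
the member minimizing mean RMSD to the rest, and that mean is reported as
the cluster's tightness (the published "tightness" measure is unnamed;
mean intra-cluster RMSD is our proxy). Centroids of the top 5 clusters are
the blind-prediction models.

Evaluation uses Kabsch superposition RMSD (SVD with reflection guard) and
the TM-score with $d_0 = 1.24\,(L-15)^{1/3} - 1.8$, floored at 0.5 with a
warning for chains too short for the standard formula; the superposition
is refined iteratively on the subset of residues within a distance cutoff,
seeded from the global and half-chain fits. The pairwise RMSD matrix is
$O(N^2)$; a warning fires above 5,000 structures and a stride option
sub-samples the pool.

## Synthetic data

Every stage is testable offline against generators with known ground
truth:

* `plant_potts` / `sample_potts_msa` — alignments drawn from a Potts model
  with planted ferromagnetic pairs (separation ≥ 2). Systems with
  $q^L \le 2^{20}$ are sampled by exact enumeration of the state space —
  this also serves as the brute-force oracle for the coupling-inference
  tests — larger ones by vectorized parallel Gibbs chains with a 200-sweep
  burn-in. The positive-control conditions are q = 4, L = 12, 6 planted
  pairs of strength 2 over weak random fields (sd 0.3), n = 2,000
  sequences.
* `make_toy_fold` — idealized β-hairpin and helix–loop–helix folds built
  from canonical torsions, with native Cβ contacts (≤ 7.5 Å, |i−j| ≥ 3)
  and torsions recomputed from the coordinates. The folding positive
  control restrains a 16-residue hairpin with its native contacts and
  ±20° native-centered torsion wells and asks that at least half of 20
  seeded 50,000-step runs reach < 2 Å Cα-RMSD to the construction target
  at some captured frame.
* `make_feature_table` — normalized 24-column feature tables; the
  angle-linked rule embeds sin/cos of target torsions in the first four
  columns, making the targets recoverable by construction.
* `make_mock_trajectories` — Gaussian torsion perturbations of a base
  fold, for exercising pooling and clustering without the sampler.

What these fixtures do *not* emulate: the statistics of real homology
searches (phylogenetic correlations beyond simple redundancy, alignment
errors), real feature predictors (whose errors are structured, not
uniform), and real protein energetics. Passing tests therefore demonstrate
the correctness of the inference, sampling, and selection machinery under
controlled conditions — not prediction accuracy on real proteins, which in
the published setting required family alignments up to hundreds of
thousands of sequences and 500 long simulations per target.

## Numerical choices and scale

* Pseudo-likelihood optimization: zero initialization, L-BFGS with
  convergence factor 1e9, at most 500 iterations; non-convergence raises
  an error carrying the gradient norm.
* DI fixed point: tolerance 1e-6, 500 iterations, pseudocount floor on
  marginals.
* Sigmoid evaluations clamp exponents at ±40 to avoid overflow.
* Contact ranking breaks ties by ascending (i, j); clustering breaks size
  ties by centroid energy, then first occurrence — all outputs are
  deterministic.
* Degenerate inputs fail loudly: empty alignments, all-gap columns,
  mismatched lengths, out-of-range contact indices, zero sin/cos pairs.
* Test/vignette problem sizes (our choice of desk scale): alignments of
  150–2,000 rows, chains of 12–16 residues, ensembles of 3–20 trajectories
  of 2,000–50,000 steps, pools up to 25,000 mock structures. The
  statistical-mechanics check uses a single restrained torsion over 10⁶
  steps, whose flat-bottom wall at vanishing width is the quadratic well
  $V = k\Delta^2$ with Boltzmann variance $T/(2k)$.

## Known limitations

* The Metropolis sampler explores more slowly than a well-tuned MD
  integrator on rugged landscapes; at the default temperature the folded
  basin is reached but frames fluctuate around ~3 Å from an idealized
  target for the 16-residue control.
* The single-Cβ burial term is a coarse proxy for rotamer-averaged
  desolvation.
* The synthetic contact-energy table preserves only the hydrophobicity
  structure of the statistical potential it stands in for.
* TM-score refinement searches a small set of superposition seeds; for
  adversarial geometries the reported score is a lower bound on the true
  maximum.

## A minimal run

```{r example, eval = FALSE}
hp <- make_toy_fold("hairpin", 16, seed = 1)
pl <- plant_potts(L = 16, q = 4, n_pairs = 5, strength = 2, seed = 2)
write_msa(sample_potts_msa(pl, 150, seed = 3), "family.fasta")
write_feature_table(make_feature_table(16, "angle-linked", seed = 4),
                    "features.txt")

cfg <- default_config("desk")
res <- run_pipeline(hp$sequence, "family.fasta", "features.txt",
                    out_dir = "run1", config = cfg,
                    reference = hp$conformation$CA)
res$report
```
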