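---
title: "Robust collaborative matrix factorization for miRNA-disease association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust collaborative matrix factorization for miRNA-disease association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcmf)
```

## The problem

Experimentally confirmed miRNA-disease associations (MDAs) cover a small
corner of the plausible association space: a typical curated adjacency
matrix $Y \in \{0,1\}^{n \times m}$ (miRNAs in rows, diseases in columns)
is over 95% zeros, and a zero means *unobserved*, not *absent*. The task
is bipartite link prediction: score every unobserved pair so that true
but unrecorded associations rank high. Two side sources of information
help: a miRNA functional similarity matrix $S_m$ (consumed as input, e.g.
MISIM scores) and a disease similarity matrix $S_d$, either supplied or
derived from a disease-ontology DAG.

## The model

The core is a collaborative matrix factorization. Two low-rank factor
matrices $A \in \mathbb{R}^{n \times k}$ (miRNAs) and
$B \in \mathbb{R}^{m \times k}$ (diseases) are sought with
$AB^{\mathsf T} \approx Y$, while similar entities are pushed toward
similar latent vectors through $S_m \approx AA^{\mathsf T}$ and
$S_d \approx BB^{\mathsf T}$. The robust variant (RCMF) adds an
$L_{2,1}$ penalty on $B$,
$\lVert B \rVert_{2,1} = \sum_i \lVert b_i \rVert_2$, which drives whole
disease rows toward zero and suppresses uninformative or outlying
profiles:

$$
\min_{A,B}\;
\lVert Y - AB^{\mathsf T}\rVert_F^2
+ \lambda_l\!\left(\lVert A\rVert_F^2 + \lVert B\rVert_F^2\right)
+ \lambda_l \lVert B\rVert_{2,1}
+ \lambda_d \lVert S_m - AA^{\mathsf T}\rVert_F^2
+ \lambda_t \lVert S_d - BB^{\mathsf T}\rVert_F^2 .
$$

Dropping the $L_{2,1}$ term gives the classical CMF baseline
(`variant = "CMF"`). The same weight $\lambda_l$ multiplies the Tikhonov
and the $L_{2,1}$ terms; `rcmfConfig(lambda21 = ...)` decouples them for
experimentation, since tying them is a modelling convention rather than a
necessity.

### Solver

`rcmf()` initializes from the rank-$k$ truncated SVD,
$A = U_k S_k^{1/2}$, $B = V_k S_k^{1/2}$, the Frobenius-optimal rank-$k$
start. It then alternates closed-form updates obtained by zeroing the
gradient of each factor's subproblem with the other factor (and the
coupled occurrences of the factor itself) frozen at the previous iterate:

$$
A \leftarrow (YB + \lambda_d S_m A)\,
(B^{\mathsf T}B + \lambda_l I_k + \lambda_d A^{\mathsf T}A)^{-1},
$$

and, row-wise for $i = 1 \dots m$ with
$M = Y^{\mathsf T}A + \lambda_t S_d B$ and
$G = A^{\mathsf T}A + \lambda_l I_k + \lambda_t B^{\mathsf T}B$,

$$
b_i \leftarrow m_i\,(G + \lambda_l d_{ii} I_k)^{-1},
\qquad d_{ii} = \frac{1}{2\max(\lVert b_i \rVert_2,\ \varepsilon)} .
$$

The $d_{ii}$ are the iteratively-reweighted-least-squares (IRLS)
surrogate of the non-smooth $L_{2,1}$ penalty; $\varepsilon = 10^{-8}$
smooths the derivative singularity at zero rows, and the CMF variant
simply sets every $d_{ii} = 0$. Because the $d_{ii}$ differ per row, the
$B$ update is solved through one symmetric eigendecomposition of $G$
plus a diagonal rescale per row, rather than $m$ separate factorizations.

Three numerical choices matter:

* **Safeguarding.** The closed-form updates are fixed-point steps, not
  guaranteed descent steps: with large similarity weights
  ($\lambda_d, \lambda_t \gtrsim 10^{-1}$) they can overshoot. Each
  half-step is therefore accepted only if it does not increase the
  objective (up to a $10^{-12}$ relative slack for roundoff); otherwise
  the step is halved toward the previous iterate, up to 30 times. In the
  small-weight regime used for association data the safeguard never
  triggers, and the objective trace is non-increasing by construction.
* **Convergence.** Iteration stops when the relative objective change
  falls below `tol` ($10^{-6}$ by default; on association-scale data the
  trace flattens after a few dozen iterations, and `maxIter = 200`
  leaves generous headroom), with a tiny absolute floor so that exactly
  factorizable inputs terminate immediately.
* **Degeneracy.** Linear systems are solved, not inverted; a
  condition-number guard (estimate $> 10^{12}$) switches to a
  pseudoinverse with a warning. An objective increase above 10% in one
  iteration aborts with a diagnostic — with the safeguard in place this
  is unreachable except through non-finite inputs.

The latent dimension $k$ is not part of the published protocol for this
model family; the default `k = min(n, m, 50)` keeps the factorization
genuinely low-rank on realistic matrices while never exceeding the data's
dimensions. It is exposed everywhere and can be added to the grid search.

## Similarities

**Disease semantic similarity** comes from a child→parent ontology DAG.
Within the sub-DAG of ancestors of a disease $t$, each term's
contribution is $\Delta$ times the best contribution among its children
in that sub-DAG (1 for $t$ itself), so a term at shortest-path depth $h$
contributes exactly $\Delta^h$; summing contributions gives the semantic
value $DV(t) \ge 1$. Two diseases are similar in proportion to their
shared ancestry:

$$
S_d(i, j) = \frac{\sum_{t \in T(i) \cap T(j)}
\left(D1_i(t) + D1_j(t)\right)}{DV(i) + DV(j)} .
$$

$\Delta = 0.5$ by default, the standard choice for disease-ontology
semantic scores; the matrix is symmetric with unit diagonal by
construction, and diseases with disjoint ancestry score 0.

**GIP kernels.** The Gaussian interaction profile kernel scores two
entities by the distance between their association profiles:
$K(i,j) = \exp(-\gamma\lVert y_i - y_j\rVert^2)$ with
$\gamma = \gamma' / \overline{\lVert y_i \rVert^2}$ and $\gamma' = 1$,
i.e. the bandwidth is normalized by the mean squared profile norm — the
construction standard throughout the MDA literature. An all-zero matrix
has no profile scale and is rejected.

**Integration.** How the functional/semantic similarities and the GIP
kernels combine into the single $S_m$ and $S_d$ the objective uses is a
genuinely open convention; both common readings are implemented and the
choice is an explicit flag. `mode = "mean"` (the default) averages the
two sources elementwise; `mode = "gip_fill"` uses the primary similarity
where defined and the GIP value elsewhere, the convention of several
related methods. Every run log records the mode used.

## WKNKN preprocessing

Before factorization, `wknkn()` raises likely-missing zeros. For each
miRNA, the $K$ most similar miRNAs *with at least one known association*
(self excluded, ties broken by label order) vote with weights
$p^{t-1} S_m(i, i_t)$, normalized by the plain similarity sum; the
disease side is symmetric over columns; the two one-sided estimates are
averaged and the entry becomes the maximum of its original value and the
average. Defaults $K = 5$, $p = 0.7$ are the stability region of the
published sensitivity analyses, and `sensitivitySweep()` reproduces such
sweeps. Both sides read the *original* matrix, which makes the operator
order-independent; known 1s are never modified, so imputation is
monotone and idempotent on complete data.

## Evaluation protocol

`runCv()` implements CV-p: the known *pairs* (1 entries) are partitioned
into 5 near-equal folds, repeatedly. For each fold the held-out pairs
are zeroed in the training copy, and — to keep test labels out of the
training pipeline — the GIP kernels, the similarity integration and the
WKNKN imputation are all recomputed from the training matrix only. A
literal once-globally preprocessing would leak held-out labels through
the imputed values; the per-fold reading is the defensible one and is
what the package does. Held-out positives are scored against all
never-known pairs (the standard CV-p negative set), the per-repeat AUC
is the mean over folds, and the result reports mean and standard
deviation over repeats, matching the usual "mean(sd)" presentation. AUC
is the rank-based Mann–Whitney statistic with ties counted half. Fold
assignment derives one RNG substream per repeat from a single integer
seed, so results are reproducible bit for bit. Desk-scale runs default
to 10 repeats; the full published protocol (100 repeats) is one argument
away.

`gridSearch()` sweeps $\lambda_l \in \{2^{-2}, 2^{-1}, 2^0, 2^1\}$ and
$\lambda_d, \lambda_t \in \{0, 10^{-4}, 10^{-3}, 10^{-2}, 10^{-1}\}$ by
default (the published grids; the two similarity weights share one grid)
and breaks AUC ties toward smaller weights.

## Synthetic fixtures and what they show

`makePlanted()` generates the study conditions used throughout the tests
and the acceptance script: nonnegative Gamma-distributed rank-2 factors,
thresholded to exactly 15% density on a 40×30 grid, 1% flipped entries
as label noise, 10% of true positives masked and recorded as held out,
and GIP kernels of the noiseless truth standing in for the functional /
semantic similarities. This emulates the low-rank-plus-noise structure
the method assumes, at desk scale. It does **not** emulate the skewed
degree distribution of curated association databases, the block
structure of disease families, or annotation bias, so passing recovery
tests demonstrate correctness of the machinery — not clinical-grade
accuracy on real data. The demonstration configuration
(`k = 10`, $\lambda_l = 0.5$, $\lambda_d = \lambda_t = 10^{-2}$) was
fixed once by a coarse grid search on a pilot instance and is used
unchanged everywhere.

### The robustness experiment

To exhibit what the $L_{2,1}$ term buys, `makeLineCloud()` samples 200
points exactly on the line $y = x$ ($x$ uniform on $[0, 20]$) plus 0-80
noise points displaced off the line, and `robustnessExperiment()` fits a
rank-1 factorization under each variant (similarity terms off) and
reports the angle between the learned one-dimensional subspace and
$(1,1)/\sqrt2$. Three design choices deserve justification:

* **Orientation.** The cloud enters the factorization as a 2×N matrix —
  points as columns — so that the penalized factor $B$ carries *one row
  per point*. Row sparsity can then downweight individual outlying
  points, which is precisely the robustness mechanism being probed; with
  points as rows the penalized factor would have only two rows (the
  coordinates) and the two variants would be indistinguishable. The
  subspace and its angle do not depend on the orientation.
* **One-sided noise.** Noise offsets are uniform on $(0, \text{spread})$
  *above* the line (spread defaulting to half the inlier range).
  Zero-mean symmetric noise exerts no net pull on any least-squares
  direction estimate, so a symmetric design could never show one variant
  drifting and the other resisting; a directional contamination can.
* **Scale normalization.** The cloud is normalized to unit
  root-mean-square point norm before fitting, which makes the reported
  angle exactly invariant to global rescaling of the data (otherwise the
  fixed $\lambda_l$ would change meaning with the coordinate units).

With no noise both variants recover the direction to well under a
degree; with 80 noise points the RCMF angle is consistently at or below
the CMF angle (compared as medians over 20 seeded clouds, the stable
summary for a heavy-tailed angle distribution). The margin is modest —
the mechanism suppresses only points with small latent coefficients —
and the experiment is a qualitative ordering, not an effect-size claim.

## Degenerate inputs and tie-breaking

Unknown identifiers, misaligned labels, cyclic "DAGs", non-binary raw
association files, asymmetric similarity files and all-zero association
matrices are hard errors with located messages. Neighbor ties in WKNKN
and score ties in rankings break by label order; fewer available known
neighbors than $K$ uses all of them with a warning; a row or column with
no known neighbor simply contributes nothing. Symmetry and unit-diagonal
checks use an absolute tolerance of $10^{-9}$.

## Known limitations

* The published headline benchmark (AUC ≈ 0.93 on an HMDD-derived
  495×383 matrix with 5430 associations) requires that curated dataset;
  the package reproduces the protocol, not the dataset. Supplying the
  matrices as TSV and running `rcmf cv --repeats 100` executes the full
  protocol.
* One iteration costs $O(nmk)$ for the reconstruction terms plus
  $O(n^2 k)$ / $O(m^2 k)$ for the similarity couplings when
  $\lambda_d, \lambda_t > 0$ — the often-quoted $O(nmk)$ holds only
  without the similarity terms. Desk-scale problems (hundreds by
  hundreds) fit comfortably; tens of thousands of entities would not.
* Test and acceptance problem sizes (12×9 oracle fixtures, 40×30
  pipeline instances, 10 CV repeats, 20-seed Monte-Carlo summaries) are
  the package's chosen desk-scale study conditions; they are stated here
  so that larger reruns are a deliberate act, not a surprise.
* The $L_{2,1}$ robustness mechanism acts through latent coefficient
  shrinkage; it is not a heavy-tailed noise model, and contamination
  aligned with the signal subspace is not suppressed.

## A worked example

```{r example, eval = FALSE}
inst <- makePlanted(40, 30, kTrue = 2, density = 0.15,
                    noiseRate = 0.01, maskFraction = 0.1, seed = 1)
Sm <- integrateSimilarity(inst@Sm, gipKernel(inst@Y, "miRNA"), "mean")
Sd <- integrateSimilarity(inst@Sd, gipKernel(inst@Y, "disease"), "mean")
fit <- rcmf(wknkn(inst@Y, Sm, Sd), Sm, Sd,
            rcmfConfig(lambdaL = 0.5, lambdaD = 0.01, lambdaT = 0.01, k = 10))
fit
head(rankCandidates(predictScores(fit), "dis-001", inst@Y))
runCv(inst@Y, inst@Sm, inst@Sd,
      rcmfConfig(lambdaL = 0.5, lambdaD = 0.01, lambdaT = 0.01, k = 10),
      plan = cvPlan(5, 10, seed = 2))
```
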