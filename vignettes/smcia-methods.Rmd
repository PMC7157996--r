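---
title: "Sparse multiple co-inertia analysis: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse multiple co-inertia analysis: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smcia)
```

## The model

Multiple co-inertia analysis (mCIA) integrates $K \ge 2$ omics matrices
$X_k \in \mathbb{R}^{n \times p_k}$ measured on the same $n$ samples.  Each
block comes with a diagonal feature metric $Q_k$, all blocks share a
diagonal sample metric $D$, and dataset weights $w_k > 0$ sum to one.  The
first axis maximizes the weighted sum of squared covariances between each
transformed block and a common *synthetic center* $v$:

$$
\max_{v,\,u_1,\dots,u_K}\; \sum_{k=1}^K w_k \left(v^\top D X_k Q_k u_k\right)^2
\quad \text{s.t.}\quad u_k^\top Q_k u_k = 1,\; v^\top D v = 1 .
$$

Substituting $\tilde X_k = \sqrt{w_k}\, D^{1/2} X_k Q_k^{1/2}$,
$a_k = Q_k^{1/2} u_k$ and $b = D^{1/2} v$ turns this into a Euclidean
problem, $\max \sum_k (b^\top \tilde X_k a_k)^2$ with unit-norm
constraints, which is the representation every solver in this package
works in.  The classical solution is spectral: $b$ is the leading
eigenvector of $\sum_k \tilde X_k \tilde X_k^\top$ (computed on the
$n \times n$ Gram form, so cost scales with $n \sum_k p_k$), and
$a_k \propto \tilde X_k^\top b$.  Higher-order axes are obtained by
*deflation*: each block is replaced by the residuals of a $D$-weighted
regression of its columns on the current center scores, which makes
successive centers exactly $D$-orthogonal.

The sparse variant (smCIA) constrains each transformed loading to at most
$s_k$ nonzero entries, $\|a_k\|_0 \le s_k$; the structured variant
(ssmCIA) additionally subtracts a network penalty
$\lambda_k\, a_k^\top \tilde L_k a_k$ built from a prior feature graph.
Because the $Q_k$ are diagonal, the back-transformed loadings
$u_k = Q_k^{-1/2} a_k$ inherit the sparsity pattern exactly.  No sparsity
is placed on the center $b$.

## The alternating algorithm

Each sparse axis is fitted by block-coordinate ascent on the penalized
objective $\sum_k (b^\top \tilde X_k a_k)^2 - \sum_k \lambda_k a_k^\top
\tilde L_k a_k$:

1. **Center update** (exact): for fixed loadings, the optimal $b$ is the
   leading eigenvector of $\sum_k M_k$ with $M_k = \tilde X_k a_k a_k^\top
   \tilde X_k^\top$.  Since $\sum_k M_k = G G^\top$ for the $n \times K$
   matrix $G = [\tilde X_1 a_1 \cdots \tilde X_K a_K]$, we take the
   leading left singular vector of $G$.
2. **Loading updates** (truncated Rayleigh flow): for fixed $b$ and the
   other blocks, block $k$'s problem is an $\ell_0$-constrained Rayleigh
   quotient maximization with numerator $R_1 = g g^\top - \lambda_k
   \tilde L_k$, $g = \tilde X_k^\top b$, and identity denominator.

Blocks are updated in index order, $b$ first, and the loop stops when the
relative change of the penalized objective falls below `outer_tol`
(default $10^{-5}$) or after `outer_max_iter` (default 100) iterations.
The non-sparse mCIA axis is the warm start.  A per-block *ascent
safeguard* only accepts a loading update that does not lower its Rayleigh
quotient, which makes the outer objective non-decreasing by construction
— a property the test suite asserts on every fitted axis.  If a block's
gradient vector $g$ degenerates to zero (a block that carries no signal
for the current center), its loading is kept fixed and a warning is
emitted.

### The inner solver

`rifle_solve()` implements the truncated Rayleigh flow: a gradient step
on the quotient followed by hard thresholding to the $s$ largest
magnitudes (ties at the cutoff keep the lower index, so results are
deterministic) and renormalization,

$$
\omega \leftarrow \mathrm{HT}_s\!\left(\mathrm{normalize}\!\left(
\omega + \frac{\eta}{\rho}\,(R_1 - \rho I)\,\omega\right)\right),
\qquad \rho = \omega^\top R_1 \omega .
$$

The $1/\rho$ factor is the multiplicative form of the flow specialized to
an identity denominator metric.  We chose it over the plain additive
gradient step because it is invariant to the overall scale of $R_1$; the
additive form oscillates between supports whenever the penalty term makes
$\|R_1\|$ large.  It requires $\rho > 0$, so indefinite numerators are
shifted: adding $c I$ with $c \ge -\lambda_{\min}(R_1)$ adds exactly $c$
to every quotient, changes no iterate (the shift cancels inside the
gradient) and preserves the argmax.  The fitting path bounds the shift by
$\lambda_k$ times a Gershgorin row-sum bound on $\tilde L_k$, avoiding a
dense eigendecomposition; `shift_to_psd()` computes the tight shift for
dense use.  Stopping is on $|\Delta\rho| < 10^{-6}$ with a 1000-iteration
cap.

The flow is a local method.  Inside the alternating algorithm it is warm
started from the current loading, which is what makes the outer loop an
ascent.  Called standalone without an `init`, `rifle_solve()` runs a
small deterministic multi-start (the four leading eigenvectors of $R_1$,
coordinate vectors on its largest diagonal entries, and the constant
vector) and returns the best endpoint; on random symmetric $8 \times 8$
problems with $s = 3$ this matches exhaustive support enumeration in
$\ge 90\%$ of instances, which the acceptance tests verify.

## Weights and preprocessing

* Blocks are column-centered and scaled to unit sample standard deviation
  (denominator $n-1$).  Constant columns are an error: filter first, e.g.
  `variance_filter()` keeps the top fraction of features by variance with
  a deterministic tie rule (lower index wins at the cutoff).
* The default $Q_k$ weights each feature by its absolute column sum as a
  proportion of the block total, computed **after** standardization, so
  $Q$ is well defined for the matrix actually analyzed.  An identity
  option is available, and custom positive vectors are accepted.
* $D$ defaults to the identity; uniform $1/n$ weights are available
  behind a switch.  User-supplied $w$ is renormalized to sum to one;
  the default is $w_k = 1/K$.
* Missing values are rejected rather than imputed.

## Feature networks

A prior network for block $k$ is an undirected weighted graph on its
features.  Two Laplacians are available:

* **normalized** (default for user data): diagonal 1 for connected
  nodes, $-w(i,j)/\sqrt{d_i d_j}$ off-diagonal, all-zero rows for
  isolated nodes;
* **combinatorial**: $\mathrm{diag}(d) - W$, whose null space is spanned
  by component-wise constant vectors.

The built-in benchmark uses the combinatorial variant because its star
networks have *constant-within-network* true loadings, which are
penalty-free under the combinatorial Laplacian but not under the
normalized one (a star's normalized-Laplacian null vector is
$D^{1/2}\mathbf{1}$, not $\mathbf{1}$).  Both readings are exposed since
the two conventions genuinely differ here.

The penalty is evaluated in the transformed metric through
$\tilde L = Q^{-1/2} L Q^{-1/2}$, so that $a^\top \tilde L a =
u^\top L u$.  One practical consequence deserves emphasis: with the
default column-sum $Q$ (entries $\approx 1/p$), $\tilde L$ is inflated by
roughly a factor $p$ relative to $L$.  Useful values of $\lambda_k$ are
correspondingly *small* — the benchmark default is $10^{-3}$, chosen once
so the penalty term is commensurate with the co-inertia term, and the
benchmark's cross-validation grid spans $\{10^{-4}, 10^{-3}\}$.  With an
identity $Q$, values of order $0.1$–$10$ are the natural range.  `tune_smcia()`
deliberately leaves the grid to the caller.

`perturb_graph()` rewires a chosen fraction of edges (removals plus
uniformly random additions) to study robustness to partially incorrect
prior networks.

## Cross-validated tuning

`tune_smcia()` grid-searches sparsity budgets, penalty weights and step
sizes over $T$-fold splits ($T = 5$ by default) shared by all
combinations, so comparisons are paired.  Two readings of the printed CV
machinery in the source literature are ambiguous, and the package fixes
them as follows (recorded in the `interpretation` field of the result):

* the held-out statistic pairs the *trained* loadings with a center
  *recomputed on the test fold* by one exact center update — the minimal
  assumption that keeps the loadings strictly out of sample while
  respecting dimensions;
* the score aggregates the $T \times K$ held-out squared co-inertia
  values as mean/sd.  Co-inertia values are unbounded (unlike
  correlations), so the mean alone is not comparable across budgets;
  standardizing by the spread rewards combinations that are large *and*
  stable.  If all values coincide the score is $+\infty$ with a warning.

Ties break toward the sparser model (smaller total $s$), then smaller
total $\lambda$, then smaller $\eta$.  Because the per-block Cartesian
product grows quickly with $K$, `shared = TRUE` tunes one sparsity
fraction of $p_k$ and one $\lambda$ for all blocks.  Tuning is per axis:
to tune axis 2, deflate and tune again.

In our experiments the mean/sd score reliably ranks the oracle budget
above a one-feature candidate and selects it modally on strong-signal
data, but its discrimination against *denser* candidates is weak (their
held-out co-inertia is nearly as stable), so selected budgets err on the
generous side.  This is a property of the score, not of the optimizer.

## The synthetic benchmark

`sample_dataset()` draws from a latent-factor model: per sample a scalar
$\theta \sim N(0, \sigma^2)$ drives all blocks, $x_k = \theta a_k +
\epsilon_k$ with independent $\epsilon_k \sim N(0, \Sigma_k)$.  The
implied joint covariance has diagonal blocks $\sigma^2 a_k a_k^\top +
\Sigma_k$ and off-diagonal blocks $\sigma^2 a_l a_m^\top$; the test suite
verifies both empirically at $n = 50{,}000$ on small blocks.  The true
loadings are unit-normalized indicators of the first $n_{en} \cdot
n_{el}$ coordinates — $n_{en}$ "effective" star networks of $n_{el}$
features each, the first feature of each network being the hub.  Eight
benchmark scenarios cross $\sigma^2 \in \{1.2, 2.5\}$, $n_{el} \in \{10,
20\}$ and $n_{en} \in \{(3,4,5), (5,5,5)\}$ at $n = 200$,
$p = (300, 400, 500)$.

The generative description pins down only the *leading* eigenpair of
$\Sigma_k$ (it must be $a_k$).  The package takes the simplest consistent
completion, $\Sigma_k = I + \gamma\, a_k a_k^\top$ with $\gamma = 1$
(`gamma_extra`, configurable).  This choice matters: the achievable
estimation accuracy at $n = 200$ depends strongly on the unspecified
non-leading spectrum, so absolute Monte-Carlo numbers produced under this
completion are internally consistent but need not match numbers produced
under a different completion.  The estimator itself is consistent: the
test suite verifies that with blocks of dimension $(60, 80, 100)$ the
mean mCIA angle rises above $0.95$ as $n$ grows from $150$ to $1500$ at
$\sigma^2 = 1.2$.

`run_scenario()` drives the Monte-Carlo study: generate, standardize,
default weights ($D = I$, column-sum $Q$, equal $w$), fit the requested
methods, and score first-axis loadings against the truth — the absolute
cosine (angle) for all methods, plus support-recovery sensitivity,
specificity and Matthews correlation for the sparse ones (classical mCIA
is dense, so only its angle is meaningful).  Results come back as a tidy
tibble of means and standard errors; a master seed spawns per-replicate
substreams so any single replicate is independently reproducible.

What the generator does *not* emulate: heavy-tailed or count-valued
omics measurements, block-specific sample quality, batch structure,
overlapping or correlated networks, and feature-feature correlations
beyond the single spike.  Passing benchmarks here demonstrates correct
mechanics and calibrated behavior under the stated Gaussian model, not
performance on real sequencing data.

Problem sizes used by the automated checks were chosen to keep full runs
in the range of minutes on a single core: the solver-equivalence oracles
run on matrices up to $12 \times 9$ with exhaustive support enumeration
at $8 \times 8$; the generative checks use $n = 50{,}000$ with $p =
(8, 6)$; the Monte-Carlo comparison runs scenarios 1–4 at 100 replicates
for mCIA and scenario 3 at 25 replicates with a coarse shared CV grid
(fractions $\{0.05, 0.1, 0.2\}$, which contains the oracle fraction 0.1)
for the sparse methods.

## Evaluation conventions

* **Angle** is the absolute cosine between estimated and true loading:
  eigenvector-type solutions are sign-ambiguous, and without the absolute
  value arbitrary flips would corrupt Monte-Carlo means.
* **Support** uses exact zeros — the $\ell_0$ machinery produces exact
  zeros, so no epsilon thresholding is applied.
* **MCC** is defined as 0 when any factor of its denominator vanishes.
* **Percent explained** divides an axis's pseudo-eigenvalue (its
  co-inertia objective value, evaluable on training, held-out or whole
  data) by the total squared Frobenius norm of the transformed tables,
  i.e. the sum of all eigenvalues of the co-inertia operator.

## Numerical conventions and degenerate inputs

* Sign convention: each center is flipped so its largest-magnitude entry
  is positive; each loading is then flipped so its covariance with the
  center scores is nonnegative.
* Deflation residualizes every block on the *shared* center scores
  (guaranteeing $D$-orthogonal successive centers); residualizing each
  block on its own block scores is available behind `deflation =
  "block"` since the convention is genuinely ambiguous in the
  literature.
* `fit_mcia()` extracts at most $\min(n, \sum_k p_k)$ axes — the number
  of nonzero eigenvalues the operator can have; blocks whose rank is
  exhausted earlier contribute zero loadings to later axes.
* Eigen-solves use the symmetric $n \times n$ form with LAPACK defaults;
  reconstruction, orthogonality and consistency identities are asserted
  at $10^{-8}$–$10^{-10}$ in the tests.
* Non-convergence of the outer loop returns the best iterate with a
  warning and a flag on the axis rather than an error.

## Limitations

* Axes are extracted greedily with deflation, not jointly.
* The $\ell_0$ problems are NP-hard; the flow finds local optima, and the
  warm start (mCIA) determines which.  The multi-start default mitigates
  this only for standalone dense calls.
* The CV score's weak penalty on dense candidates (above) means selected
  $s_k$ should be read as upper bounds on the interesting support.
* The general (non-identity) denominator metric of the Rayleigh problem
  is represented in the API but deliberately not exercised.
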