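---
title: "Cherry and pitchfork counts as a balanced urn: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cherry and pitchfork counts as a balanced urn: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treeurn)
```

## The statistics and the two null models

A rooted binary phylogenetic tree on $n$ labelled leaves carries two
classic shape statistics: $B_n$, the number of **cherries** (fringe
subtrees with exactly two leaves) and $A_n$, the number of **pitchforks**
(fringe subtrees with exactly three leaves).  Both are widely used to
compare reconstructed trees against neutral null models, e.g. in studies
of pathogen transmission trees and of speciation models.

`treeurn` implements the two standard null processes.  Both grow a tree
one leaf at a time, starting from any tree with $m \ge 2$ leaves (the
default start is the unique two-leaf tree):

* **YHK** (Yule–Harding–Kingman): the new leaf is attached to a
  *pendant* edge chosen uniformly at random ($n$ candidates at size $n$);
* **PDA** (proportional to distinguishable arrangements): the new leaf is
  attached to *any* edge chosen uniformly at random.  The degree-one root
  $\rho$ is kept as a real vertex, so a rooted tree with $n$ leaves has
  $2n$ vertices and $2n - 1$ candidate edges — without the explicit root
  edge the PDA edge counts (and the associated urn below) would be wrong.

Label permutations play no role in any statistic computed here (all
statistics are shape functionals), so new leaves are labelled
sequentially `t3`, `t4`, …

## The edge-type urn

The law of $(A_n, B_n)$ depends on the growing tree only through a small
census.  Every edge belongs to exactly one of six types:

1. pendant edge in a *dependent* cherry (a cherry inside a pitchfork),
2. pendant edge in an *independent* cherry,
3. pendant edge in a pitchfork but not in a cherry,
4. pendant edge in neither,
5. internal edge adjacent to an independent cherry (its far-side subtree
   is exactly that cherry; the root edge of the two-leaf tree qualifies),
6. any other internal edge.

Writing $\alpha(T)$ for the counts of types 1–4 and $\beta(T)$ for all
six, the identities $A = \alpha_1 / 2$, $B = (\alpha_1 + \alpha_2) / 2$,
$\alpha_3 = \alpha_1/2$ and $\beta_5 = \beta_2/2$ hold on every tree.
Attaching a leaf to an edge of type $i$ changes the census by a fixed
integer vector — row $i$ of a replacement matrix $R$ — so the census
evolves as a **balanced Pólya urn** $C_k = C_{k-1} + \chi_k R$ in which
colour $i$ is drawn with probability $C_{k-1,i} / t_{k-1}$.  The YHK urn
uses the $4 \times 4$ pendant-type matrix with row sum $s = 1$
(`yhk_replacement_matrix()`); the PDA urn uses the $6 \times 6$ matrix
with row sum $s = 2$ (`pda_replacement_matrix()`).  Some rows contain
negative off-diagonal entries (attaching inside a pitchfork *removes*
type-1 edges), which is what puts these urns outside the classical
positive-replacement theory and motivates the extended assumptions below.

## Limit theory implemented

For a balanced urn satisfying

* (A1) *tenable* — the rules never drive a count negative,
* (A2) *small* — real spectrum with $\lambda_1 = s > 2\lambda_j$,
* (A3) *strictly balanced* — constant row sums, all-ones right principal
  eigenvector, stochastic left principal eigenvector $v_1$,
* (A4) *diagonalisable over the reals*,

the configuration obeys a strong law $C_k / (ks) \to v_1$ a.s. and a CLT
$(C_k - k s v_1)/\sqrt{k} \Rightarrow N(0, \Sigma)$ with

$$\Sigma \;=\; \sum_{i,j\ge 2}
  \frac{s\,\lambda_i \lambda_j\; u_i^\top \mathrm{diag}(v_1)\, u_j}
       {s - \lambda_i - \lambda_j}\; v_i^\top v_j ,$$

assembled from the non-principal eigen-pairs normalised so that
$v_i u_j = \delta_{ij}$.  `urn_spectral()` produces that normalised
eigensystem, `limit_law()` evaluates $s v_1$ and $\Sigma$, and
`project_law()` maps them to $(A, B)$ through
$L = \bigl(\begin{smallmatrix}1/2&0&\cdots\\ 1/2&1/2&\cdots\end{smallmatrix}\bigr)$:

```{r limits}
law <- ab_limit_law("yhk")
law$mean          # (1/6, 1/3)
1260 * law$Sigma  # ((69, -28), (-28, 56))
```

The YHK urn has eigenvalues $\{1, 0, -2, -3\}$ and
$v_1 = (1/3, 1/3, 1/6, 1/6)$; the PDA urn has $\{2, 0, 0, 0, -2, -4\}$
and $v_1 = (2,2,1,3,1,7)/16$, giving $(A_n, B_n)/n \to (1/8, 1/4)$ and a
diagonal projected covariance $(3, 0; 0, 4)/64$.  Because $\beta$ sums to
$2n - 1$, the per-leaf limit of the census is $s\,v_1$ (summing to 2),
and the CLT centering is $n s v_1$; the projections above are the checks
that fix this convention.

### Numerical choices

* **Two arithmetic paths.**  When the replacement matrix is integer with
  integer eigenvalues (both built-in urns), the whole spectral pipeline —
  null spaces, $U^{-1}$, $\Sigma$, projections — runs in exact rational
  arithmetic (numerators/denominators in doubles; every intermediate is
  tiny), so equalities like $1260\,\Sigma_{11} = 276$ are exact, not
  approximate.  Arbitrary matrices fall back to `eigen()` in double
  precision with a $10^{-9}$ tolerance for realness, biorthogonality and
  stochasticity checks.  Complex spectra are rejected with an error: the
  implemented theory assumes a real spectrum.
* **Repeated eigenvalues.**  The PDA urn has eigenvalue $0$ with
  multiplicity three.  The eigenbasis inside that eigenspace is not an
  observable; $\Sigma$ is.  The suite checks that the exact basis (from
  reduced row echelon form), the `eigen()` basis, and an independently
  published basis all give the same $\Sigma$ to $10^{-8}$.
* **Eigenvalue ordering** is descending; the principal eigenvector is
  replaced by the all-ones vector (its eigenspace is one-dimensional
  under A2), which fixes $v_1$ to be stochastic automatically.
* **Tenability (A1)** is undecidable from $R$ alone.  For the two
  built-in urns it is certified: their dynamics mirror an actual tree
  process whose census cannot go negative.  For user urns
  `check_assumptions()` probes it by simulation (default 100 trajectories
  of 200 steps) and reports "no violation observed" rather than a proof.

## Exact finite-$n$ law by dynamic programming

Because the transition law depends only on the census, the census is a
Markov chain on a polynomial state space ($O(n^2)$ reachable states,
versus the Catalan-sized shape space).  `evolve_distribution()` runs the
forward recursion **in exact rational arithmetic**: at step $k$ every
state probability has the common denominator $\prod_j t_j$, so the
compiled core only needs arbitrary-precision integer numerators with
addition and multiplication by small integers; a single gcd reduction per
reported quantity produces canonical `"p/q"` strings.  The denominators
are factorial-sized (about $10^{372}$ at $n = 200$), far beyond doubles
and beyond 128-bit integers, which is why the package carries a minimal
big-integer implementation in `src/bignum.h`.

`exact_joint_moments()` projects the DP law to exact moments of
$(A_n, B_n)$, and `closed_form_moments()` evaluates the published
closed forms (valid for $n \ge 7$) in the same exact arithmetic, e.g.

```{r moments}
print(exact_joint_moments("yhk", 20))
```

### A correction to the PDA closed forms

While validating the DP we found that two of the commonly printed PDA
moment formulas carry one-step denominator shifts.  Exhaustive
enumeration of all $3 \cdot 5 \cdot 7 \cdot 9 \cdot 11 = 10395$ equally
likely PDA growth paths to $n = 7$ — an independent code path that builds
every tree and counts subtrees directly — gives
$E(B_7) = 21/11$ and $V(B_7) = 140/363$, matching the DP and *not* the
printed $E(B_n) = \frac{n(n-1)}{2(2n-5)}$,
$V(B_n) = \frac{n(n-1)(n-2)(n-3)}{2(2n-3)^2(2n-7)}$.  The forms
implemented here are

$$E(B_n) = \frac{n(n-1)}{2(2n-3)}, \qquad
  V(B_n) = \frac{n(n-1)(n-2)(n-3)}{2(2n-3)^2(2n-5)},$$

together with the (verified as printed) pitchfork mean, the
$V(A)/V(B)$ polynomial factor, and $\mathrm{Cov} = -V(B)/(2n-7)$.  The
DP equals these forms exactly for every $n$ in $7..20$ (and the YHK
forms for $7..60$) in the test suite.  Both versions agree to leading
order, so the CLT limits are unaffected.

### Guards

The DP guard defaults to $n \le 200$ (YHK) and $n \le 25$ (PDA) and is a
plain argument: the PDA state space is the larger of the two per leaf and
these sizes keep any exact run in the test suite below a few seconds on
one core.  Beyond the guard, pass `guard =` explicitly; cost grows like
$O(n^3)$ states-times-steps with big-integer numerators whose length
grows linearly in $n$.

## Unrooted trees

Deleting $\rho$ and suppressing its child turns a rooted tree into an
unrooted one with $2n - 3$ edges; both growth processes run directly on
unrooted trees as well (`grow(..., rooted = FALSE)`), where unrooted
trees are stored handle-rooted at their lowest-labelled leaf.  Edge
typing is well defined only for $n \ge 6$ (at $n = 5$ the middle pendant
edge fits no type), which is why `exact_unrooted_shape_dist()` seeds the
unrooted analysis at $n = 6$: exhaustive path enumeration gives the two
shape atoms $\alpha = (4,0,2,0)$ and $(0,6,0,0)$ with exact
probabilities $4/5$ and $1/5$ under YHK.  All paths at a given size are
equally likely because the number of candidate edges depends only on the
size — that is what makes plain path counting exact.  From the $n = 6$
atoms onward the rooted urn machinery applies unchanged (the replacement
matrices are the same), so unrooted limits coincide with rooted ones.

## Simulation design

The growth hot loop is compiled (Rcpp) and consumes R's RNG stream via
`unif_rand()`, so a single `set.seed()` (or the `seed` arguments) makes
trees, replicate tables and whole experiment reports bit-reproducible.
Uniform edge choice indexes edges by internal vertex id, which is a
fixed, deterministic order — `enumerate_edges()` additionally exposes a
canonical depth-first order (children by smallest descendant label) for
user-facing listings and for the pure-R single steps `yhk_step()` /
`pda_step()`.  Those R steps are deliberately an independent
implementation of the same move; the suite checks the compiled and the
pure-R routes against each other and both against the exact DP law (at
$n = 8$, chi-square).

What the simulators emulate is exactly the two null processes — no
extinction, no sampling through time, no branch lengths, no rate
variation.  Agreement of the Monte-Carlo experiments with the analytic
law therefore validates the package's own machinery; it says nothing
about whether real phylogenies follow either null model (they generally
do not; that comparison is the *use* of these statistics, not their
validation).

## Experiments and tolerances

`run_slln_experiment()`, `run_clt_experiment()` and
`run_start_independence_experiment()` compare seeded simulations with
analytic targets that are recomputed from the urn engine on every call.
The tolerance policy is **3 standard errors** (`z_tol = 3`): for means,
the SE across replicates; for covariance entries, the normal-theory
$\sqrt{(\sigma_{jj}\sigma_{kk} + \sigma_{jk}^2)/m}$.  Normality is
summarised by Mardia's multivariate skewness and kurtosis (computed
in-package; the skewness double sum is evaluated in row blocks to keep
memory linear in the number of replicates).  The test suite runs the CLT
experiments at $n = 2000$ with $5000$ replicates per model and the
start-independence experiments (caterpillar versus balanced 8-leaf
starts) at $n = 2000$ with $2000$ replicates — sizes chosen so the whole
suite completes in about a minute on one core while keeping the
Monte-Carlo SEs well below the distances that would signal a real
defect.

## Known limitations

* Only binary trees; multifurcations are rejected at parse time.
* Branch lengths are read and discarded; there is no time-embedded
  (birth–death) simulation.
* The urn engine requires a real spectrum and rejects complex
  eigenvalues rather than implementing the complex-spectrum extension.
* Exact spectral arithmetic requires integer eigenvalues; other exact
  cases (rational but non-integer spectra) fall back to floating point.
* One-parameter deformations (Ford's alpha, Aldous' beta), $k$-pronged
  nodes and $k$-caterpillars, and phylogenetic networks are out of
  scope.
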