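---
title: "Sparse SVD integration of multi-omic blocks: model, tuning, and design"
author: "OmicSSVD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse SVD integration of multi-omic blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OmicSSVD)
```

## The model

`OmicSSVD` treats a multi-omic study as a single low-rank factorization
problem. Each omic block is a samples-by-features numeric matrix over the
same samples. Preprocessing maps the blocks into one extended matrix
$X \in \mathbb{R}^{n \times P}$, and the decomposition extracts $K$ latent
factors $(u_k, d_k, v_k)$ with unit-norm sample scores $u_k$, singular
values $d_k$, and feature loadings $v_k$ that are sparse: most entries are
exactly zero, so a factor is read as a short feature list plus a sample
gradient.

One factor solves, approximately,
$$\min_{u, \tilde v}\; \|X - u \tilde v^{\top}\|_F^2
  + 2\lambda\big(\alpha \|\tilde v\|_1 +
  \tfrac{1-\alpha}{2}\|\tilde v\|_2^2\big),$$
by alternating exact coordinate updates: $\tilde v$ is the elastic-net
proximal map of $X^{\top}u$, and $u = X v / \|X v\|$ with
$v = \tilde v / \|\tilde v\|$. Each update is a coordinate-wise minimizer,
so the penalized criterion is non-increasing along the iteration (a
property the test suite asserts from traced iterates). Convergence is
declared when the relative $L_2$ change in $v$ falls below `tol` (default
`1e-6`, capped at `maxIter = 1000` with a warning on non-convergence).
Subsequent factors repeat the procedure on the deflated residual
$X - \sum_{j<k} d_j u_j v_j^{\top}$.

### Assumptions

* Shared structure is (approximately) low-rank and linear after per-column
  standardization; features that load on a factor do so through
  cross-sample correlation.
* Noise is roughly exchangeable across samples within a feature; no
  heavy-tailed robustness is attempted.
* Sparsity lives on the feature side only. Sample scores stay dense —
  the selection question the package answers is "which features", not
  "which samples". (Sample-side sparsity is out of scope.)

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `alpha` | elastic-net mixing weight, unitless in $[0,1]$ | 1 | strict selection; values in $(0,1)$ trade selection for shrinkage when many features carry signal, e.g. 0.5 for dense signals |
| `lam` | penalty magnitude, on the scale of $X^{\top}u$ | 0 | unpenalized = dense SVD; set via `degree` in practice |
| `degree` | number of nonzero loadings per factor | tuned | the interpretable knob: "keep the top $k$ features" |
| `K` | number of latent factors | 2 | smallest interesting rank; raise until dense $d_k$ flattens |
| `tol` | relative $L_2$ change in $v$ | `1e-6` | loading support stabilizes well before this level |
| `candidateDegrees` | tuning grid | 20 log-spaced values in $[1, P]$ | log spacing matches the diminishing effect of added coordinates |

### Degree targeting and ties

A requested degree $k$ is converted to a data-driven magnitude
$\lambda^\ast = |w|_{(k+1)}/\alpha$, the $(k{+}1)$-th largest absolute
entry of $w = X^{\top}u$ (0 when $k = P$): soft-thresholding at
$\alpha\lambda^\ast$ then leaves exactly the $k$ largest entries nonzero
when magnitudes are distinct. The threshold is applied at
$|w|_{(k+1)}$ directly rather than through $\alpha \cdot (|w|_{(k+1)}/\alpha)$,
so the cutoff entry is zeroed exactly in floating point. Order statistics
break ties by smallest column index; entries exactly tied with the cutoff
shrink to zero, so under ties the realized nonzero count can fall below the
request — the deterministic price of an order-statistic rule. `alpha = 0`
with a degree target is rejected: ridge shrinkage cannot zero a
coordinate.

### Automatic tuning

With `penalty = "auto"` each factor's degree minimizes
$$\mathrm{BIC}(k) \;=\; \log\!\frac{\mathrm{RSS}_k}{nP}
  \;+\; k\,\frac{\log nP}{nP},
  \qquad \mathrm{RSS}_k = \|R - d u v^{\top}\|_F^2 ,$$
over the candidate grid ($R$ = current residual; smallest minimizer on
ties, for parsimony). Because the iteration ends with $u = Rv/\|Rv\|$ and
$d = u^{\top}R v$, the identity $\mathrm{RSS}_k = \|R\|_F^2 - d^2$ is
exact, and $\|R\|_F^2$ itself updates recursively as
$\|R_{\mathrm{new}}\|^2 = \|R\|^2 - d^2$; no residual matrix is ever
formed, which is what lets tuning run on chunked on-disk inputs. Tuning is
per factor: successive factors see different residuals and routinely want
different degrees.

On data with no low-rank signal the criterion curve is nearly flat. A
factor is flagged (and a warning raised) when its best candidate improves
on the null fit ($d = 0$) by no more than the leading singular value of an
equally sized pure-noise matrix would explain: the largest singular value
of an $n \times P$ unit-Gaussian matrix is about $\sqrt{n} + \sqrt{P}$, so
a drop in $\log \mathrm{RSS}$ below $(\sqrt{n} + \sqrt{P})^2 / (nP)$ is
indistinguishable from fitting noise. This threshold is this package's own
quantification of "no material improvement".

## Numerical design

**Initialization.** Every factor starts from the leading dense singular
pair of the current residual, computed by Golub–Kahan–Lanczos
bidiagonalization with full (two-pass) reorthogonalization. The start
vector is a fixed quasi-random sequence ($\sin j + \tfrac12\cos 2j +
10^{-3}$, normalized), so results are deterministic and contain no RNG
state; a fixed start is generic for the data-dependent singular subspaces
encountered in practice. The dense pairs double as the reported dense SVD.

**Accuracy.** Lanczos runs until the Ritz residual
$\beta_m |p_i[m]|$ of every requested triplet falls below
$10^{-11}\,\sigma_1$, capped at $\min(n, P, \max(250, 8K))$ steps. The
final triplets are recomputed by exact Rayleigh–Ritz over the full Krylov
basis (one block product), and if the residual criterion was not met —
typically when the Krylov space exhausts at $\min(n,P)$ steps, where
recurrence drift limits accuracy — the leading subspace is polished by
plain subspace iteration until the subspace angle moves less than
$10^{-10}$ per sweep. The unit tests pin the result to a LAPACK SVD at
$10^{-8}$ relative on singular values and $10^{-6}$ on principal angles.

**Deflation.** Implicit: products with the residual are computed as
$Xv - U\,\mathrm{diag}(d)\,(V^{\top}v)$, so chunked matrices are streamed,
never materialized. The exported `deflate()` gives the explicit in-memory
form. Because sparse factors are not exactly orthogonal, a later factor can
occasionally carry a larger $d$ than an earlier heavily-penalized one;
factors are therefore sorted by decreasing $d$ on output.

**Sign convention.** Each factor is flipped so its largest-magnitude
loading is positive; singular vectors are otherwise sign-ambiguous.

**Degenerate inputs.** An all-zero matrix is an error. Rank deficiency
pads zero singular values with deterministic orthonormal filler vectors. A
penalty so large that every loading is zeroed returns $d = 0$ with a
warning. Constant columns standardize to zero (with a warning) rather than
being dropped, keeping the column map aligned with the input feature ids.

## Preprocessing choices

"Standardized" is per-column z-scoring (mean 0, sample sd 1, divisor
$n-1$); "normalized" is division of each standardized block by its
Frobenius norm, so every block contributes equal total variance to the SVD
regardless of its feature count — the usual motivation in multi-block
factorization, and the reason a 200-feature proteomic panel is not drowned
by a 20 000-feature expression matrix. Missing entries are imputed by the
column mean over observed values (the mask is kept for provenance; a fully
missing column is an error). Confounders are removed by least-squares
residualization on an intercept-plus-covariates design (treatment-coded
factors, first level dropped), applied after imputation and **before**
standardization: adjustment on the original scale removes confounder main
effects from every feature, and the order is fixed here because the
alternative is not observationally distinguishable from the method's
description. Missing covariate values are an error rather than silently
imputed — covariate imputation distorts the adjustment it feeds. All
constants are stored, so `inverseTransform()` restores the input scale to
within rounding.

## The out-of-core backend

A `ChunkedMatrix` stores row chunks of float64 values in a flat
little-endian binary file with a JSON header (shape, dtype, chunk rows,
ids); read-back is bit-exact. Row chunking is chosen because both $Xv$ and
$X^{\top}u$ stream naturally over row blocks; all accumulation is in
float64, and peak resident data for a product is one chunk plus the
result. Since every routine touches data only through the
matvec/block-product operator layer, in-memory and chunked decompositions
are the same algorithm and agree to chunk-summation rounding — the test
suite checks equality at $10^{-8}$ across chunk sizes $\{1, 7, 64, n\}$.

## Downstream analysis

Clustering runs k-means (20 seeded restarts) on the variance-weighted
scores $U\,\mathrm{diag}(d)$ — weighting makes the partition invariant to
factor sign flips and, at isotropic $d$, to rotations — and selects the
number of clusters by mean silhouette width over a candidate range
(smallest $k$ on ties). Identical points yield a single-cluster result
with a warning rather than an error. The 2-D embedding is either the first
two weighted score columns or an exact $O(n^2)$ t-SNE (perplexity
calibration by bisection, early exaggeration 12 for 100 iterations,
momentum 0.5 to 0.8, 500 iterations, seeded initialization): latent score
matrices have one row per sample, so the exact gradient is affordable and
avoids approximation parameters.

## The simulation benchmark

`runFeatureBenchmark()` measures selection quality by shuffle
decorrelation: per replicate, a random fraction of features (10% by
default; 80% is the standard hard scenario) keeps its natural cross-sample
correlation while every other feature is independently row-permuted —
destroying its correlation with everything while preserving its marginal
distribution exactly. The matrix is standardized, decomposed at each
degree in a grid, and the union of nonzero loadings across factors is
scored against the informative set. Defaults follow the protocol this
reproduces: 1000 replicates, strict selection ($\alpha = 1$), replicate
$r$ seeded as `seed + r`.

The bundled generator `makeCorrelatedBase()` stands in for the real tumor
expression matrices the protocol was designed around: $X = LF^{\top} + E$
with standard-normal rank-$r$ structure (default $r = 3$, a few dominant
co-regulation axes, at a few hundred samples and features) and unit noise.
It reproduces the essential property the benchmark needs — genuine
cross-feature correlation destroyed by shuffling, with a known
independence baseline $E|r| \approx \sqrt{2/(\pi n)}$ — but not the
heavy tails, blockwise correlation structure, or batch effects of real
tumor data; passing benchmarks here demonstrate the selection mechanics,
not field performance on any particular cancer dataset.
`makePlantedRank1()` generates the complementary calibration instance: a
rank-1 spike of strength $d_0 = 5\sqrt{n}$ whose support loadings have
equal magnitudes $\pm 1/\sqrt{s}$ — Gaussian loadings would place
arbitrarily small signal on some support coordinates and make *exact*
support recovery an ill-posed target at any fixed strength.

## Problem sizes used by the tests

The suite exercises dense-SVD agreement on twenty random matrices up to
200 x 500, support recovery and degree tuning on 100 x 50 spikes (100 and
50 replicates), backend equivalence on a 2000 x 5000 matrix at four chunk
sizes, and the benchmark at 50 samples x 200 features with 25 replicates
per scenario — sizes chosen so the full suite documents every claim while
running comfortably on a laptop; all parameters scale up by argument.

## Known limitations

* No inferential support for the selected features (no p-values or
  bootstrap stability); selections are point estimates.
* One penalty for all blocks; per-block penalties are not implemented.
* Mean imputation is deliberate and simple; heavily missing data deserve a
  dedicated imputation method upstream.
* Supervised variants (PLS-style responses, discriminant analysis) are out
  of scope.
* With strict selection ($\alpha = 1$) sensitivity degrades as the
  informative fraction grows — the benchmark shows the 80% scenario
  trailing the 10% one; mixing weights between 0 and 1 recover sensitivity
  at the cost of exact zeros.
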