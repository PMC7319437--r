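---
title: "Clustering single-cell Hi-C data: models, parameters and validation"
author: "schicr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering single-cell Hi-C data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schicr)
```

## The problem

A single-cell Hi-C experiment yields, per cell, a sparse symmetric
matrix of contact counts between fixed genomic bins. At the working
resolution of 1 Mb a mammalian genome has a few thousand bins, so the
flattened per-cell feature space has millions of dimensions while each
cell contributes only $10^4$–$10^6$ reads. Grouping cells by chromatin
structure therefore hinges on dimension reduction; clustering the raw
vectors is supported but rarely advisable. `schicr` implements the
container, the per-cell preprocessing and five reduction schemes, then
k-means or spectral clustering, and two cluster-level summaries.

All matrices are stored upper-triangular as `(bin1_id, bin2_id,
count)` triplets with 0-based global bin ids over half-open
`[start, end)` bins. A cell's *total reads* is the plain sum of stored
pixel values (off-diagonal pixels are not doubled); quality-control
thresholds act on exactly this number, which keeps the default
threshold semantics unambiguous.

## Quality control

`compute_qc()` reports per cell the total reads and the *sparsity*:
the fraction of possible intra-chromosomal upper-triangle pixels
(diagonal included) that are non-zero. Inter-chromosomal pixels are
excluded from the sparsity denominator because at 1 Mb they are
dominated by noise and all downstream per-chromosome analyses ignore
them. `filter_cells()` keeps a cell iff `total_reads >= min_reads`
(default 100000 — a cell with exactly 100 000 reads passes) **and**
`sparsity >= min_density`. There is no accepted numeric convention for
"too sparse", so `min_density` defaults to 0 (disabled) and is left to
the user. A cell failing both checks is reported as `low_reads`.

## Normalization and matrix balancing

Three depth-normalization modes mirror standard Hi-C practice:
scaling every cell to the total of the shallowest cell (idempotent;
the mode to use before comparing cells), scaling one matrix to the
value range 0–1, and multiplication by a user factor.

Two balancing algorithms remove per-bin biases under the usual
factorizable-bias model $A_{ij} = b_i b_j T_{ij}$:

* **Iterative correction** (`ice_correct()`): each pass divides the
  working matrix by the outer product of (row sum / mean row sum);
  convergence is declared when the coefficient of variation of the
  unmasked row sums drops below `tol` (default `1e-5`). The bias
  vector is renormalized to geometric mean 1, which fixes the
  arbitrary global scale without changing relative values.
* **Knight–Ruiz balancing** (`kr_correct()`): finds $x > 0$ with
  $\mathrm{diag}(x)\,A\,\mathrm{diag}(x)$ doubly stochastic via the
  damped symmetric fixed point $x \leftarrow \sqrt{x / (Ax)}$, run to
  `max |row sum − 1| < tol` (default `1e-6`). The square-root damping
  prevents the 2-cycling that plain Sinkhorn iterations exhibit on
  symmetric matrices. Only the contract (unit row sums) is promised;
  the inner iteration is an implementation detail.

Both mask all-zero bins by default and report the same
`raw / (bias_i bias_j)` factorization, so on a strictly positive
matrix the two corrected matrices agree up to one global scalar — a
property the test suite asserts on random positive matrices.
Balanceability is not guaranteed for arbitrary sparse supports: a
diagonal scaling to unit row sums exists only when the support has
*total support*. Disconnected support components are fine (each
balances independently; a diagonal matrix is the extreme case), but
e.g. a star support admits no solution. Rather than attempt a costly
structural pre-test, `kr_correct()` raises an error on
non-convergence, naming a disconnected component when one exists.

## Dimension reduction

**Raw and PCA.** `flatten_cells()` lays each cell out over the fixed
row-major upper-triangle ordering (kept sparse). `pca_reduce()`
projects the mean-centered matrix onto its top components via SVD.
The target dimensionality "number of bins" is ambiguous for a
bins²-sized feature space; we read it as *n_bins components* (capped
at `min(cells, features)`) and expose `n_components`. Component signs
are fixed (largest-magnitude loading positive) so results are
bit-reproducible.

**Exact kNN.** Euclidean neighbors with weight $1/(1+d)$ — bounded,
monotone, and 1 at distance 0. Ties are broken by cell index; the
graph is symmetrized by element-wise maximum, so every vertex keeps
between $k$ and $2k$ neighbors.

**MinHash.** Each cell is reduced to the *set* of its non-zero pixel
indices; count magnitudes are deliberately ignored, which makes the
similarity robust to per-cell coverage differences. For min-wise
independent hashes the probability that two cells' signature slots
agree equals their Jaccard similarity, so the matching fraction over
`num_hashes` slots (default 800) is an unbiased estimate with standard
error $\sqrt{J(1-J)/H}$. One numerical subtlety: the affine family
$h(x) = (ax+b) \bmod p$ alone is only *approximately* min-wise
independent and is measurably biased on arithmetically structured
sets — and pixel index sets are exactly that (runs of consecutive
flat indices). On the 3-element toy sets `{1,2,3}` vs `{2,3,4}` the
raw affine family estimates ≈ 0.42 for a true Jaccard of 0.5, an
error eight times the sampling noise at 2000 hashes. All hashes
therefore share one seeded random permutation of the universe applied
before the affine map, which restores the collision probability to
the Jaccard value. Candidates are ranked by estimated similarity
directly; exact-distance re-ranking would be a natural extension but
is intentionally not performed, keeping the operation's cost
independent of the feature dimension.

**Short-versus-long ratio (SVL).** Per cell and chromosome, the ratio
of intra-chromosomal counts at genomic distance `(0, t]` to counts
beyond `t`, diagonal excluded — a coverage-invariant, n_chromosomes-
dimensional summary of decay shape. The boundary `t` defaults to 2 Mb,
separating the sub-TAD regime from long-range contacts; it is a flag,
not a constant. A chromosome with no long-range contacts in a cell
yields a large sentinel (recorded in `params`) rather than an
infinity.

**Compartment tracks.** Per chromosome: observed/expected matrix
(expected = mean count per bin distance, zeros included), Pearson
correlation of its columns (zero-variance columns masked), then the
eigenvector of the largest eigenvalue — the classical A/B compartment
track whose sign separates the two large chromatin domains. The sign
of an eigenvector is arbitrary, so each cell's track is oriented to
have non-negative dot product with the track of a reference matrix —
by default the pooled bulk of the container. Using the bulk as the
orientation reference keeps the tool annotation-free (no GC or gene
density needed); note it aligns signs consistently *within* the
dataset but does not decide which sign is "A" in the biological sense.
Chromosomes with fewer than 3 unmasked bins contribute zero-filled,
flagged segments.

## Clustering

`kmeans_cluster()` runs `n_init = 10` Lloyd iterations (via
`stats::kmeans`) from k-means++ seeded centers drawn from the seeded
RNG and keeps the lowest-inertia solution. `spectral_cluster()` forms
the symmetric normalized Laplacian $L = I − D^{-1/2} W D^{-1/2}$,
takes the $K$ eigenvectors of the smallest eigenvalues (dense
symmetric eigendecomposition — deterministic and exact at the few
hundred cells this package targets; eigenvector signs fixed as in
PCA), unit-normalizes the rows and applies the seeded k-means. A graph
with $K$ connected components has $K$ zero eigenvalues with
piecewise-constant eigenvectors, so component splits are recovered
exactly for any seed. Isolated vertices have no defined normalized
Laplacian row and are reported as an error naming the cell. Labels are
always relabeled to first-occurrence order starting at 0, so any
permutation of cluster identities yields the identical output; `K` is
user input — no automatic model selection is attempted.

When a neighbor graph is clustered with k-means, its weight rows are
used directly as features (the `samples × samples` reading); the
spectral route is usually the better match for graph input.

## Consensus matrices and decay profiles

`build_consensus()` sums the matrices of each cluster pixel-wise and
scales every consensus to the smallest cluster total — the same
"depth of the shallowest" convention as `normalize_smallest()`, chosen
because the target value is otherwise arbitrary. `decay_profiles()`
bins each cell's intra-chromosomal counts by distance from the main
diagonal (0 to 50 Mb inclusive by default, in bin-size steps) and
normalizes each cell's row to sum 1: profiles compare decay *shapes*,
and per-cell normalization stops deep cells from dominating the
figure. Normalizing per cluster instead would hide within-cluster
coverage structure; per cell is the deliberate choice. Cells with no
counts in range are flagged and left as zero rows. The plotting
functions always write the underlying numeric tables next to the
images, so every figure has a testable surface.

## The synthetic generator

`simulate_cells()` is the package's source of ground truth. For a
cell of cluster $\kappa$, each intra-chromosomal pixel $(i,j)$ carries
sampling weight

$$w_{ij} = (1+|i-j|)^{-\alpha_\kappa}\,
           \max\!\bigl(0,\; 1 + \varepsilon_\kappa c_\kappa(i,j)\bigr),$$

where $c_\kappa = +1$ if bins $i,j$ share the cluster's checkerboard
compartment and $-1$ otherwise, and the cell's reads are placed by one
multinomial draw over these weights. This emulates the two structural
signals count matrices can expose — distance decay and compartment
plaid — and nothing else: no TADs or loops, no per-bin biases
(balancing is validated on separately constructed matrices), no
inter-chromosomal contacts, no read-level artifacts. Results on it
show the pipeline recovers *decay- and compartment-level* structure;
they cannot certify performance on signals the generator does not
contain.

Reference conditions (the defaults): a 100 Mb genome (60 + 40 Mb
chromosomes) at 1 Mb bins, $K = 3$ clusters × 50 cells, exactly
50 000 reads per cell, decay exponents $\alpha = 0.8/1.2/1.6$
(spanning the range typically fit to contact-probability curves), and
compartment checkerboards with 10 Mb blocks at contrast
$\varepsilon = 0.8$, phases offset by one third of the 20 Mb
checkerboard period per cluster (0, 7, 13 bins) so the three patterns
are pairwise distinct. The strong contrast reflects single-cell
compartment polarization: in an individual cell a locus pair occupies
one spatial partition, so cross-compartment long-range contacts are
heavily depleted relative to the ensemble average. One scaled-down
artifact deserves a caveat: 50 000 reads over ~2 650 intra-chromosomal
pixels makes these matrices near-saturated (real 1 Mb scHi-C is
<10–20% dense), which compresses Jaccard similarities between cells
that differ only in decay exponent. The MinHash estimator itself is
validated separately on a fixture with lognormal per-cell coverage
(median ~1 500 reads, `sdlog` 0.6) whose 10–20% density matches real
data; there its neighbor graph recovers ≥ 90% of the exact-Jaccard
graph's edges, with mean absolute similarity error ≈ 0.01 at 1000
hashes. The equal-$\alpha$, $\varepsilon = 0$ configuration is the
negative control: clusters are then statistically identical and any
pipeline should score an adjusted Rand index near 0.

## Numerical choices and degenerate inputs

* All stochastic operations take an explicit integer seed and restore
  the caller's RNG state; identical inputs and seeds give bit-identical
  outputs (containers round-trip through HDF5 byte-identically).
* Validation sizes: simulations of 150 cells × 50 000 reads on 100
  bins, balancing on 50×50 matrices, round trips over containers of up
  to 20 cells × 200 bins — sizes at which every check runs in seconds
  to a couple of minutes while exercising the full code paths.
* Ties: kNN neighbor ties break by cell index; k-means++ center draws
  and Lloyd assignment follow `stats::kmeans` semantics; eigenvector
  signs are canonicalized everywhere.
* Degenerate inputs are first-class: empty containers read and write
  correctly, zero-pixel cells get sparsity 0 and fail QC, all-zero
  matrices are rejected by balancing and range normalization with
  instructive errors, and cells with empty pixel sets are rejected by
  MinHash with a pointer to QC.
* Merging bins by factor $n$ sums counts exactly (integer arithmetic),
  so totals are conserved to the last read; chromosome subsetting
  drops pixels touching removed chromosomes and re-indexes bins
  contiguously.

## Known limitations

* One resolution per container; multi-resolution (mcool) files and
  foreign matrix formats are out of scope.
* Correction is offered per cell or per matrix; whether to correct
  single cells at all (rather than only consensus matrices) is left to
  the user, as sparse per-cell matrices can be fragile under
  balancing.
* MinHash neighbor lists are not re-ranked with exact distances.
* No automatic choice of $K$, no ensemble clustering, and no 2-D
  embedding visualizations: at these dimensionalities such projections
  are more misleading than informative, and the consensus-matrix and
  decay-profile views are offered instead.
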