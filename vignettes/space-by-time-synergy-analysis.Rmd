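---
title: "Space-by-time muscle synergy analysis: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space-by-time muscle synergy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`emgsynergy` analyses multi-muscle EMG recordings under the space-by-time
modularity hypothesis: every single-trial muscle pattern
$M^l \in \mathbb{R}_+^{T \times M}$ (here $T = 50$ time bins, $M = 30$
muscles) is approximated by a three-factor product

$$M^l \approx W_t\, A^l\, W_s, \qquad l = 1, \dots, L,$$

where the columns of $W_t \in \mathbb{R}_+^{T \times K}$ are *temporal
synergies* (stereotyped activation profiles shared by all trials), the rows
of $W_s \in \mathbb{R}_+^{N \times M}$ are *spatial synergies* (fixed
balances of muscle activation), and $A^l \in \mathbb{R}_+^{K \times N}$
holds the trial-specific scalar coefficients $a^l_{ij}$ that recruit
temporal synergy $i$ through spatial synergy $j$. All three factors are
non-negative, which matches rectified EMG envelopes (muscles cannot be
activated "negatively") and is what distinguishes this factorisation from
PCA/ICA-style decompositions.

Goodness of fit is the variance accounted for,

$$\mathrm{VAF} = 1 - \frac{\sum_l \lVert M^l - W_t A^l W_s \rVert_F^2}
{\sum_l \lVert M^l - \bar{m} \rVert_F^2},$$

with $\bar m$ the mean trial pattern. VAF is 1 exactly for a perfect
reconstruction, 0 for a model no better than the mean pattern, and can be
negative.

The scale of each synergy is not identified (doubling a column of $W_t$ and
halving the corresponding coefficients changes nothing), so fitted models
are normalised: unit Euclidean norm for every temporal and spatial synergy,
all scale absorbed into the coefficients. This convention is what makes
synergies comparable, and clusterable, across subjects.

# Fitting

The factorisation minimises the total squared Frobenius error by
block-coordinate descent over the three blocks in the cyclic order
$W_t \rightarrow \{A^l\} \rightarrow W_s$. Each block update is an exact
coordinate-wise non-negative least-squares step (HALS updates for the
synergy matrices, entrywise coordinate descent with the Gram matrices
$W_t^\top W_t$ and $W_s W_s^\top$ for the coefficients), so the objective
is non-increasing after every update — a property the test suite asserts on
the returned objective trace. A restart stops when the relative objective
decrease falls below `tol` (default `1e-8`) or after `max_iter` (default
500) iterations; hitting the cap flags the fit with a warning rather than
failing. The inner loop is implemented in C++ (RcppArmadillo), which is
what makes the 100-point $(K, N)$ grid searches practical.

The problem is non-convex; following the reference protocol the optimiser
is restarted from `restarts = 50` random initialisations (uniform factors
scaled to the data magnitude; restart $r$ is seeded `seed + r - 1`) and the
lowest-error solution is kept. Tests and the acceptance harness use 4-10
restarts to stay inside their time budgets; on the synthetic worlds used
there this recovers planted factors with per-synergy correlation above 0.95
when noiseless. At moderate noise the best-objective solution occasionally
mixes one planted synergy (correlation ~0.87 instead of >0.94 at some
seeds) — more restarts do not repair this, because it is a property of the
objective's global optimum for that noise draw, not of the optimiser.

# Choosing the number of synergies

$K$ and $N$ are free parameters. They are selected by decoding: fit every
pair on a grid ($K, N = 1 \dots 10$ by default), decode the 72-class
movement identity from the full coefficient set with LDA, and return the
smallest pair (scanning by total $K+N$, then lexicographically — the scan
order is a package choice, the criterion is not) for which neither adding a
temporal nor a spatial synergy yields a *significant gain*. Significance is
assessed by permutation: the added component's coefficients are shuffled
across trials, everything else left untouched, and decoding is repeated
(`n_perm = 200` by default; one-sided p with add-one correction; degenerate
`alpha` outside (0, 1) is rejected).

One guard proved necessary in practice. When the data are effectively
rank-$K$, the $(K{+}1)$-synergy optimum often *splits* a real synergy into
two collinear components. Shuffling one of them then destroys amplitude
information that the intact model shares between the two copies, so the
permutation null collapses far below the observed performance — every
increment looks "significant" even when the enlarged model decodes no
better (sometimes worse) than the smaller one, and no plateau ever appears.
Since the criterion is about a decoding *gain*, the package treats an
observed performance at or below the smaller model's as non-significant by
definition (`p = 1`) and applies the permutation null only to genuine
improvements. With this gate the selection recovers planted model orders
and returns (1, 1) on label-shuffled data.

# Decoding and task information

Each temporal synergy $i$ is represented on every trial by the $N$
coefficients pairing it with the spatial synergies ($A[l, i, \cdot]$), each
spatial synergy $j$ by the $K$ coefficients $A[l, \cdot, j]$, and the full
model by all $K \times N$ coefficients. Ten discrete task parameters are
decoded per synergy: start target/bar/height, direction (8 classes),
horizontal and vertical direction, end bar/height/target, and the full
72-class movement.

The decoder is linear discriminant analysis with a shared pooled covariance
and empirical class priors, evaluated by leave-one-out cross-validation.
Numerical choices:

* the pooled covariance is shrunk towards the identity with
  $\lambda = 10^{-3}\,\mathrm{tr}(\Sigma)/d$ whenever its condition number
  exceeds $10^8$ (collinear coefficient slices occur routinely);
* prediction ties break towards the lowest class index, making the decoder
  fully deterministic;
* classes with a single trial cannot be held out and are skipped with a
  warning;
* the leave-one-out loop downdates the pooled scatter by a rank-one
  Sherman-Morrison step, so the covariance is inverted once, not $L$ times.

The implementation is validated against `MASS::lda(CV = TRUE)` on
well-conditioned fixtures. Note a known property of leave-one-out
percent-correct on null data: removing the held-out trial shifts the
empirical prior and the class mean *against* its own class, so null
decoding sits slightly below the nominal $100/V$ and is over-dispersed
relative to a binomial; the calibration checks use a central 99% binomial
band, which holds in the tested regimes but is an approximation, not an
exact null.

Decoding quality beyond percent correct is quantified from the confusion
matrix by the mutual information between true and predicted classes
(base-2 logarithms; $0 \log 0 \equiv 0$). Because plug-in information is
biased upward at finite trial counts, the Panzeri-Treves analytic
correction is subtracted, with occupied response bins counted naively (the
canonical default; the correction variant is not stated in the reference
analysis). The corrected value is floored at zero for reporting and kept
unfloored in metadata. Reporting follows the field's style: bits to two
decimals, percentages of the $\log_2 V$ maximum as integers. A useful
sanity property, asserted in the tests: at matched percent correct, a
confusion matrix whose errors concentrate near the true class carries
strictly more information than one with uniformly spread errors.

# Functional-similarity clustering

To compare synergies across subjects by *what they do* rather than what
they look like, every synergy is summarised by its 72-class confusion
matrix, reshaped to a 5184-vector; functional similarity of two synergies
is the Pearson correlation $r_{ij}$ of these vectors, computed across all
pairs pooled over subjects. Synergies are then clustered by agglomerative
complete linkage. The reference description uses $r_{ij}$ "as distance",
which is ambiguous since correlation is a similarity; this package builds
the tree on $d = 1 - r$ (the only choice that makes linkage well defined)
and applies the published cutoffs — 0.5 for temporal synergies, 0.6 for
spatial — on that distance scale, where they indeed separate well-formed
branches. Temporal and spatial synergies are never mixed in one tree.
Undefined correlations (a degenerate, zero-variance confusion matrix) are
imputed as distance 2, beyond the attainable maximum, so degenerate
synergies end up unclustered; after cutting, singleton components are
labelled "unclustered". Clusters are summarised by the entrywise mean of
their members' (unit-norm) synergies with per-element dispersion, and by
the entrywise mean of their confusion matrices, row-renormalised.

Two empirical regularities of this method are worth knowing. First, it
works best with *imperfect* decoders: as decoding approaches 100%, all
confusion matrices converge to the identity and their correlations rise
toward 1 regardless of function, washing out the cluster structure. Second,
task parameters that are logically related (horizontal direction is a
function of start and end bar) induce genuinely correlated confusion
structure, so synergies tuned to related parameters sit closer in the tree
— which mirrors how such clusters behave on real data.

# The synthetic world

Real recordings for this protocol are not publicly deposited, so the
package ships a generator that emulates the experiment with a known ground
truth: 9 targets on 3 bars (left to right) at 3 heights, all 72 ordered
pairs as movements, 30 repetitions each, 30 muscles, 50 time bins. Within a
row, targets are numbered right-to-left so that the canonical example
movements (horizontal leftward, vertical downward, diagonal down-left) come
out as illustrated in the source protocol. The source text is internally
inconsistent about which side bar 1 is on; the generator fixes bar 1 = left
(as in the protocol summary) without claiming fidelity on this point.

The planted model draws temporal synergies as truncated-Gaussian bumps
(width $T/2K$, peaks staggered across the movement), spatial synergies from
a sparse gamma prior with one dominant muscle each, and gives every synergy
a tuned task parameter: the earliest temporal synergy encodes the start
target, transient middle ones the movement direction, the latest the end
target; spatial synergies encode bar- and height-related parameters. Trial
coefficients are the product of the two per-class mean gains and
multiplicative lognormal noise (sigma 0.2 by default); EMG noise is
additive Gaussian truncated at zero (sd 0.05 on the unit-amplitude scale).
Both choices preserve non-negativity and are standard for rectified EMG
envelopes. "Subjects" share the temporal synergies and the entire tuning
map but have independently redrawn spatial loadings — exactly the situation
(same function, different shape) that functional clustering targets.

The per-class gains are evenly spaced over 0.7-1.3 for temporal synergies
(movement-phase bursts occur in every movement, so their amplitude
modulation is moderate) and 0.3-1.7 for spatial synergies (postural demand
varies strongly with target position). This asymmetry is a considered
choice: because the mean coefficient is a *product* of a temporal and a
spatial gain, every coefficient slice carries some information about both
parameter families, and making the two ranges equal lets the shared
temporal structure dominate all spatial-synergy confusion matrices, which
merges the planted functional clusters. A wider temporal range was tried
and rejected for exactly that reason. A corollary is that the generator
cannot make non-tuned parameters decode *at* chance — the rank-1 coupling
forbids it — so recovery is asserted as an ordering (each synergy decodes
its own parameter best) rather than as absolute chance levels.

What the generator does **not** emulate: biomechanics and muscle-model
realism, reflex/tonic background activity, electrode artifacts,
trial-to-trial temporal misalignment (no phase or time-shift variability —
also explicitly outside the decomposition model), or correlated noise
across muscles. A green recovery test therefore establishes that the
pipeline's statistics behave as designed on data satisfying the model's
assumptions, not that the model is true of any particular recording.

Optionally the generator produces raw-like traces for preprocessing tests:
a white-noise carrier amplitude-modulated by the planted envelope, plus a
minimum-jerk fingertip-speed profile. This tests the preprocessing
arithmetic, not EMG electrophysiology.

# Preprocessing

The preprocessing chain mirrors the reference protocol: detect the
movement window as the span where fingertip speed exceeds 5% of its peak,
start the analysis 100 ms before onset; high-pass the raw EMG at 20 Hz,
full-wave rectify, low-pass at 3 Hz; linearly resample the window to a
uniform 1000-step grid and reduce it to 50 bins by per-segment trapezoidal
integration; finally divide each muscle by its maximum over the whole
experiment. Unstated details resolved here: both Butterworth filters are
4th order and both are applied forward-backward (the source states
zero-phase only for the low-pass; applying it to the high-pass as well
avoids distorting onset timing), interpolation is linear, windows are
half-open, and filtering is applied to the full trace before windowing.
Manual artifact-trial screening is replaced by an optional automatic
amplitude-outlier flag and is off by default.

# Limitations

* The decomposition assumes fixed temporal synergies with no per-trial
  time shifts; temporally misaligned data will spread one true synergy
  over several fitted ones.
* The model-order permutation test inherits the collinear-split issue
  described above; the gain gate resolves the decision but the reported
  p-values for genuinely redundant increments remain conservative
  fictions (p = 1 by definition).
* Functional clustering requires decoders far from both chance and
  perfection; outside that regime the confusion correlations lose
  contrast.
* All validation is against the package's own synthetic world; no claim is
  made that the fitted synergies of any real dataset are "true" modules.
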