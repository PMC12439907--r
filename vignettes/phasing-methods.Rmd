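---
title: "Methods: cluster-based phasing of nano-NOMe-seq molecules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cluster-based phasing of nano-NOMe-seq molecules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Nano-NOMe-seq reads out chromatin accessibility molecule by molecule: an
exogenous GpC methyltransferase methylates accessible DNA, so the GpC
methylation pattern along one nanopore read is a footprint of that single
molecule's nucleosomes, nucleosome-free regions (NFRs) and bound factors.
The statistical task this package solves is a mixture deconvolution with
fragmentary observations: a locus is occupied by a small number `t` of
recurrent chromatin states with unknown mixing proportions, each sequenced
molecule is one (noisy, partial) draw from one state, and no molecule spans
the locus. The pipeline recovers locus-spanning state profiles and a state
assignment per molecule in four stages.

**Binning.** Calls are aggregated into fixed bins (fraction of methylated
GpC calls per bin). A bin a read does not cover, or covers with no call, is
*missing*, not zero. Bin values are kept fractional rather than
re-binarised: the distance below reduces to the Hamming fraction on binary
data, and fractional values lose no information when bins straddle
nucleosome edges.

**Masked distance.** All comparisons use
\[
d_H(u, v) \;=\;
\begin{cases}
0 & \text{if } \sum_i m_i = 0\\[2pt]
\dfrac{\sum_i m_i\,|u_i - v_i|}{\sum_i m_i} & \text{otherwise,}
\end{cases}
\qquad m_i = 1 \iff u_i, v_i \text{ both observed.}
\]
Missing bins carry no penalty, so partially overlapping molecules are
compared only where they genuinely overlap. The degenerate case — two
profiles with no co-observed bin — is defined as distance 0, i.e.
*indistinguishable*, which is the permissive convention; see "Degenerate
inputs" below for where the package refuses to exploit it.

**Windowed clustering.** Valid bins (covered by at least one read) are
tiled with windows of `window_size` valid bins advancing by
`window_size - overlap`, the last window right-anchored on the final valid
bin. Within a window, reads with at least `min_read_valid_bins` observed
bins are clustered agglomeratively: start from singletons, repeatedly merge
the pair with minimal average-linkage distance, and update distances to the
merged cluster with the size-weighted (Lance–Williams average-linkage)
formula
\[
d(C_r \cup C_s, C_k) =
\frac{|C_r|\,d(C_r, C_k) + |C_s|\,d(C_s, C_k)}{|C_r| + |C_s|},
\]
stopping at `t` clusters. On complete data this update provably equals
recomputing the mean over all cross-pair distances, and the test suite
asserts the equality against an independent recomputation oracle; under
missing data the two can diverge, and the update formula is taken as the
definition.

**Stitching.** Each window yields `t` clusters with mean profiles
\(\mu_i = |C_i|^{-1} \sum_{r \in C_i} m_r\). Clusters of consecutive
windows are matched one-to-one by minimising
\(\sum_i D[i, \sigma(i)]\) with \(D[i,j] = d_H(\mu_i^{(N)},
\mu_j^{(N+1)})\) restricted to the bins the two windows share — the only
common support of the window-local profiles. The assignment problem is
solved exactly with a Hungarian-algorithm variant (shortest augmenting
paths with dual potentials, O(t³)); optimality is verified against
brute-force enumeration in the tests. Chaining the per-boundary matchings
left to right yields `t` locus-spanning cluster series, whose region-level
profile averages the per-window means bin-wise (unweighted across the
windows observing a bin — a symmetric choice; window-size weighting was
considered and rejected as it privileges interior windows for no modelled
reason).

**Global reassignment.** Every clustering-eligible molecule is finally
assigned to the series whose region profile is closest under \(d_H\) over
the molecule's full binned vector. This single global pass corrects
window-level inconsistencies; an optional iterative refinement
(`max_reassign_iter > 0`) alternates profile recomputation and
reassignment, but is off by default because the single pass is the
operative procedure and the iteration's objective (sum of \(L_1\)-type
distances to mean profiles) is not guaranteed monotone under mean updates.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| `bin_width` | 50 | bp | resolves mono-nucleosome (147 bp) footprints into ~3 bins; matches the published pipeline |
| `min_read_span` | 10 | bp | discard degenerate alignments |
| `min_gpc` | 10 | calls | a read with fewer GpC calls carries almost no footprint information |
| `window_size` | 60 | valid bins (~3 kb) | large enough to hold several nucleosome-scale features, small enough that most reads span a window |
| `window_overlap` | 20 | valid bins (~1 kb) | the shared support on which stitching costs are computed |
| `min_read_valid_bins` | 30 | bins | half a window; a read observed on fewer bins cannot be placed reliably within the window |
| `extreme_theta` | 0.95 | fraction | molecules with mean methylation ≥ θ (or ≤ 1−θ) are pre-assigned fully methylated/unmethylated: they are ambiguous for stitching; near-1 so genuinely footprinted reads are kept |
| `smooth_half_window` | 0 | bins | smoothing (masked rolling mean) is available but **off** for distance computation: the reference procedure describes smoothed matrices for visualisation and extreme-read identification, and smoothing before clustering blurs exactly the 1–2-bin TF footprints the method is after |
| `t` | user | clusters | the published analyses chose 7–9 per locus by inspection; no selection rule is prescribed, so `t` is a required argument and `sweep_t()` (an extension) reports a profile-silhouette across candidate values |

## Numerical and degenerate-input choices

* **Tie-breaking, clustering:** among merge pairs at exactly the minimal
  distance, the pair whose (smaller label, larger label) is
  lexicographically smallest is merged, labels being the smallest original
  row index in each cluster. Two runs on the same input are identical.
* **Tie-breaking, assignment:** among equally optimal matchings the
  lexicographically smallest permutation is returned (columns are fixed row
  by row, testing extendability to the known optimum within a relative
  tolerance of 1e-9).
* **Zero-overlap reads:** a molecule sharing no observed bin with any
  series profile is labelled `UNASSIGNED` rather than assigned at distance
  0 to series 0 — the permissive \(d_H = 0\) convention would make that
  choice arbitrary. A configuration switch (`disjoint_value = 1` on the
  distance functions) inverts the convention for sensitivity analyses; it
  is off by default to follow the reference formula.
* **Deficient windows:** a window with fewer members than `t` is padded
  with empty clusters that enter stitching at distance 1 to everything, so
  real clusters pair preferentially and the cost matrix stays square.
* **Read-boundary bins:** a read's first and last covered bins are masked
  during binning (`mask_boundary = TRUE`). The read boundary truncates
  those bins, so their methylation fraction is estimated from a censored
  subset of the bin's GpC sites; at nucleosome edges this is biased, and
  the bias propagates into cluster means. Masking costs two bins per read
  (~1% of a median read) and makes cluster means exact mixtures of
  fully-observed bin values — without it, noise-free leave-one-out
  accuracy saturates at ~0.9995 instead of 1.
* **Low-confidence calls** are treated as missing, not as unmethylated,
  mirroring the masked-distance philosophy.
* **Coordinates** are 0-based half-open everywhere, including bedGraph
  output.

## The simulator: what a green test establishes

`simulate_locus()` draws molecules from `t` latent accessibility tracks
built from the vocabulary of the assay: 147-bp nucleosomes in phased
arrays (state-specific phase offsets), 50-bp linkers, 150–400-bp NFRs at
state-specific positions, and 35–50-bp TF footprints inside some NFRs.
Defaults describe a realistic locus: 50 kb, GpC sites every ~20 bp
(gamma-jittered), log-normal read lengths with median 8 kb (so stitching is
always exercised), 60× coverage, mixing weights (0.45, 0.35, 0.20),
asymmetric noise — accessible sites missed at 0.10, protected sites
spuriously methylated at 0.05, reflecting that methyltransferase
under-labelling exceeds spurious labelling — 5% call dropout, and two
locus-spanning long reads for hold-out validation. The seed fully
determines the output.

The simulator deliberately omits: nucleotide sequence and HGC/GCG context
(assumed handled upstream), endogenous CpG methylation, nanopore
base-calling error structure, coverage waviness, and diploid haplotypes.
Latent states are also *globally* distinct — every window is informative —
whereas real loci can contain windows where two cell states coincide.
A green recovery test therefore establishes that the machinery (binning,
masked distances, window clustering, stitching, reassignment) composes
correctly under realistic noise and fragmentation; it does not establish
performance on states that are locally indistinguishable, nor calibrate
accuracy on real data.

## Leave-one-out accuracy: what the score means

Holding out a long read, re-phasing without it (grid, valid bins, windows
and filters are recomputed from scratch, so the held-out read cannot leak
into any stage), and scoring \(A(r) = 1 - \min_j d_H(r, c_j)\) measures
how well the locus-spanning profile of one molecule is explained by the
best series. Two properties of this score are worth keeping in mind:

* With no noise, a held-out read equals its state's series profile on every
  co-observed bin, and \(A = 1\) exactly (the test suite asserts this to
  1e-12, the tolerance covering only floating-point summation).
* With per-call flip noise \(\varepsilon\), \(A\) does **not** converge to
  \(1 - \varepsilon\). The read is compared to the *estimated* cluster
  mean, which the same noise shrinks towards 0.5
  (\(\mu_b = a_b(1-2\varepsilon)+\varepsilon\)); for a bin with \(s\)
  co-observed GpCs the expected deviation is that of a mean of \(s\)
  centred two-point variables taking \(\pm\varepsilon\) /
  \(\mp(1-\varepsilon)\), which is \(2\varepsilon(1-\varepsilon)\) at
  \(s = 1\) and decays only slowly in \(s\). At the default geometry
  (50-bp bins, ~20-bp GpC spacing, i.e. \(s \approx 2.4\)) the expected
  per-bin deviation is ≈ 0.09, so mean \(A \approx 0.91\) at
  \(\varepsilon = 0.05\) — the value the acceptance suite measures. An
  accuracy in the high 0.8s/low 0.9s on noisy data is therefore the
  expected behaviour of a *correct* implementation, not evidence of
  misphasing; only comparisons against the (unobservable) true state
  profiles would concentrate at \(1 - \varepsilon\).

## Known limitations

* `t` must be supplied; the silhouette sweep is a heuristic aid, not a
  model-selection procedure.
* The Lance–Williams update is the definition of average linkage under
  missing data; it is not identical to re-averaging masked pairwise
  distances, and no claim is made about which is preferable.
* Stitching is pairwise-sequential left→right, as in the reference
  procedure; a globally joint matching across all windows is out of scope.
* Proportions are interpretable as cell-fraction estimates only for
  PCR-free libraries.
* Configuration files are JSON (flags win over file values); YAML is not
  supported to keep the dependency footprint to pre-installed packages.
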