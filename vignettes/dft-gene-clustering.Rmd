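---
title: "Alignment-free gene clustering from Fourier power spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free gene clustering from Fourier power spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dftree)
```

## The method

Comparing gene-length DNA sequences without alignment is attractive when
the sequences differ wildly in length and when alignment cost or
ambiguity is prohibitive. `dftree` implements a spectral route:

1. **Voss indicator encoding.** A sequence of length $N$ becomes four
   binary signals $w, x, y, z$, one per base (A, T, G, C): the A-signal
   is 1 wherever the residue is A and 0 elsewhere. The encoding is
   lossless at unambiguous positions. Ambiguity codes (N, R, Y, ...) map
   to 0 in all four signals, keeping them strictly binary; real gene
   records can carry hundreds of masked N positions, so this rule is
   explicit rather than incidental.

2. **Discrete Fourier transform.** Each indicator is transformed by
   $X[k] = \sum_{n=0}^{N-1} x[n]\, e^{-j 2\pi k n / N}$, and the power
   spectrum $P[k] = |X[k]|^2$ is taken. The DC coefficient $X[0]$ equals
   the base count; the spectrum of a real binary signal has conjugate
   symmetry, and the power spectrum is invariant to cyclic shifts of the
   sequence.

3. **Power-spectrum moments (PSM).** Spectra of different-length
   sequences live on different frequency grids, so they are summarised
   by fixed-length moments over the normalized frequency $k/N$. For each
   base $b$ the package computes a total-power term
   $T_b = \frac{1}{N}\sum_{k=1}^{N-1} P_b[k]$ and moments
   $m_j^{(b)} = \sum_{k=1}^{N-1} p_b[k]\,(k/N)^j$ for $j = 1..J$, where
   $p_b[k]$ are the non-DC powers normalized to sum to one. With the
   default $J = 3$ every sequence — 7 bp or 79 kbp — maps to the same 16
   features. The moment entries lie in $[0, 1]$; a base that is absent
   (or whose indicator is constant) contributes zeros.

4. **Four linkages and evidence accumulation.** Euclidean distances
   between feature vectors drive agglomerative clustering under single,
   complete, average (UPGMA) and median (WPGMC) linkage. Each tree is
   cut into $k$ clusters, the cuts are averaged into a co-association
   matrix $c_{ij}$ = fraction of base clusterings placing $i$ and $j$
   together, and a consensus tree is learned by average linkage on
   $1 - c$. The consensus cut at $k$ is the headline partition.

## Design choices where the design was open

**The PSM formula.** The moment construction above is this package's own
concrete definition: normalized spectral moments over $k/N$ plus a
per-base total-power term. It is length-invariant by construction,
separates composition (in $T_b$) from spectral shape (in $m_j$), and
degenerates gracefully for absent bases. The DC term is excluded from
the moments because it carries only base composition, which would
otherwise dominate every moment; `include_dc = TRUE` restores it for
experimentation. Because published applications of spectral-moment
clustering do not pin down a single formula, exact reproduction of any
particular published gene tree is not guaranteed — the package's
guarantees are the contracts tested here (length-invariant dimension,
shift invariance, the degenerate cases, and recovery of synthetic
families).

**Median linkage on squared distances.** WPGMC is the median method in
the standard Lance–Williams taxonomy ($\alpha = \tfrac12$,
$\beta = -\tfrac14$). The update is applied to squared Euclidean
distances and merge heights are reported as square roots, keeping all
four trees on one scale. Median trees may contain height inversions;
`cut_tree()` therefore cuts by merge order, and `to_newick()` clamps a
negative branch length to zero with a warning rather than emitting an
invalid tree.

**Deterministic tie-breaking.** When several active pairs tie at the
minimal distance, the pair with the lexicographically smallest node-index
pair merges (leaves are numbered first, internal nodes in creation
order). Agglomeration output is then a pure function of the input
matrix, which the test suite exploits by comparing against brute-force
re-agglomeration.

**Consensus linkage.** Evidence accumulation only requires "a
hierarchical clustering" of $1 - c$; average linkage is the standard
choice in the cluster-ensemble literature and the default here
(`consensus_method` switches it). Base trees are all cut at the same
shared $k$ before fusion; fusing full dendrograms instead of partitions
is a different algorithm and out of scope.

**Raw vs standardized features.** Distances default to the raw feature
columns; `standardize = TRUE` z-scores each column first. Raw is the
default because the total-power terms carry meaningful scale
(composition variance), but note they dwarf the $[0,1]$ moments, so the
default distance is composition-dominated — a documented property, not
an accident.

**Labels.** Cluster labels are 0-based (`0..k-1`), assigned in order of
first leaf appearance, so identical inputs give identical labelings.

## The synthetic generator

`simulate_families()` stands in for curated gene sets: each family
descends from an independent i.i.d. random ancestor with
$P(\mathrm{G\ or\ C}) =$ `gc_bias` (default 0.48, around the mean GC of
mammalian gene loci), members receive i.i.d. substitutions at
`substitution_rate` and geometric-length indels (mean 2 bp, half
insertions, half deletions) at `indel_rate`. Indels make member lengths
unequal on purpose — handling unequal lengths is the method's central
claim, so fixtures must not be length-matched. The default scenario is
4 families × 6 members, 3 kb ancestors, 2% substitution, 0.2% indels,
seed 20230309.

What it does *not* emulate: realistic substitution processes (no
transition/transversion bias, no rate heterogeneity), exon/intron
architecture, repeats, or shared ancestry *between* families. Passing
recovery tests on these fixtures shows the pipeline separates families
whose spectra differ by independent ancestry; it does not certify
performance on real genes, where between-gene signal structure is richer.
Two properties of the generator matter for interpreting results: because
all families share one `gc_bias`, between-family separation rests on
random spectral-shape differences between ancestors rather than on
composition; and within-family spread grows with `substitution_rate`. At
2% substitution the consensus recovers the default four families
exactly; by 5% the two spreads are comparable and recovery becomes
seed-dependent — expected behaviour of the statistic, not a defect of
the implementation.

## Numerical notes

- `dft()` is computed by `stats::fft`; the contract, enforced in tests,
  is agreement with the defining sum to 1e-8 per element on signals up
  to length 64, plus conjugate symmetry and Parseval consistency
  ($\sum_n x[n]^2 = \frac{1}{N}\sum_k P[k]$, within 1e-8 relative) on
  indicator spectra.
- Text artifacts render floating point at 10 significant digits
  (12 for the PHYLIP distance matrix, which must round-trip within
  1e-9); GC percent is rendered half-up to one decimal, matching the
  precision of published gene feature tables, while full precision is
  kept internally.
- Degenerate inputs are first-class: all-ambiguous sequences encode to
  all-zero indicators; constant indicators yield zero spectral features;
  `k = 1` and `k = n` cuts, two-leaf trees and single-family simulations
  are all tested paths.
- Problem sizes in the test suite (random signals ≤ 64, matrices
  ≤ 12 leaves, fixtures ≤ 24 sequences × 3 kb) were chosen as the
  smallest scales at which every contract is non-trivially exercised;
  the pipeline itself is O(n² · N log N) and handles 30 genes of up to
  80 kb comfortably.

## Worked example

The seven-base gene `agcttta` gives indicator
`w = 1,0,0,0,0,0,1` for base A, and its DFT starts
`W[0] = 2`, `W[1] ≈ 1.623 + 0.782j`:

```{r}
sp <- spectrum_set(indicator_set("AGCTTTA"))
round(sp$dft$A, 3)
```

An end-to-end run on synthetic families:

```{r}
sim <- simulate_families(n_families = 4, members_per_family = 6,
                         ancestor_length = 3000, seed = 20230309)
fv <- psm_features(sim$sequences)
ens <- run_ensemble(fv, k = 4)
tidy(ens)
glance(ens)
```

```{r, fig.width = 7, fig.height = 4}
autoplot(ens$consensus)
autoplot(ens$coassociation)
```

## Known limitations

- The feature vector is a 16-number summary; genes with similar
  composition and smooth spectra can collide regardless of sequence
  identity. The moments are also insensitive to reversal of the
  sequence (conjugation symmetry of the spectrum), which is a feature
  for strand-agnostic use and a limitation otherwise.
- Median-linkage inversions mean the "cut at k" and "cut at height"
  views can disagree for that linkage.
- Exporting per-cluster gene lists for functional-annotation services
  is left to the user: `tidy(ens)` gives the id-to-cluster table that
  such services accept as plain gene lists.
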