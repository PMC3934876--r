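---
title: "Consistency-based maximum expected accuracy alignment: methods and design"
author: "consMSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consistency-based maximum expected accuracy alignment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consMSA)
```

## The method

consMSA aligns a set of protein (or nucleotide) sequences with the
four-stage strategy used by the ProbCons/MSAProbs family of
consistency-based aligners:

1. **Pairwise posteriors.** For every unordered pair (x, y) it computes a
   posterior probability matrix P_xy whose entry (i, j) estimates the
   probability that residues x_i and y_j are paired in the true
   alignment. Two independent estimates are combined entrywise as root
   mean squares,

   P_xy(i,j) = sqrt( (P^hmm(i,j)^2 + P^pf(i,j)^2) / 2 ),

   one from forward–backward decoding of a five-state pair hidden Markov
   model, one from a partition function over Boltzmann-weighted
   affine-gap global alignments. The RMS favours a confident vote from
   either model over the arithmetic mean while staying inside [0, 1].
   A pairwise distance d_xy = 1 − MEA(P_xy)/min(l_x, l_y) is read off
   the same matrix with a gap-cost-free Needleman–Wunsch pass, and the
   matrix is compressed to a sparse row representation.

2. **Guide tree.** UPGMA (size-weighted average linkage) over the d_xy,
   with ClustalW sequence weights computed from the tree's branch
   lengths: each sequence's weight sums, over its root-path edges,
   edge-length divided by the number of leaves sharing the edge.

3. **Consistency transformation.** Each sparse posterior is relaxed
   through every third sequence z:

   P'_xy = [ (w_x + w_y) P_xy + Σ_{z≠x,y} w_z · P_xz P_zy ] /
           [ (w_x + w_y) + Σ_{z≠x,y} w_z ].

   The relaxation runs on sparse operands and obeys a strict *no-fill*
   rule: a product cell with no corresponding element in P_xy is
   discarded, so support can only shrink. After each round,
   sub-threshold elements are dropped. All pairs in a round read a
   snapshot of the pre-round table, so results are independent of pair
   order and worker count.

4. **Progressive alignment and refinement.** Profiles are merged along
   the tree in post-order. The score of putting profile columns i and j
   together is the weighted average of relaxed posteriors across the
   cross pairs; the merge itself is the same zero-gap-cost recursion

   M[i][j] = max(M[i−1][j−1] + p(i,j), M[i−1][j], M[i][j−1]),

   solved row-wise with a deterministic traceback (diagonal over up over
   left on ties). Refinement then repeatedly splits the alignment's rows
   into two random profiles, removes all-gap columns from each half, and
   realigns them, accepting the result unconditionally.

## Assumptions

* Posterior mass is informative even when individual pairwise alignments
  are unreliable; the consistency average is what injects
  multi-sequence evidence into pairwise matrices. The benefit is largest
  in the twilight zone (below ~30% identity), which is also where the
  method is evaluated here.
* Entries below a small threshold carry negligible signal; discarding
  them (sparsification) trades a bounded accuracy loss for a large
  memory/time gain.
* The guide tree only fixes the merge order; errors there are partly
  recoverable by refinement.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `c_reps` | 2 | consistency rounds |
| `r_reps` | 10 | refinement iterations |
| `tau` | 0.01 | static sparsification / per-round drop threshold (probability) |
| `f` | 0.15 | adaptive mode: fraction of a matrix's positive entries retained |
| `seed` | 1 | refinement split stream |
| `workers` | 1 | processes for pair-level stages (never changes output) |

Increasing `c_reps` beyond 2 tends to *lose* accuracy under static
filtering, because each extra round discards more sub-threshold
elements than the extra averaging gains; that interplay is exactly what
the adaptive (accurate) mode addresses.

**Accurate mode** (`accurate = TRUE`) replaces the global threshold by a
per-matrix one chosen so that each matrix retains the fraction `f` of its
positive entries. A global cutoff removes far more mass from distant
pairs (whose entries are small across the board) than from close pairs;
the per-matrix quantile equalises the information loss. Two choices here
were genuinely open and are fixed as follows: the reference population
for `f` is *all positive entries* of the dense matrix (the most inclusive
reading, making `f` interpretable across matrices); and adaptive
filtering applies both when stage-I matrices are first sparsified and
after every consistency round, behind the single `accurate` switch.
Ties at the cutoff value are kept in (row, column) lexicographic order
and trimmed from the end so the retained count is exactly `⌈f·N⌉`.

**Model parameters.** The five-state HMM (match plus short/long insert
pairs on either side) uses transition scalars in the conventional
ProbCons-family range (short-gap open 0.01195, extend 0.3966; long-gap
open 0.00801, extend 0.8989) and match emissions derived from BLOSUM62:
the Boltzmann transform t(a,b) ∝ q_a q_b 2^{s(a,b)/2} at the table's
half-bit scale, with the background q taken at the self-consistent fixed
point (q equals the marginal of t). Insert states emit q. The partition
function uses the same half-bit BLOSUM62 scores with β = 1, gap open
−4.5 and gap extension −0.25 — a recalibration of Probalign-style
Gonnet-scale settings onto the BLOSUM62 scale, so a confident identity
match outweighs a gap opening by a similar margin. All scalars can be
overridden via a plain-text `key = value` parameter file
(`read_params_file()`); none of them is load-bearing for the package's
correctness claims, which are all oracle-based.

## Numerical choices

* Both posterior models run in log space (log-sum-exp), so pairs up to
  several thousand residues cannot underflow; correctness is defined by
  the full-matrix semantics, not by any storage trick.
* The partition function treats a gap run of length L as
  `gap_open + (L−1)·gap_ext`, terminal gaps included; the posterior cell
  factorises as prefix ensemble × match weight × suffix ensemble, which
  is exact because a match at (i, j) interrupts any gap run.
* Degenerate inputs: duplicate sequences produce zero-length terminal
  branches; these are clamped to 1e-9 only on *terminal* edges so
  duplicates keep a positive ClustalW weight while symmetric trees still
  give exactly equal weights. UPGMA ties are broken toward the pair with
  the lexicographically smallest leaf labels; MEA traceback ties prefer
  diagonal, then consuming the first profile.
* The refinement RNG is an explicitly named Mersenne-Twister stream,
  private to the call (the caller's RNG state is saved and restored), so
  a fixed seed reproduces bit-identical alignments across platforms and
  worker counts.
* Relaxation never creates elements, and filtering never enlarges
  values, so element counts are non-increasing across rounds — asserted
  exactly, not approximately, in the tests.

## The synthetic-family generator

`evolve_family()` simulates an ancestor of given length and mutates it
along a star, balanced, or random binary topology. Substitutions replace
a residue uniformly among the other letters at a fixed per-site,
per-branch probability; indels occur per-site per-branch with geometric
lengths. Every residue carries a homology-column key, so the true
multiple alignment of the leaves is recorded exactly, with a full core
mask (every simulated column is a genuine homology statement). Default
study conditions used throughout the tests: families of 8 sequences,
ancestor length 80, substitution rate 0.35 and indel rate 0.05 per
branch, which lands the families in the twilight zone (mean pairwise
identity ≈ 15–20%).

What the generator does *not* emulate: position-specific substitution
preferences (a uniform Jukes–Cantor-style process over 20 letters, no
empirical rate matrix), rate heterogeneity across sites, domain
shuffling, and compositional bias. Passing tests therefore demonstrate
algorithmic correctness and the direction of the consistency effect
under controlled conditions — not benchmark-level accuracy on real
protein families.

## What the tests establish

* Stage-I posteriors agree with exhaustive path/alignment enumeration
  oracles to 1e-9 per cell on short sequences (all pairs of length ≤ 2
  over a 4-letter reduced alphabet, plus 200 longer random pairs
  covering every length combination up to 4).
* The sparse consistency round equals a dense matrix-product reference
  to 1e-9 on random instances (up to 8 sequences, lengths up to 12), and
  the MEA kernels attain the brute-force monotone-matching optimum on
  grids up to 7×7 (200 seeds each).
* The full pipeline, on 50 seeded families (4–10 sequences, ancestor
  length 40–120), degaps to its inputs, emits no all-gap column, and is
  bit-identical across runs and across 1 vs 4 workers.
* On 20 twilight-zone families, mean SP with two consistency rounds is
  at least the mean without consistency. This is a stochastic, batch-mean
  property; individual families can and do go either way.

These problem sizes were chosen to exercise every code path at
enumeration-checkable scale; all stages scale to realistic family sizes
(hundreds of sequences, thousands of residues) limited mainly by the
quadratic number of pairs.

## Known limitations

* No GPU or anti-diagonal wavefront execution; parallelism is pair-level
  via forked workers, with a snapshot-merge contract that keeps outputs
  worker-count-independent.
* Nucleotide support uses a simple +5/−4 substitution model; it is
  functional but untuned.
* Refinement accepts every realignment unconditionally (replacement, not
  hill climbing); with pathological posteriors it can cycle rather than
  converge, which is why the iteration count is fixed rather than
  convergence-based.
* The SP/TC scorer counts reference pairs only in columns with at least
  two residues and requires exact column-content reproduction for TC,
  the usual benchmark-scoring convention; alternative conventions exist
  and give slightly different numbers.
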