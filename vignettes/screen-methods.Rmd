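---
title: "Sketching and sampling screens: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sketching and sampling screens: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readscreen)
```

## The problem

Assigning long reads (PacBio HiFi, Oxford Nanopore) to their source genome
within a known reference collection does not require alignment: for
low-error reads of 10 kb, a small subset of each genome's canonical k-mers
is enough to identify the source with high confidence. `readscreen` builds
such a subset — a *screen* — per reference genome, and classifies each read
to the screen element with which it shares the most stored hashes. The
appeal is economy: the screen stores a few percent of the genomes' k-mers,
classification touches only those, and the screen is reusable and editable
(genomes can be added or removed without rebuilding the rest).

## Sizing the screen

All five selection strategies are sized by the same rule. Let t be the
number of stored hashes a read should share with its true source ("target
matches"), R the read length, e the per-base error rate and n the genome
size. A read covers R bases, a fraction (1−e)^k of its k-mers survive
sequencing error intact, so the per-genome sketch size is

    s = ceil( t · n / (R · (1−e)^k) )

`sketch_size()` implements this; `error_free_kmer_fraction()` exposes the
correction term. At e = 1% and k = 21 about 81% of k-mers survive, at 5%
about 34%, and near 10% only about one in ten — which is why the approach
favours long, low-error reads and why screens grow sharply with error rate.
Rounding is `ceil` (the target density is a floor, not an average), and s
is capped at the n − k + 1 available k-mer positions. For multi-contig
genomes n is the summed contig length and positional selection apportions
across contigs through a concatenated coordinate space.

## The five strategies

All strategies operate on canonical k-mers (the lexicographic minimum of a
k-mer and its reverse complement), hashed by a seeded 64-bit mixer whose
output is masked to 53 bits so every hash is exactly representable in an R
double; screens are comparable only at equal seed. Windows containing
non-ACGT characters are skipped. A test-only identity mode exposes the
2-bit encoding directly (exact for k ≤ 26), enabling brute-force oracles.

* **Uniform** — one k-mer every n/s bases, at positions `round(i·n/s)`.
  Guarantees the spacing of stored k-mers; if a target window is invalid
  the nearest valid window to the right is used.
* **MinHash** — the s smallest distinct hash values, found in one pass
  with a bounded max-heap (memory O(s)). Since hashing permutes k-mer
  space, this is a uniform random sample of distinct k-mers.
* **Weighted MinHash** — MinHash plus a per-hash weight: the number of
  genomes in the screen minus the number of genomes containing the hash,
  with hashes unique to one genome further multiplied by M. Weights are
  recomputed whenever the screen's membership changes.
* **Order MinHash** — MinHash plus the positional order of the selected
  hashes, stored both as a position table and as `floor(s/L)` disjoint
  sublists of L consecutive (by position) hashes, remainder dropped.
  Scoring adds an order-agreement term, so rearranged sequences with
  identical k-mer content score lower.
* **Minimizer** — the smallest-hash k-mer of every sliding window of
  `w = max(1, floor(2n/s))` k-mer positions, leftmost on ties. The factor
  two reflects the expected two minimizers per w bases, so the sample size
  is s in expectation (not as a hard cap; in practice counts fall well
  within [0.5s, 2s]). Consecutive selected positions are never more than
  w apart.

## Classification

A read contributes *all* of its canonical k-mer hashes (no read-side
sketching). Against a flat screen the winner is the maximum by
(shared-hash count, secondary score), where the secondary score is the
summed weights of shared hashes (weighted MinHash) or the longest common
subsequence between the shared hashes in read order and in stored genome
order (order MinHash). Remaining ties are broken uniformly at random under
a caller-supplied seed and reported in `tied_with`. Reads whose best count
falls below `min_shared` stay `UNCLASSIFIED`. The default `min_shared` is
1 for simulation experiments; 5 is the recommended threshold for real
reads, where the reference collection may not contain the true source.
Raising the threshold can only move reads from classified to unclassified,
never the reverse.

Accuracy, as reported by `evaluate()`, is the fraction of reads whose
prediction equals the true source; a randomly resolved tie counts as
correct only when the resolution hits the truth.

## Clustered screens

`build_sketch_tree()` arranges the sketches at the leaves of an
average-linkage hierarchy over pairwise Jaccard distances of the stored
hash sets (the sketches themselves are the clustering input, and average
linkage is our choice where several linkages would serve). Internal nodes
hold the union of their children's hashes, optionally downsampled without
replacement: by a constant factor f per merge, or by f^h at height h. We
read "proportional to the height" as compounding (f^h); a multiplicative
schedule f·h would downsample more gently near the root, and the choice is
recorded in the tree parameters rather than asserted as canonical. Each
node draws its subsample under a sub-seed derived from (master seed,
node id), so rebuilding a subtree leaves the rest bit-identical.

Classification descends greedily from the root into the child sharing the
most hashes, stopping unclassified when no child reaches `min_shared`.
Greedy descent is not provably equivalent to the flat argmax, but on
dissimilar communities it agrees with it in ≥ 95% of reads while scoring
fewer stored hashes per read. On a tie, `tie_mode = "stop"` reports the
tied node's subtree instead of guessing — the analogue of classifying to a
lowest common ancestor, useful because ties concentrate among
near-identical genomes near the leaves.

## The simulator

`generate_community()` emulates two regimes: mutually dissimilar
communities (independent uniform-random genomes, whose 21-mer sets
essentially never collide), and communities containing clusters of
near-identical genomes. Each cluster's first member is a random ancestor
and later members are independent mutants at a per-base substitution
divergence d, so a pair is separated by d and shares about (1−d)^k of its
k-mers. `simulate_reads()` draws fixed-length reads from uniform starts
and strands and substitutes each base independently with probability e —
substitutions only, matching the uniform-error model the screens are sized
for; no indels, no quality model, no technology-specific error profile.
Reads never span contig boundaries. What passing tests on this generator
show is that the method behaves as designed under its own error model;
real long reads add indels, non-uniform error, repeats and shared sequence
between unrelated genomes, all of which can only lower accuracy relative
to these simulations.

## Numerical and degenerate-input choices

* Hashes live in 53 bits so doubles hold them exactly; collision
  probability at screen scale (≤ 10^6 stored hashes) is negligible.
* Identity (verification) hashing requires k ≤ 26, where the 2-bit code
  is injective within the 53-bit budget.
* `s` larger than the distinct k-mer count saturates to the full set
  (with a warning for uniform sampling); sequences shorter than k yield
  empty extractions, not errors.
* Minimizer ties within a window go to the leftmost position; linkage
  ties resolve by `stats::hclust`'s deterministic scan order; downsampling
  that would empty a node clamps to one hash with a warning.
* Order MinHash treats genomes as linear; only sublists spanning a
  circular origin would be affected, a handful for short L.

## Problem sizes used in the bundled checks

The package's end-to-end checks run at desk scale, chosen to exercise the
default study conditions (10 kb reads, 1% error, k = 21, t = 100): a
24-genome dissimilar community of 200–300 kb genomes with 40–200 reads per
genome, a 5 Mb host plus ten 500 kb contaminants, and 12-genome hard
communities with two pairs at 99.9% identity. The hard-community
divergence of 0.001 was chosen a priori: at k = 21 siblings then share
~97.9% of k-mers, leaving only ~2 discriminative stored hashes per 10 kb
read, so ties between siblings are frequent enough to measure
misclassification routing without external reference data.

## A small worked example

```{r example}
com <- generate_community(community_spec(6, 50000, rng_seed = 1))
p <- screen_params(k = 21, read_length = 2000, error_rate = 0.01,
                   target_matches = 50, hash_seed = 1)
scr <- build_screen(com$genomes, method_params("minhash"), p)
scr
sim <- simulate_reads(com$genomes, read_length = 2000, error_rate = 0.01,
                      n_reads_per_genome = 20, seed = 2)
res <- classify_reads(sim$reads, scr, seed = 3)
evaluate(res, sim$truth)
```

## Known limitations

Screens from different hash seeds or k are not comparable, and the
package refuses mixed containers rather than guessing. The weighted
method's weights depend on the whole screen, so adding or removing a
genome rewrites every sketch's weights (space O(s) extra per genome, as
the approach inherently costs). Order MinHash scoring is O(L) per
comparison and its LCS tie-break is quadratic in the shared-hash count in
the worst case; both are negligible at tie-break scale but make OMH the
most expensive method. Greedy tree descent can be misled by aggressive
height-proportional downsampling near the root — constant factors of 2–4
are the safe operating range.
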