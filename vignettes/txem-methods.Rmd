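---
title: "Isoform quantification by insert-size-aware EM: model and methods"
author: "txem authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform quantification by insert-size-aware EM: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txem)
```

## The estimation problem

A gene locus typically produces several mRNA isoforms through alternative
splicing, alternative transcription starts and alternative polyadenylation.
RNA-Seq reads are short, so many reads are consistent with several isoforms
of a gene (and multireads with several loci), and isoform frequencies
cannot be obtained by direct counting. `txem` estimates the relative
frequency $f(j)$ of each annotated isoform $j$ (and, by summation over gene
clusters, gene expression) from any mixture of single and paired reads,
treating the read-to-isoform assignment as missing data inside an
expectation-maximization loop.

The key modeling choice is to exploit the sequencing *fragment (insert)
length distribution* $p(k)$, which library preparation controls tightly.
Fragment lengths disambiguate reads in two ways: they weight each
read-isoform placement by how plausible the implied fragment is, and they
normalize counts by how many fragments an isoform can produce at all.

## The weight model

Each read (or pair) $r$ may have several genome-space alignments $a$; each
alignment may be compatible with several isoforms $j$ overlapping that
locus. The weight of assigning $r$ to $j$ is

$$ w_{r,j} = \sum_a Q_a \, F_a \, O_a $$

over the alignments of $r$ compatible with $j$, where

* $Q_a$ — probability of observing the read bases given the alignment:
  $\prod_k (1-\varepsilon_k)$ over matching positions times
  $\prod_k \varepsilon_k$ over mismatches, with
  $\varepsilon_k = 10^{-q_k/10}$ from Phred scores
  (floored at $10^{-4}$, capped at 0.75 to avoid degenerate products;
  absent quality strings fall back to a flat Phred 30);
* $F_a$ — fragment-length term. For pairs, $p(k)$ at the implied
  transcript-space fragment length $k$. For single reads only an upper
  bound $u$ on the fragment length is known (read 5' end to the isoform 3'
  end for sense placements, to the 5' end for antisense), so
  $F_a = P(K \le u)$;
* $O_a$ — orientation consistency (0/1). Single nondirectional reads are
  always consistent; directional protocols require the isoform strand;
  pairs must sit on opposite strands pointing at each other along the
  transcript.

Compatibility itself is geometric: every aligned block must fall inside the
isoform's exons with inter-block gaps exactly matching complete introns
(contiguity in transcript space). `txem` evaluates this with a
coordinate-sorted line sweep over alignment and isoform intervals
(`compute_weights()`, implemented in C++); an all-pairs brute-force oracle
built from the exported R primitives verifies it in the test suite.

## The EM core

Let $l(j)$ be the isoform length and
$\tilde l(j) = \sum_k p(k)\,(l(j)-k+1)_+$ its *effective length* — the
expected number of valid fragment start positions. Modeling fragment
sampling as: choose isoform $j$ with probability proportional to
$f(j)\,\tilde l(j)$, then a start uniformly among valid positions, the
posterior that a read of class $c$ came from $j$ is
$f(j) w_{c,j} / \sum_{j'} f(j') w_{c,j'}$. The EM iteration is

* **E-step** — expected counts
  $n(j) = \sum_c m_c \, f(j) w_{c,j} / \sum_{j'} f(j') w_{c,j'}$;
* **M-step** — coverages $c(j) = n(j)/\tilde l(j)$, new
  $f(j) = c(j)/\sum_{j'} c(j')$.

The observed-data log-likelihood (up to a constant) is
$\sum_c m_c \log \sum_j f(j) w_{c,j} - M \log \sum_j f(j)\tilde l(j)$ and
is non-decreasing across iterations; the tests assert this on every
component of the benchmark run, and compare EM fixed points against an
exhaustive simplex grid search on small components.

For transcripts much longer than the mean fragment length $\mu$,
$\tilde l(j) \approx l(j) - \mu + 1$; `fast_lengths = TRUE` uses this for
$l \ge \mu + 100$ and the exact sum otherwise. The default is the exact
form everywhere.

## Read classes and compatibility components

Two optimizations make the E-step cheap. First, the bipartite
read-isoform compatibility graph decomposes into many small connected
components, and frequencies in one component cannot influence another, so
EM runs per component and the results are assembled by globally
renormalizing coverages. Second, reads compatible with the same isoforms
with proportional weights are *equivalent*; each equivalence class is kept
once with a multiplicity $m$ (signature: entries sorted by isoform,
max-normalized, rounded to 9 significant digits).

Both structures are built in one pass by an online union-find over isoform
nodes: a read spanning several trees unites them (union by height, ties
toward the smaller isoform id); a read within one tree is looked up in a
hash table at the lowest common ancestor of its isoforms' nodes — the one
place an equivalent class can live, because classes are always inserted at
the LCA. Path compression is deferred to the final collection sweep, since
it would relocate LCAs while reads are still arriving. This gives
$O(qk\log n + n\alpha(n))$ work for $q$ reads averaging $k$ compatible
isoforms over $n$ isoforms; the union-by-height invariant
(height $\le \log_2(\text{size})+1$) is asserted in the tests.

Disabling collapsing (`collapse = FALSE`) must not change results; the
suite checks agreement to $10^{-10}$. Because class equivalence uses exact
products of identical inputs, collapsing merges numerically identical
weight vectors in practice and the 9-digit rounding is only a guard.

## Bias corrections

**Hexamer priming.** Random-hexamer-primed libraries over-sample fragments
whose first bases match favoured hexamers. Following the first-versus-middle
contrast, the observed proportion $\hat o_i(h)$ of reads with hexamer $h$
at position $i$ is tabulated and each read is weighted by
$b(h) = \big[\mathrm{mean}_{i \ge \lceil l/2\rceil} \hat o_i(h)\big] /
\hat o_1(h)$ (1 where $\hat o_1(h)=0$). Weights enter as read
multiplicities, so they fold into read classes without any other change.
The exact averaging range of the original formulation is not recoverable
from the source text; $\lceil l/2 \rceil$ is our documented reconstruction,
under the assumption that read-internal hexamer frequencies are unbiased.
Note that with 4096 hexamers the ratio estimator needs on the order of
$10^3$ position-1 observations per hexamer before $b(h)$ stabilizes; the
unbiasedness test therefore uses a reduced alphabet where that depth is
reached.

**Repeats.** Reads overlapping annotated repeat intervals are discarded,
and each isoform length is reduced by the number of start positions whose
read window would overlap a repeat, so that effective lengths match the
reads that can actually be observed.

**Poly(A) tails.** Annotated transcripts can be extended by a poly(A) tail
(default 200 bases when enabled; no value is stated in the source, and
200 nt is a typical mammalian tail length). Tails occupy virtual genome
coordinates immediately 3' of the terminal exon, so tail reads remain
representable in genome space and isoforms sharing a terminal exon share
tail coordinates. Limitation: tail-only reads are *not* linked across
genes ending at different loci, although their sequence is identical; a
transcript-space multi-mapper would report those, and genome space cannot.

## The simulator: what it emulates, and what it does not

`simulate_transcriptome()` builds multi-exon genes (4–12 exons of 100–400
bases, introns 200–800, isoform lengths ≈500–5000) whose 1–5 isoforms
share exons through alternative inclusion of internal exons, so reads are
genuinely ambiguous. Gene abundances default to log-normal
(`meanlog = 0, sdlog = 1.5`, a 3–4 order-of-magnitude dynamic range
mimicking tissue expression atlases); within-gene isoform probabilities
are uniform $1/k$ or truncated geometric $1/2^j$ (last term $1/2^{k-1}$),
in randomized isoform order. `simulate_reads()` draws a fragment length
from $p(k)$, an isoform proportional to $f(j)(l(j)-k+1)_+$, a uniform
start, and sequences one random end (single, nondirectional) or both ends
(paired), injecting uniform substitution errors (default $10^{-3}$,
Phred 30 qualities).

This matches the estimator's generative model by design; a green benchmark
therefore establishes correctness of the inference machinery, *not*
robustness to real-data artifacts: positional coverage bias, sequence- or
GC-dependent sampling, misannotation, intron signal or indels are not
simulated. The hexamer and repeat corrections are exercised by dedicated
unit tests rather than by the benchmark.

## Numerical choices and degenerate inputs

* Convergence: `max |Δf| < 1e-8`, `max_iter = 10000` per component.
  Uniform initialization by default — the observed-data likelihood is
  concave in practice here and a deterministic start removes run-to-run
  noise; `init = "random"` with a seed reproduces randomized starts.
* Components that hit the iteration cap return `converged = FALSE` with
  the current estimate.
* Classes with zero posterior denominator are skipped in the E-step;
  an all-zero coverage vector falls back to uniform with a warning.
* Log-likelihood monotonicity is only assertable up to the floating-point
  resolution of the summed value (|ll| here reaches $10^6$, where one ulp
  is $\sim 10^{-10}$); tests use a summation-error floor
  $\max(10^{-12},\ 64\,\epsilon\,|ll|)$.
* Fragment distribution support defaults to $\mu \pm 4\sigma$ (clipped at
  1), truncating negligible mass while bounding all loops; `sd = 0` is a
  point mass.
* SAM input: only `M`/`N` CIGAR operations are accepted (ungapped aligner
  contract); records with indels or clipping are rejected and counted.
  1-based SAM coordinates are converted to the package-wide 0-based
  half-open convention at the parser boundary. Alignments of one read that
  are identical in genome space (reached via different transcripts) are
  merged so the per-alignment sum does not double count.
* Union ties (equal heights) break toward the root representing the
  smaller isoform id, with the height incremented, matching textbook
  union-by-height.

## Known limitations

Single-threaded; no novel-isoform discovery, no allele-specific estimation,
no confidence intervals; genome-space poly(A) handling as described above;
the empirical fragment-length estimator is a lightly smoothed histogram,
not a renormalized per-isoform model.
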