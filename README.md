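# txem — isoform and gene expression from RNA-Seq by EM

`txem` estimates the relative expression of annotated transcript isoforms
(and, by summation over gene clusters, of genes) from RNA-Seq read
alignments. Short reads rarely identify their isoform of origin uniquely —
a read inside a shared exon is consistent with every isoform containing
it — so counting cannot work at the isoform level. `txem` treats the
read-to-isoform assignment as missing data and estimates frequencies with
an expectation-maximization algorithm whose distinguishing feature is the
explicit use of the sequencing **fragment (insert) length distribution**,
together with base quality scores, strand and read pairing information.

It is aimed at anyone benchmarking or building transcript-level
quantification: it ships a complete, tested implementation of the model,
a read simulator that generates synthetic transcriptomes, truth tables and
FASTQ/SAM data, and the standard accuracy metrics (r², error fraction
EF_τ, median percent error).

## Model

Each read r gets a weight against every compatible isoform j,

    w_rj = Σ_a  Q_a · F_a · O_a

summed over the read's alignments: Q is the base-quality likelihood
(Π(1−ε_k) over matches × Π ε_k over mismatches), F the fragment-length
probability (p(k) at the implied insert size for pairs; P(K ≤ u) for
single ends, u the largest fragment the placement allows), and O ∈ {0,1}
orientation consistency. With effective length
l̃(j) = Σ_k p(k)·(l(j)−k+1)₊, EM alternates

    E-step:  n(j) = Σ_c m_c · f(j) w_cj / Σ_j' f(j') w_cj'
    M-step:  f(j) = (n(j)/l̃(j)) / Σ_j' (n(j')/l̃(j'))

per connected component of the read–isoform compatibility graph. Reads
with identical isoform sets and proportional weights are collapsed into
classes with multiplicity m_c by an online union-find (classes stored at
the LCA of their isoform nodes), which makes runtime nearly independent of
read count once classes saturate. Optional corrections: hexamer-priming
reweighting, repeat masking with length adjustment, poly(A) tail
extension. See `vignettes/txem-methods.Rmd` for the full account.

## Worked example

```r
library(txem)
tr    <- simulate_transcriptome(n_genes = 50, isoforms_per_gene = 1:5, seed = 42)
truth <- assign_true_frequencies(tr$txome, mode = "geometric", seed = 43)
sim   <- simulate_reads(tr$txome, tr$seqs, truth, n_reads = 50000,
                        read_len = 25, dist = frag_dist_normal(250, 25),
                        error_rate = 0.001, seed = 44)
fit   <- quantify(reads_to_alignments(sim), sim$txome, dist = sim$dist)
fit
#> txem_fit: 152 isoforms, 50 genes
#>   reads 50000 (dropped 0), classes 1069, components 50
#>   EM iterations 29597, converged: FALSE

head(fit$isoforms, 5)
#>       tx_id gene_id    frequency expected_count effective_length       fpkm
#> 1 G00001.I1  G00001 6.509970e-03     234.000000             1074 4357.54190
#> 2 G00002.I1  G00002 8.979319e-05       3.558178             1184   60.10436
#> 3 G00002.I2  G00002 1.460944e-04       4.444574              909   97.79041
#> 4 G00002.I3  G00002 4.086913e-04      10.997248              804  273.56338
#> 5 G00003.I1  G00003 1.376761e-03      37.276900              809  921.55502

ev <- evaluate_estimates(fit$isoforms$frequency, truth$true_freq)
sprintf("isoform r2 = %.4f, MPE = %.2f%%", ev$r2, ev$summary$mpe[nrow(ev$summary)])
#> "isoform r2 = 0.9948, MPE = 15.65%"
```

`frequency` is the estimated fraction of transcript molecules,
`expected_count` the EM-allocated fragment count, `effective_length` the
insert-size-aware length used for normalization, `fpkm` the usual
per-kilobase rate. `converged: FALSE` means a few ambiguous components hit
the 10 000-iteration cap at tolerance 1e-8; their estimates are still
reported. The r² of 0.995 against the simulated truth is typical at this
depth.

Quantifying real alignments instead:

```r
fit <- quantify("aln.sam", "annotation.gtf", dist = frag_dist_normal(250, 25))
```

A command-line front end mirrors the R API
(`inst/cli/txem simulate|quantify|evaluate|bench ...`).

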