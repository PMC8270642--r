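# hgtmatch

Alignment-free detection and quantification of horizontal gene transfer
(HGT) from long exact sequence matches.

## The problem

Orthologous sequences of bacteria from different genera rarely exceed
90–95% nucleotide identity, so an exact match of 300 bp between two such
genomes has a chance probability of roughly 0.9³⁰⁰ ≈ 10⁻¹⁴ — effectively
zero, even across millions of genome pairs. Long exact matches between
distant taxa are therefore xenologs: sequences shared because of recent
horizontal transfer. This package is for microbiologists and genome
bioinformaticians who want to detect such events, estimate how often two
taxa exchange DNA, and date individual transfers — without alignments,
phylogenies, or gene annotation.

## The model

A transfer event places a segment of length *K* ≫ 1 bp in both genomes;
substitutions at rate *μ* per bp per generation in each lineage then
break it up, so after time *t* the surviving exact matches are
exponentially distributed with mean 1/(2*μt*):

> m(r | t) = (f₁f₂K / L₁L₂) · (2μt)² · e^(−2μtr)

With events at constant rate *ρ* (ages uniform over the past),
integrating over *t* gives a power law with fixed exponent −3:

> m(r) = A / r³,  A = K f₁ f₂ ρ / (L₁ L₂ μ)

The prefactor *A* is an effective transfer rate per genome length; it is
estimated from data by a one-parameter fit (slope held at −3, intercept
ln A free) to the logarithmically binned tail (r ≥ 300 bp) of the
normalised match-length distribution m(r) = M(r)/(ℓᵢℓⱼ). Inverting the
model dates a match of length *r* to t_ML = 1/(μr) generations.

The package provides: a native maximal-exact-match finder (k-mer seeded,
both strands, all matches regardless of uniqueness, N never matches),
MLD construction/binning/fitting, the closed-form model (including
deletion-suppressed and general Taylor age distributions), a forward
simulator with planted-xenolog FASTA fixture generation, weighted
enrichment arithmetic, and a command-line entry point
(`inst/scripts/hgtmatch`).

## Worked example

Plant two transfer events — one brand new (t = 0), one a million
generations old — into a pair of 50-kb genomes, and recover them:

```r
library(hgtmatch)
pair <- generateGenomePair(50000, 50000,
    planted = data.frame(K = c(500, 1200), t = c(0, 1e6),
                         strand = c("forward", "reverse")),
    mu = 1e-9, seed = 42)
A <- ContigSet(pair$seqA, taxonLabel = "GenusA")
B <- ContigSet(pair$seqB, taxonLabel = "GenusB")
(m <- findAllPairs(A, B, minLength = 300))
#> DataFrame with 3 rows and 6 columns
#>        ref_id      qry_id ref_start qry_start    length      strand
#> 1     genomeA     genomeB     22364     24740       500     forward
#> 2     genomeA     genomeB     42955     35303       347     reverse
#> 3     genomeA     genomeB     43303     35651       693     reverse
```

The fresh 500-bp event comes back intact at its planted locus; the aged
1200-bp event took one substitution and is recovered as two adjacent
reverse-strand pieces (347 + 693 = 1199 bp + 1 mutated site) — the
fragmentation process the model is built on, visible in a single event.

The forward simulator confirms the steady-state predictions: 20,000
events of K = 5,000 bp with ages uniform up to t_max (chosen so the
oldest events fragment to a 30-bp mean, far below the 300-bp threshold):

```r
sim <- simulateSteadyState(20000, K = 5000, mu = 1e-9,
                           tMax = 1 / (2e-9 * 30), seed = 1)
b <- binLogarithmic(mldFromLengths(sim$fragments[sim$fragments < 5000]),
                    rMin = 300, binsPerDecade = 8)
fitFreeSlope(b)$slope
#> [1] -3.007065
fitPrefactor(b)
#> PowerLawFit: m(r) = A / r^3
#>   A = 6.041e+09  (ln A = 22.52 )
#>   fit range: [ 346.4346 , 4619.78 ] bp over 10 bin(s); residual RMS = 0.0433
```

The free slope lands on −3, and the fitted prefactor matches the closed
form A = K·(nEvents/t_max)/μ = 6.0 × 10⁹ within 1%. Dating works the
same way from the command line:

```sh
inst/scripts/hgtmatch age --length 19117 --mu 1e-9
# {"length_bp":19117,"mu":1e-09,"generations":52309.46...,"years":59.67...}
```

A 19,117-bp match between two genomes from different phyla dates the
transfer to about 60 years ago; a 300-bp match sets the method's
detection horizon at ~3.3 × 10⁶ generations (order a thousand years).

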