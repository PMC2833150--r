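# loopwords

Systematic mining of recurrent structural motifs in protein loops using a
structural alphabet and word statistics.

## The problem

Loops — everything between α-helices and β-strands — hold about half of
all protein residues and much of their function, yet they are too
variable in sequence and geometry for secondary-structure tools, and long
loops in particular resist whole-loop classification. `loopwords`
sidesteps structural alignment entirely: it discretizes each C-alpha
trace into a string over a **structural alphabet** — a hidden Markov
model whose states are four-residue backbone prototypes ("structural
letters") with Gaussian emissions over four inter-Cα descriptors — so
that a chain of *n* residues becomes a string of *n* − 3 letters. Loops
are then runs of letters between simplified helices and strands, and
every loop of ℓ letters is decomposed into its ℓ − *k* + 1 overlapping
*k*-letter **structural words** (default *k* = 4, i.e. seven-residue
fragments). All fragments sharing a word form a cluster, which is scored
four ways:

- **Structural variability** — RMSd*w*, the mean Kabsch-superposed Cα
  RMSD over sampled member pairs (and RMSd*dev* between clusters).
- **Sequence specificity** — positional amino-acid Z-scores
  *Z* = (obs − μ)/√μ with μ = *N*<sub>a,ℓ</sub>·*N*<sub>w</sub>/*N*
  (Poisson standardization; cells with μ ≤ 5 masked), summarized by
  *Z*max and the number of significant positions.
- **Loop-type preference** — the Kullback-Leibler divergence
  KLD(*w*) = Σ<sub>ℓ</sub> *p*<sub>w,ℓ</sub> ln(*p*<sub>w,ℓ</sub>/*p*<sub>ℓ</sub>)
  between a word's distribution over loop types (short/long, flank
  classes αα/αβ/βα/ββ, or their 8-type product) and the bank-wide
  distribution, tested via the G statistic 2·*N*<sub>w</sub>·KLD with
  Benjamini-Hochberg correction.
- **Statistical exceptionality** — each word's observed count is compared
  with its distribution under a first-order Markov background fitted on
  the loop corpus, computed **exactly** by embedding the word's pattern
  automaton in the letter chain and running a dynamic program per
  sequence length (self-overlaps counted; compound-Poisson approximation
  for very large corpora). Tail p-values become signed scores
  *L<sub>p</sub>* = −log₁₀ *p*(over) (or +log₁₀ *p*(under), negated),
  and words are classed OR / NS / UR at |*L<sub>p</sub>*| > 5.94.

The exact published 27-letter parameterization is not redistributable, so
the package ships the model-file format, a seeded Baum-Welch trainer, a
27-state template, and a small fixture model trained on its own synthetic
structures.

## Worked example

```r
library(loopwords)
model <- readAlphabetModel(system.file("extdata", "fixture_alphabet.json",
                                       package = "loopwords"))
syn    <- genStructures(nChains = 8, dir = tempfile(),
                        architecture = c("helix","loop","strand","loop","helix"),
                        seed = 11)
chains <- readStructures(syn$files, minResidues = 20)$chains
letters <- vapply(chains, function(ch)
  as.character(encodeStructure(ch, model)), "")
cat(letters[[1]])
#> AAAAAAFKBBBBGLLLLLLBBBBBBGFAAAAAAAA
```

The helix spans encode as runs of `A`, the strand as `L`, and the
connecting loops as coil letters. Extracting loops and words:

```r
loops <- extractLoopsFromStrings(letters)
head(loops[, c("loop_id","letters","n_letters","flank_class","length_class")], 3)
#>         loop_id  letters n_letters flank_class length_class
#> 1  syn01_A:7-13  FKBBBBG         7          ab        short
#> 2 syn01_A:20-27 BBBBBBGF         8          ba        short
#> 3  syn02_A:7-13  FKBBBBG         7          ab        short

frag <- buildFragments(loops, chains)
cw   <- clusterWords(frag, minCount = 5)
bg   <- fitBackground(loops$letters)
exc  <- wordExceptionality(setNames(as.list(cw$summary$N_w),
                                    cw$summary$word)[cw$retained], bg)
exc[order(-exc$lp), c("word","N_w","expected","lp","class")]
#>   word N_w  expected         lp class
#> 2 BBBG  16  6.664522  5.4562186    NS
#> 1 BBBB  53 35.405273  1.6793198    NS
#> 3 BBGF   8  7.919020  0.2398526    NS
#> 5 KBBB   8  8.633236 -0.3229446    NS
#> 4 FKBB   8 11.575428 -1.1214003    NS

intraWordRMSD(cw$clusters[[cw$retained[1]]], seed = 1)
#> [1] 0.7260332
```

`BBBB` is seen 53 times against 35 expected but the excess does not
reach the |*L<sub>p</sub>*| > 5.94 significance threshold on a corpus
this small, so every word is classed NS; the retained cluster's
intra-word RMSD of 0.73 Å shows the low structural variability typical
of recurrent words. `coverageRate()`, `zscoreProfile()` and
`loopTypePreference()` complete the per-word characterisation, and
`runPipeline()` chains every stage, writing TSV tables and a JSON
manifest.

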