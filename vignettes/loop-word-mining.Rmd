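---
title: "Mining protein loops with structural words: models and methods"
author: "loopwords"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining protein loops with structural words: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopwords)
```

This vignette is the package's own account of the science it implements:
the models, the tunable parameters and why their defaults are what they
are, what the synthetic generators do and do not emulate, and the
numerical and design choices that were genuinely open.

## 1. The structural alphabet model

A structural alphabet discretizes backbone geometry: each state of a
hidden Markov model is a four-residue prototype fragment ("structural
letter"), and decoding a chain yields one letter per overlapping
four-residue fragment, i.e. $n-3$ letters for $n$ residues. The full
alphabet has 27 letters named A–Z plus a; letters $\{a, A, V, W\}$
describe helices and $\{L, M, N, T, X\}$ strands, the remaining 18
describe loops.

**Descriptors.** Each fragment $(r_1, r_2, r_3, r_4)$ is summarized by
four inter-C$\alpha$ quantities. The literature fixes their number but
not the exact set, so the package adopts a convention and documents it:
the three non-adjacent distances $d(r_1,r_3)$, $d(r_1,r_4)$, $d(r_2,r_4)$
plus the *signed* distance of $r_4$ to the plane $(r_1,r_2,r_3)$. The
sign is essential — it is the only carrier of handedness, and without it
left- and right-handed helices are indistinguishable. Because
consecutive fragments share three residues, $d(r_2,r_4)$ of fragment $i$
equals $d(r_1,r_3)$ of fragment $i+1$; the implementation computes each
distance once, so the identity holds to machine precision, and the test
suite asserts it.

**Emissions and decoding.** Emissions are full-covariance Gaussians per
state (a diagonal option exists for small training sets). Decoding uses
the Viterbi algorithm in log space — products of hundreds of densities
underflow otherwise — and breaks exact ties toward the letter earliest
in alphabet order, so encodings are deterministic across platforms.

**Training.** The published 27-letter parameters are not printed
anywhere reusable, so the model is an *input*: a JSON file with the
letters, initial distribution, transition matrix and emission moments.
The package ships a seeded Baum–Welch trainer (k-means initialization,
monotone log-likelihood asserted per iteration, collapsed states
re-seeded from random fragments with a warning) plus a 27-state
template, and a 6-letter fixture model (`inst/extdata/
fixture_alphabet.json`) trained once, with a fixed seed, on the
package's own synthetic structures. In that fixture the helix-dominant
state was named `A` and the strand-dominant state `L`, so the default
segmentation patterns apply to fixture encodings too. Tests verify that
an ideal helix trace encodes as a constant run of `A`.

## 2. Loops and structural words

Helix and strand segments are maximal regular-expression matches over
the letter string; the published bounding expressions are not printed,
so the defaults are the minimal runs consistent with the geometry — a
helix turn needs four residues (`[AaVW]{4,}`) and a strand three letters
(`[LMNTX]{3,}`) — and both are configurable, with helix matches given
precedence where sets overlap. Everything else is coil. Internal coil
segments of at least 4 letters (the word length, so that every loop can
contribute at least one word) become loops; terminal coils are excluded
by default because every flank class (αα, αβ, βα, ββ — written `aa`,
`ab`, `ba`, `bb` in the tables) requires two structured neighbours. A
loop of $\ell$ letters spans $\ell + 3$ residues, and loops of more than
12 residues ($\ell \ge 10$) are classed long.

Words are the $\ell - k + 1$ overlapping $k$-letter substrings. The
default $k = 4$ (seven residues) is the sparsity optimum identified by
the word-length survey that `wordLengthSurvey()` reproduces: longer
words explode the number of distinct types faster than the data can
populate them. Words beginning or ending with a secondary-structure
letter are excluded — such fragments protrude into the flanks rather
than describing the loop. Clusters with at least 30 members (the
recurrent set) are retained by default; the survey's own phrasing
wavers between "more than 30" and "at least 30", and the package reads
the operational footnote, $N_w \ge 30$, keeping the threshold
configurable. Coverage is reported per structural letter: the union of
letters spanned by matches, never double-counting overlaps. Clusters
whose mean member B-factor exceeds 40 Å² (strictly) are flagged as
high-positional-uncertainty, the usual rule of thumb for mobile regions.

## 3. Per-word statistics

**RMSD.** Superposition is least-squares (Kabsch via SVD) with
reflections disallowed — the field standard for C$\alpha$ RMSD; tests
cross-check it against an independent quaternion implementation and
against `bio3d`. RMSd$_w$ averages all pairs among $\min(30, N_w)$
members sampled without replacement under an explicit seed; RMSd$_{dev}$
averages 30 seeded cross-pairs between two clusters (the estimate
depends on the seed and sampling order, but is symmetric in
expectation). Sampling keeps the cost of large clusters bounded at
$\binom{30}{2}$ superpositions.

**Z-scores.** For amino acid $a$ at position $l$, the observed count in
a cluster of size $N_w$ is compared with
$\mu_{a,l} = N_{a,l} \, N_w / N$, the count expected if the cluster drew
from the bank of $N$ fragments at random, standardized as
$Z = (\mathrm{obs} - \mu)/\sqrt{\mu}$ — the Poisson approximation to the
underlying binomial. The exact formula was garbled in the source
material's typesetting; this standardization matches its stated Poisson
approximation and validity rule, and the tests confirm it agrees with
the exact binomial tail's z-equivalent in the regimes where both apply.
Cells with $\mu \le 5$ are masked invalid and never contribute to
$Z_{\max}$ or to the count of significant positions; the significance
cutoff of 4 is adopted as a constant (its original Bonferroni arithmetic
is not reconstructible). $Z_{\max}$ is the maximum *signed* Z — the
summaries describe over-representation. Euclidean distances between
140-cell profiles treat masked cells as 0 in both vectors, a convention
that keeps distances comparable across words with different masks.

**Loop-type preference.** $KLD(w) = \sum_l p_{w,l}
\ln(p_{w,l}/p_l)$ in nats, with $0 \ln 0 = 0$; natural logs matter
because only then is $2 N_w KLD$ the G statistic with a chi-square
reference. The source text states $N_w - 1$ degrees of freedom, which is
dimensionally inconsistent with an $L$-category multinomial; the package
defaults to $L - 1$ and offers `dfAsPaper = TRUE` for comparability.
"FPR correction" is read as Benjamini–Hochberg FDR at 0.05 across the
tested words. Global type frequencies are estimated from the loop bank.
The chi-square reference is asymptotic: at $N_w = 100$ with a skewed
background its exact level is $\approx 0.045$, converging to the nominal
0.05 as $N_w$ grows — the calibration test therefore simulates at
$N_w = 200$, where the exact level is 0.049.

## 4. Exceptionality under a Markov background

The background is a first-order Markov chain fitted by maximum
likelihood on the loop letter corpus only (not whole chains) — loops are
the population under study. For a word $w$, its KMP prefix automaton is
embedded in the chain: the dynamic-programming state is (automaton
state, last letter, occurrence count), occurrences counted with
self-overlaps (`XX` occurs three times in `XXXX`). One pass per distinct
sequence length gives that length's exact per-sequence count
distribution; sequences are independent, so per-length distributions are
raised to the length's multiplicity by repeated convolution
(exponentiation by squaring) and convolved across lengths. Counts are
truncated at a bound (default observed + 1) with an overflow bucket;
both tails remain exact because the overflow mass belongs entirely to
the upper tail. Convolutions are direct, not FFT-based, so tail masses
of $10^{-100}$ and below survive arithmetically. $p_{\mathrm{over}} =
P(X \ge N_w)$ and $p_{\mathrm{under}} = P(X \le N_w)$ share the point
mass at $N_w$, hence always sum to at least 1.

For corpora beyond $10^5$ sequences or $10^4$ expected occurrences, a
Pólya–Aeppli (geometric compound Poisson) approximation replaces the
exact convolution: clumps of overlapping occurrences arrive as a Poisson
process with rate $(1-a)E[N]$ and geometric sizes, where $a$ sums the
word's period-extension probabilities. The result records which path
ran; a seeded Monte-Carlo oracle (`mcPvalueOracle()`) with a naive
scanner provides an independent check of either.

Scores are $L_p = -\log_{10} p_{\mathrm{over}}$ when the word is seen at
least as often as expected, $+\log_{10} p_{\mathrm{under}}$ (negative)
otherwise, and the OR/NS/UR classification uses the threshold 5.94 — the
original survey's Bonferroni level, adopted as a configurable constant
because its multiple-testing universe cannot be reconstructed from the
available material. Comparing two databases requires rescaling scores by
the ratio of total letter counts, since large-deviation scores grow
linearly with database size. A word whose transition probability is zero
under the background gets expectation 0 and, if observed, an infinite
score, flagged rather than underflowed.

## 5. Synthetic data: what it does and does not emulate

Three generators make the pipeline fully testable offline, each a pure
function of its arguments including the seed:

- **Letter corpora** sampled from a specified Markov chain, with planted
  words inserted by overwriting random positions at a rate of
  $(f-1) E_0$ copies for enrichment factor $f$ (factor $\le 1$ inserts
  nothing); the truth table reports the analytic background expectation
  and the number of insertions.
- **Structures**: ideal helices (2.3 Å radius, 1.5 Å rise, 100° turn)
  and extended strands joined by linear connectors with Gaussian jitter
  (default $\sigma = 0.4$ Å), written as parseable PDB files with
  resolution headers and B-factors, plus per-residue truth labels.
  Connector geometry only needs to generate descriptor statistics
  distinct from the regular classes; it is *not* a physical loop model —
  no excluded volume, no realistic Ramachandran statistics, no side
  chains. Passing tests therefore demonstrate the machinery, not
  biological realism: real loop descriptor distributions are broader and
  the real alphabet has 27 letters, not the fixture's 6.
- **Fragment sequences** drawn from background amino-acid frequencies
  with designated (position, residue) cells enriched by a fold factor,
  for Z-score recovery tests.

Default sizes in the test and acceptance runs are desk-scale by design
(tens of chains, hundreds of loops, clusters of 30–2000): the original
survey's headline counts come from an 8186-chain snapshot that a
self-contained package cannot and should not re-download. The
calibration suites instead check the *statistical* properties the large
survey relies on: exact DP versus full enumeration on two-letter
corpora, Monte-Carlo agreement within 3 binomial SE on randomized Markov
cases, EM parameter recovery within 0.05 per transition entry, Z-score
null exceedance at the two-sided normal rate within 3 SE (simulated at
$\mu = 100$, where the binomial null is close to its normal limit), and
G-test level within 3 SE of nominal.

## 6. Numerical choices and degenerate inputs

- All probability arithmetic (Viterbi, forward–backward, DP) is in log
  space or rescaled per position; covariance estimates carry a
  $10^{-6}$ ridge and transition/initial updates a $10^{-10}$ floor.
- Viterbi ties break to alphabet order; `which.max`'s first-maximum
  semantics implement this because states are stored in letter order.
- Fewer than 4 residues cannot form a fragment (error); loops shorter
  than $k$ yield an empty word list (not an error); clusters of one have
  undefined RMSd$_w$ (`NA`); all-masked Z-profiles have `NA` $Z_{\max}$
  and 0 significant positions; empty word sets give 0% coverage.
- Chains are filtered, never silently dropped: every rejection carries
  reasons (`min_residues`, `resolution`, `missing_residues`, `altloc`),
  and missing residues are detected both by numbering gaps and by absent
  C$\alpha$ atoms.
- Letters never observed as a transition source get uniform background
  rows, with a warning; a degenerate segmentation pattern that matches
  the empty string is a configuration error.

## 7. Known limitations

- The fixture alphabet is a 6-state stand-in trained on synthetic
  geometry; encodings of real PDB chains with it are structurally
  meaningful only at the helix/strand/coil level. Supply a full model
  file for real analyses.
- The Pólya–Aeppli branch is an approximation with relative tail errors
  of a few percent in the regimes tested; the exact branch covers
  everything the package's own runs produce.
- Sequence-identity redundancy filtering of the input chains, SCOP
  bookkeeping, and the ordination graphics (Sammon maps, correspondence
  analysis) are out of scope; the tables expose everything those
  visualizations would need.
- Only first-order backgrounds are implemented; the interface reserves
  an order argument for future higher-order chains.
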