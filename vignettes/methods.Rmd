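---
title: "Weighted rank concordance for transcription-factor screening: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted rank concordance for transcription-factor screening: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfconcord)
```

## The question the method answers

Given (i) a table of differential expression across the transcriptome and
(ii) a motif model for each transcription factor, which factors' predicted
targets move together — and in which direction? A factor whose
best-scoring promoter sites sit disproportionately on downregulated genes
behaves like a repressor in that contrast; one whose strong sites sit on
upregulated genes behaves like an activator. `tfconcord` formalises this
as a rank-concordance test between two orderings of the same genes.

## The two orderings

**Gene set (S side).** Each promoter (by default the 550 bp upstream of
the TSS, on the gene's strand) is scanned with the factor's position
weight matrix. A window's **Jindex** is its log10 likelihood ratio,

$$J(w) = \sum_p \log_{10} \frac{P_{\text{motif}}(w_p \mid p)}{P_{\text{bg}}(w_p)},$$

so the retention threshold of 1.0 reads as "ten times more likely under
the motif than under background". The Jindex is this package's own
definition of the scan score: upstream motif-scanning tools publish a
score under that name whose exact normalisation is not documented, and
only its threshold and its monotone meaning (higher = more likely a true
site) are fixed; a per-window log-likelihood ratio is the canonical choice
with those properties. A gene joins the factor's target set when it has at
least one retained site; its set score is by default its **maximum**
Jindex (the most confident single site; `sum` and `count` aggregations are
available), and set ranks $S_i$ run from the best-scoring target down,
ties broken by gene identifier.

**Gene list (L side).** Each gene's differential expression collapses to
the raw score of differential expression,

$$\mathrm{RDE} = -\operatorname{sgn}(\log_2 FC)\cdot 2^{|\log_2 FC|}\cdot \log_{10} FDR,$$

positive for significant upregulation, negative for downregulation, zero
at $FDR = 1$. All genes are ranked by descending RDE — no significance
filter, because the test needs the full ordering, including the
uninteresting middle. An $FDR$ of exactly 0 (as upstream tools sometimes
print) is clamped to the smallest positive value in the table.

## The statistic

Restrict both sides to the shared genes, re-rank 1..n within the
intersection, and let $R_i$ be the list rank paired with set rank $i$.
With pair weights $v_i \in (0,1)$ the weighted Kendall's tau is

$$\tau_w = \frac{2}{(\sum_i v_i)^2 - \sum_i v_i^2}
  \sum_{i>j} v_i v_j\, \operatorname{sgn}(i-j)\operatorname{sgn}(R_i-R_j).$$

It is $+1$ on the identity pairing, $-1$ on the reversal, reduces to the
classical Kendall tau for constant weights, and is invariant to rescaling
all weights by a constant. Re-ranking within the intersection (rather
than keeping global list ranks) is what makes the permutation null exact:
under no association $R$ is a uniform random permutation of $1..n$.

### The null variance, derived rather than transcribed

Writing $\tau_w = (2/D)\sum_{i>j} v_i v_j X_{ij}$ with
$X_{ij}=\operatorname{sgn}(R_i-R_j)$ and $D = (\sum v)^2 - \sum v^2$, the
null moments of the $X$ are classical: $\mathrm{Var}(X_{ij}) = 1$;
two pairs sharing an index in the same slot (such as $(i,j)$ and $(i,k)$)
have covariance $+1/3$; a shared index that switches slots (such as
$(i,j)$ and $(j,k)$) gives $-1/3$; disjoint pairs are uncorrelated.
Summing the $v$-products over those three classes (computed in $O(n)$ via
cumulative sums) gives the exact $\mathrm{Var}(\tau_w)$; for constant
weights it collapses to the familiar $2(2n+5)/(9n(n-1))$, which the test
suite verifies along with full $n!$ enumeration at small $n$ and Monte
Carlo at $n = 200$. The standardized statistic
$LD = \tau_w/\sqrt{\mathrm{Var}(\tau_w)}$ is compared with $N(0,1)$
two-sided. This asymptotic route is a reconstruction: the published
limiting-distribution expression for this statistic is typographically
corrupted in the source material, so the package states the contract —
standardize by the exact permutation-null SD — and validates it against
permutation p-values (`permutation_p()`, including exhaustive enumeration
up to $n = 8$) rather than transcribing a formula. Two-sided testing is
used because both directions are scientifically meaningful: a negative
$\tau_w$ with elevated factor expression is the repressor signature.

### Weights

The headline weighting mode, `mixed_density`, reconstructs the "mixed
density of the pooled ranks" idea: pool the normalized set positions
$i/n$ with the paired list positions $R_i/n$, give each point mass
proportional to its gene's $|\mathrm{RDE}|$ (equal mass when RDE values
are unavailable), fit a Gaussian KDE with Silverman's bandwidth, evaluate
at $i/n$, and rescale into $(\varepsilon, 1-\varepsilon)$ with
$\varepsilon = 10^{-6}$. When differential-expression mass concentrates at
the extremes of the list, pairs involving those genes dominate the
statistic — the intended "do the top targets sit among the top movers"
emphasis. Because the construction upstream of this package is not fully
specified, two transparent alternatives ship alongside: `uniform`
($v_i = 0.5$, the classical tau) and `top_linear`
($v_i = (n-i+1)/(n+1)$). Every result row records which mode produced it.

### Multiplicity

p-values are adjusted across all tested factors with Benjamini–Hochberg
(the screening context's standard choice; the multiplicity handling
upstream is unstated). Factors whose set/list intersection is below 3
genes are skipped with a logged reason — below that size the statistic is
vacuous.

## The sliding-window profile

To show *why* a factor is flagged, `sliding_profile()` orders the paired
genes by RDE or by the weighted-rank key $v_i (S_i + R_i)/2$ (the
combined ordering is a documented reconstruction — its upstream
definition is not given) and slides a window of $w = \lceil 0.02n \rceil$
genes (step 1 by default; both rounding and step are unstated upstream
and exposed as arguments). Each window keeps its members' Jindex and RDE
values for violin/box rendering plus the $v$-weighted means `Saverage`
(set side) and `Laverage` (list side). For a recovered repressor the top
weighted-rank windows show Jindex mass high and RDE mass low.

## What the synthetic data emulates — and what it does not

`simulate_dataset()` builds the full study geometry with no external
downloads: Dirichlet-sampled motifs (concentration 0.5 ⇒ informative
columns; one focal + 24 decoys), 2,000 promoters of 550 bp with uniform
base composition, a planted focal occurrence in 15% of genes whose
per-gene strength (consensus-emission probability, uniform on
0.70–0.95) grades the site quality, and a DE table where each focal
target's latent score is
$z = \pm\,\text{effect}\times\text{standardized Jindex} + N(0, \sigma)$
with effect 1 and $\sigma = 1$, mapped monotonically to
$(\log_2 FC, FDR) = (z,\ 2\Phi(-|z|/\sigma))$. Those defaults are the
generator's definition of the study conditions and are not tuned per
experiment. What this emulates well: graded binding-site quality, decoy
motifs finding targets only by chance, a signal that lives in ranks
rather than raw values. What it does not emulate: real promoter base
composition and repeat structure, correlated gene regulation (all noise
is i.i.d.), motif databases' redundancy, or limma's mean–variance
behaviour — so passing recovery tests here demonstrates the statistics,
not performance on any particular genome.

## Numerical and degenerate-input choices

- Probabilities are smoothed with a background-proportional pseudocount
  (default 0.25); a zero-count column with zero pseudocount is an error.
- `N` bases contribute 0 to the Jindex (neutral), other non-ACGT
  characters are errors.
- Both promoter strands are scanned by default (strandedness upstream is
  unstated); the reverse strand is scored via the reverse-complemented
  score matrix in the same pass.
- Coordinates: GFF3 input is 1-based inclusive; offsets within promoters
  and BED-like hit output are 0-based (half-open intervals in the BED
  columns).
- All rank ties (set scores, RDE) break by gene identifier, making every
  pipeline output byte-reproducible for a fixed seed; the seed is
  recorded in the run metadata.
- Empirical permutation p-values use the add-one estimator
  $(1 + \#\{|\tau^*| \ge |\tau|\})/(B+1)$, never exactly zero.

## Problem sizes used in the checks

The packaged checks run the full default design (2,000 genes, 25 motifs)
for 50 + 50 seeded screens, 5,000 null replicates at $n = 500$ for
calibration, 20,000 permutations at $n = 200$ for the variance check, and
full enumeration up to $n = 7$ — sizes at which the Monte-Carlo error of
each check is far below its acceptance margin while the whole suite stays
in the minutes range on one core.

## Known limitations

- The asymptotic p-value leans on the $N(0,1)$ limit; for intersections
  of a few dozen genes or extremely skewed weights, prefer
  `permutation_p()` (the screen can attach it via `n_perm`).
- The mixed-density weighting is a documented reconstruction, not a
  transcription of the upstream tool's `-w 7`; results depending
  sensitively on the weighting mode should be reported with the mode, and
  compared across modes.
- Set scores ignore site multiplicity under the default `max`
  aggregation; factors acting through many weak sites are better served
  by `sum`.
- The screen treats factors independently; correlated motifs (paralogous
  families) will co-flag, and no motif clustering is attempted.
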