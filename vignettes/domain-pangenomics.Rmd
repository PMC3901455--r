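---
title: "Pangenomes from domain sequence families: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pangenomes from domain sequence families: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panarch)
```

## The clustering idea

A pangenome analysis starts from gene families. `panarch` defines them by
*domain sequence*: the ordered list of non-overlapping Pfam-A domains
along a protein, taken from an HMMER3 `hmmscan --domtblout` scan. All
proteins with an identical domain sequence form one family. Proteins
without any Pfam hit are discarded — which is a feature, since the union
of several gene finders is deliberately permissive and most false calls
carry no domain. Order and multiplicity matter: `PF00005` and
`PF00005,PF00005` are different families.

Upstream of the scan, predictions from several gene finders are merged by
their stop codon. A stop codon sits at the `Right` coordinate on the +
strand and at `Left` on the − strand, and when one stop has several
predicted starts the **longest** ORF is kept; over-extension is cheap
because the Pfam filter cleans up afterwards. Partial predictions (no
start and/or stop) are removed before merging; overlaps *between distinct
ORFs* are deliberately left alone. Translation uses the bacterial genetic
code (table 11). The code table is not dictated by the input formats, so
the package assumes table 11 with every alternative initiator
(TTG, CTG, ATT, ATC, ATA, ATG, GTG) rendered as M; a trailing stop is
trimmed, and an internal stop causes the prediction to be skipped with a
warning rather than an error — such calls are gene-finder noise that the
domain filter would have discarded anyway.

## Overlap elimination

Within one protein, overlapping domain hits are resolved recursively:
while any two retained hits share at least one alignment position
(nesting counts), the hit with the largest independent E-value among all
hits currently involved in an overlap is removed. The iEvalue is used
because it is also the filtering criterion; alignment (not envelope)
coordinates are used because envelopes are looser and would eliminate
more hits. Ties are broken deterministically — shorter alignment first,
then larger start, then lexicographically larger accession — so the
procedure is a pure function of the hit table. A literal brute-force
restatement of this rule serves as the test oracle on random hit sets.

Version suffixes (`PF07690.11` → `PF07690`) are stripped from family keys
by default so that scans against different Pfam releases co-cluster;
`keep_versions = TRUE` restores verbatim keys. Stripping is idempotent
and can never merge families that differ in unversioned accession order.

## The pan-matrix and diversity measures

The pan-matrix holds copy numbers of each family in each genome; every
derived quantity here uses only presence/absence. Manhattan distance
counts presence disagreements; the Jaccard distance and genome fluidity
are two closely related lack-of-overlap measures. Fluidity has no unique
textbook formula at the pair level, so the per-pair ratio of unique
families over total families, averaged over unordered pairs, is used —
for two equal-sized genomes sharing a fraction v of their families it
equals (1 − v)/1, while the Jaccard distance is 2(1 − v)/(2 − v); a 90%
overlap hence gives fluidity 0.10 and Jaccard 0.18.

PCA is computed on the column-centred presence matrix without scaling:
all columns are already on the 0/1 scale, and scaling would inflate rare
families. The pangenome tree applies average-linkage (UPGMA) clustering
to the Manhattan distances — the customary choice for pangenome trees —
with the linkage configurable.

The E-value cutoff sweep re-runs filtering, overlap resolution and family
construction from the raw hits at every cutoff. No incremental shortcut
is possible: removing one hit can *change* a protein's family identity
(a two-domain protein becomes a one-domain protein) rather than delete
it.

## The zero-truncated binomial mixture

With `x_j` the number of genomes containing family j, the spectrum
`y_g = #{j : x_j = g}` is modelled as a K-component binomial mixture
`f(x) = Σ_k π_k Binom(x; G, ρ_k)`, truncated at zero because families
absent from every sampled genome are invisible. The ρ's are selection
probabilities — a family with ρ = 0.1 appears in 1 of 10 genomes on
average.

The EM treats the unseen families as missing data: each iteration imputes
the expected zero-class count per component,
`z_k = S π_k (1−ρ_k)^G / (1 − p0)` with `p0 = Σ_k π_k (1−ρ_k)^G`, and the
M-step then uses ordinary binomial-mixture updates on observed plus
imputed mass. This keeps the observed (truncated) likelihood monotone,
which the implementation asserts at every iteration, and gives a simple
convergence test (|Δ logLik| < 1e-8, at most 1000 iterations).
Initialization spreads ρ at quantiles of `x/G`, jittered by the seeded
generator across restarts (default 10); π starts uniform. ρ = 1 is
permitted exactly — the core component — and `(1−ρ)^G` is evaluated
directly so no log-domain trick is needed. When K exceeds the number of
distinct observed frequencies, surplus components are allowed to collapse
(π → 0) with a warning.

Model size is selected by BIC = −2 logLik + (2K − 1) log S, with S (the
observed family count) as the sample size and ties resolved toward
smaller K. Downstream estimates: `N̂ = S/(1−p0)`, `ŷ0 = N̂ p0` (so
N̂ = S + ŷ0 by construction), population core `N̂ Σ π_k ρ_k^G`, and the
expected overlap between m genomes `Σ π_k ρ_k^m / Σ π_k ρ_k`, in which N
cancels. Uncertainty is quantified by bagging: genomes (rows) are
resampled with replacement, the spectrum rebuilt (families missing from
every sampled row drop out), the mixture refitted at fixed K, and the
empirical 5%/95% percentiles of N̂ reported — a percentile construction,
the simplest defensible choice. Note that resampled rows duplicate
genomes, so bagging replicates see slightly fewer families than the full
data; the interval describes resampling variability, not bias.

## Heaps law

Along an ordering of the genomes, `n_g` counts families first seen in the
g-th genome. The Heaps model `E(n_g) = β g^(−α)` is fitted on the points
of all permutations *pooled* (default 100 permutations), not on averaged
curves: pooling matches the permutation procedure and preserves the
dispersion that drives the fit's stability. g = 1 is excluded (the model
describes novelty relative to previous genomes); the permutation mean of
`n_1` is kept for extrapolation. The least-squares objective is minimized
by bounded quasi-Newton (`L-BFGS-B`) on (log β, log α), which enforces
positivity; the start is α = 1, β = mean(n₂).

α < 1 calls the pangenome open. Extrapolation sums `β g^(−α)` directly up
to 10⁶ genomes and switches to a midpoint integral for any tail beyond —
accurate to well under 0.1%. When α > 1 the series converges and the
closed population size is `n̄₁ + β(ζ(α) − 1)`; the zeta-series
construction is this package's choice, as is returning `Inf` (rather than
an error) for an open population. A pan-matrix of identical genomes makes
every `n_g` zero for g ≥ 2; the fit is then flagged degenerate with α
reported as NaN rather than pretending a decay exists.

## What the synthetic data does and does not emulate

`simulate_panmatrix` draws families independently from the planted
mixture — exactly the generative model the estimator assumes — with
defaults in the package's worked examples of N = 2000 families,
G = 100 genomes and a three-component mixture (π = 0.2/0.3/0.5,
ρ = 1.0/0.5/0.05): a core, a shell, and a cloud of rare families, the
qualitative structure seen in real spectra at a size that keeps every
analysis under a minute. `simulate_domain_fixtures` fabricates complete
on-disk inputs (genome FASTA assembled from back-translated proteins,
two finders' prediction tables, domtblout scans) with each pipeline
decision planted at least once: an alternative start sharing a stop
codon, a partial call, minus-strand ORFs, a domain-free protein, and an
overlapping decoy hit whose iEvalue (fixed at 1e-2) exceeds every real
hit's, so elimination must remove it. Hit iEvalues are drawn log-uniform
on [1e-60, 1e-2] so that cutoff sweeps have breakpoints.

Passing on these fixtures demonstrates the bookkeeping and the estimators
under their own assumptions. Real data violate those assumptions in ways
the generator does not emulate: genomes are phylogenetically correlated
(sub-sampled serotypes create bumps in the spectrum), families are not
independent, draft genomes truncate genes at contig edges, and real Pfam
hit structure is richer than planted 40-residue blocks. Mixture data are
also exchangeable draws from a *finite* pool, so Heaps fits on them tend
toward α ≥ 1 (closed) regardless of the mixture — openness is a
statement about the sampling process that this generator does not try to
mimic; Heaps recovery is therefore tested on curves generated from the
Heaps model itself (Poisson noise around `50 g^(−0.7)`).

## Numerical and interface choices

* Jaccard of two empty sets is 0 (continuity of the identity case).
* The merge key, sort order (`GenomeSequence`, then `Left`) and
  first-seen `Cluster n` labelling (genomes in input order, proteins in
  file order) are all deterministic, so reruns are byte-identical.
* BIC sample size is S, the number of observed families; parameter count
  2K − 1.
* All seeded functions restore the caller's RNG stream.
* Problem sizes in the shipped tests and the acceptance script —
  N = 2000, G = 100 for mixture recovery (20 seeds), 100 pooled
  permutations over 39 positions for Heaps recovery, 1000 random hit
  sets for the overlap oracle — were chosen as the smallest scales at
  which the estimators' sampling error is comfortably inside the claimed
  tolerances.

## Limitations

Domain sequence families are coarse: a family sharing only a promiscuous
single domain can span several orthologous groups, and proteins without
Pfam-A hits are invisible to the whole analysis. The mixture model
assumes exchangeable genomes and independent families; both fail for
structured collections, and the pangenome size estimate is best read as a
lower bound. The Heaps openness call is known to be very sensitive to the
ORFan count and hence to the E-value cutoff — the cutoff sweep exists
precisely to make that sensitivity visible.
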