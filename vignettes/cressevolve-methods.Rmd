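---
title: "Methods: similarity networks, Rep domain classification and codon usage selection pressure"
author: "cressevolve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity networks, Rep domain classification and codon usage selection pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cressevolve)
```

# Scope

CRESS-DNA viruses carry two core proteins: Rep, a rolling-circle
replication initiator combining an HUH endonuclease with a superfamily-3
helicase, and the structural capsid protein Cap. Their genetic diversity is
typically surveyed by (i) clustering proteins in an all-vs-all pairwise
similarity network, (ii) classifying Rep domain organization, (iii) asking
whether network clusters are concordant with phylogenetic trees and whether
Rep and Cap assignments of the same genomes are congruent (incongruence
being evidence of recombination), and (iv) decomposing codon usage bias
into mutational and selective contributions. `cressevolve` implements this
workflow as composable, seeded, fully offline-testable functions. This
vignette records the models, the tunable parameters, and the design
decisions made where the methodology leaves genuine freedom.

# Pairwise similarity networks

## Scores and statistics

Every unordered pair of protein sequences is scored with an exact
Smith–Waterman local alignment (`Biostrings::pairwiseAlignment`) under a
substitution matrix (default BLOSUM45) and affine gap penalties (default
open 15, extend 2). Raw scores are converted to BLAST-style HSP statistics

$$E = K \, m \, n \, e^{-\lambda S}, \qquad P = 1 - e^{-E},$$

with $m, n$ the raw sequence lengths — no edge-effect correction, which
only shifts E-values by a smooth factor absorbed by the network threshold.
Pairs whose best local alignment scores $\le 0$ return no hit.

## Calibration of $\lambda$ and $K$

The built-in parameter table carries the classical ungapped
Karlin–Altschul values and, for the gapped defaults, a deliberately
conservative calibration (BLOSUM45 15/2: $\lambda = 0.10$, $K = 0.05$).
The reasoning: seeded BLAST simply fails to report HSPs between unrelated
proteins, but exact Smith–Waterman assigns every pair a score, and for
~300-residue random sequences the empirical score distribution has a heavy
right tail (scores up to ~100 occur at rate $10^{-3}$ per pair). An
exactly calibrated per-pair E-value would, by construction, pass about 1%
of unrelated pairs at any $P \le 10^{-2}$ cutoff — in an all-vs-all
comparison of $N$ sequences that is $\mathcal{O}(N^2/200)$ spurious edges,
enough to bridge unrelated clusters under single-linkage components. The
conservative decay places the $P = 10^{-2}$ score cutoff above the random
score range while leaving genuinely related pairs (scores an order of
magnitude higher) maximally significant. Users comparing to external BLAST
runs can override $\lambda$/$K$ in `scoring_params()`, or feed precomputed
hit tables directly to `build_network()` — the network layer only consumes
(query, subject, E-value) triples.

## Network, layout, clusters

`build_network()` merges reciprocal hits keeping the smaller P-value
(whether a published all-vs-all analysis merges by min, mean or best HSP is
generally unstated; min is the most permissive symmetric choice and is
documented here), drops edges with $P$ above the threshold (default
$10^{-2}$), and keeps isolated nodes. The force-directed layout follows
the CLANS recipe: attraction $a = \min(1, -\log_{10}\max(P, 10^{-200})/200)$
acts as a linear spring along edges against an inverse-square-distance
repulsion between all node pairs, with a per-round step cap; coordinates
are a pure function of the seed. The layout is visualization only —
clustering never reads coordinates.

Two cluster extractors are provided. `components` (default) takes
connected components of the thresholded graph: parameter-free and
reproducible. `network_offset` reproduces the CLANS network-clustering
option: iterative reassignment of each node to the cluster maximizing its
average attraction to members, accepted only when that average exceeds
`offset` × the global mean attraction (default offset 1.0 — the published
description names the option but no numeric value), for at most 10,000
rounds, with lexicographic scan order and lowest-cluster-id tie-breaks for
determinism. Clusters smaller than `min_size` (default 10, the
minimum-cluster-size convention for these datasets) are routed to an
explicit unclustered pool.

# Rep domain organization

The published classification logic needs only presence/completeness calls
for two domains; `cressevolve` supplies them with configurable motif
regular expressions rather than a conserved-domain database search (no
database download, and the downstream mapping depends only on the calls).
Defaults: HUH motifs I (`[FYWLIV]T[LIVF]`), II (`H[ILVMFYWAC]H`),
III (`Y..[KR]`) restricted to the N-terminal half (the endonuclease is
canonically N-terminal), Walker A (`[GA]....GK[ST]`) and Walker B
(`[ILVMFACW]{3}[DE][DE]`) in the C-terminal half. Halves split at the
sequence midpoint.

Completeness is operationalized as: Viral_Rep **complete** when ≥ 2 of the
3 HUH motifs match (≥ 1 ⇒ incomplete), P-loop **complete** when Walker A
and B match with B starting within 120 residues after A ends (a lone motif
or a too-distant pair ⇒ incomplete). Both cutoffs are arguments. These
rules are stand-ins for partial domain-database hits and are flagged as
such in output metadata. A Viral_Rep→P-loop gap exceeding 150 residues
raises an `insert_suspected` flag (additional domains between the two are
reported as a gap flag only, not identified). The category map —
both → {CRESSV1–3, Circoviridae(-related), Nanoviridae};
Viral_Rep-only → {CRESSV4, CRESSV5}; P-loop-only → pCRESS-related;
neither → {Smacoviridae(-related), outgroups 1–4}; complete+incomplete →
{CRESSV2-related, Nanoviridae} — is data, not code. The
(incomplete, incomplete) cell of the status grid is not covered by the
published descriptions; it is assigned to `both_one_incomplete` as the
nearest category.

# Trees, concordance, recombination screen

Maximum-likelihood phylogenetics is out of scope here; the concordance
question asked of the trees is purely topological (do network clusters
form clades), so neighbor joining on alignment-identity distances is an
adequate and fast stand-in. Distances are
$d = 1 - \text{identities}/\text{aligned columns}$ from the same local
alignments the network uses; no-hit pairs saturate at 1. NJ (`ape::nj`)
runs on lexicographically ordered taxa with negative branch lengths
clamped to 0. A cluster is concordant when one tree edge bipartitions its
members from everything else; the summary fraction covers clusters of
size ≥ 2 (singletons are trivially concordant and excluded).

`rep_cap_crosstab()` is the recombination screen: given genome-id → Cap
cluster and genome-id → Rep group maps, it counts genomes over the shared
ids and flags Cap clusters whose members carry more than one distinct Rep
group. Pairing Rep and Cap annotations of the same genome is the caller's
responsibility (the operation takes explicit maps).

# Codon usage suite

Input CDS pass `validate_cds()`: length divisible by 3, a single terminal
stop trimmed (flagged), codons containing ambiguity codes excluded and
counted, internal stops an error under `strict` (curated CDS should be
clean) or excluded under `lenient`. Genes with > 10% excluded codons are
dropped from dataset aggregates with a warning (threshold configurable).
The genetic code defaults to NCBI table 1 and is configurable.

Per gene: base fractions; GC1/GC2/GC3 (percent G+C per codon position over
sense codons); GC12 = (GC1+GC2)/2; GC3s over synonymous third positions
only (amino acids with ≥ 2 codons — Met and Trp excluded; this is the
standard GC3 vs GC3s distinction); RSCU$_j = x_j/(N/k)$ within each
synonymous family (unobserved families NA, singletons excluded); and
Wright's ENc from family homozygosities
$F = (n\sum p_i^2 - 1)/(n-1)$:

$$\mathrm{ENc} = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3} +
\frac{5}{\bar F_4} + \frac{3}{\bar F_6},$$

with six-fold families kept whole (the 9/1/5/3 class structure of the
standard code), $\bar F_3$ imputed as $(\bar F_2 + \bar F_4)/2$ when Ile
is unobserved, families with $F \le 0$ or $n < 2$ treated as missing, the
result capped at 61, and NA when $\bar F_2$, $\bar F_4$ or $\bar F_6$ is
undefined (the $\bar F_6$ condition is our extension of the usual
$\bar F_2/\bar F_4$ rule; with realistic gene lengths the Leu/Ser/Arg
families are essentially always observed). Genes with NA ENc are excluded
from dataset means, with the exclusion count reported. Note the
finite-sample correction in $F$ decays like $1/n$, so ENc at typical
depths sits visibly above its infinite-depth proportion limit (uniform
usage at 100 counts/codon gives raw 61.41 against a limit of 61.03); the
tests assert monotone convergence rather than exact scale invariance.

Dataset level: the ENc–GC3s plot compares each gene to the mutation-only
expectation $\mathrm{ENc}(s) = 2 + s + 29/(s^2 + (1-s)^2)$; genes well
below the curve indicate selection beyond mutation pressure. The
neutrality regression fits GC12 on GC3 (percent scale, forced by the
published intercept conventions) by OLS with Pearson correlation and a
two-sided $t$-test p-value; $100 \cdot \text{slope}$ is reported as the
mutation-pressure share and $100 \cdot (1-\text{slope})$ as the selection
share. The PR2 plot takes A3/(A3+T3) against G3/(G3+C3); third-position
counts default to all sense codons (matching the common toolchain output)
with Sueoka's fourfold-degenerate-only site set behind `pr2_sites =
"fourfold"`. Aggregate RSCU >1/<1/<0.7/>1.5 counts are computed on codon
counts pooled across genes (the convention behind single 59-codon dataset
profiles); a per-gene-mean alternative can be had by averaging the
per-gene profiles directly.

# Synthetic data generators

The generators define the conditions every recovery test runs under; they
are pure functions of (parameters, seed).

* `gen_protein_families()`: independent uniform-random consensus per
  family, members derived by i.i.d. substitution at probability $q$ to a
  uniformly chosen different residue. Expected within-family identity
  $(1-q)^2 + q^2/19$. Defaults used in the recovery analyses — 5 families
  × 20 members, length 300, $q = 0.1$ (≈ 81% pairwise identity, typical of
  a well-defined Rep cluster) — give within-family alignment scores
  (≥ ~1400) an order of magnitude above the random-pair range.
* `gen_cds()`: per gene a mutational GC pressure $m \sim U(0.25, 0.75)$
  (the spread needed for a well-conditioned neutrality regression; real
  Rep/Cap datasets span roughly GC 30–60%). Codon positions 1–2 are G/C
  with probability $(1-w)m + wc$ (anchor $c = 0.5$), position 3 with
  probability $m$; G/C and A/T equiprobable; stop codons rejected and
  redrawn, keeping exactly $L$ codons per gene. The neutrality slope then
  has analytic expectation $1 - w$ before attenuation. Because GC3 enters
  the regression as a binomial realization of $m$ (sampling noise at
  $L = 300$), the fitted slope is attenuated by ≈ 0.96; the stop-codon
  rejection also nudges GC12 up by ~1–2% at $w = 1$ (stops are AT-rich).
  These are properties of the generative model, not estimator bugs, and
  the tests band them accordingly ($w = 0$: slope ∈ [0.90, 1.02];
  $w = 0.7$: [0.24, 0.33]; $w = 1$: |slope| ≤ 0.05 at $n = 200$ genes).
* `plant_motifs()`: a random backbone is repair-sampled until free of all
  default motif patterns (matched stretches are overwritten with
  glutamine, which no default pattern requires at a constrained position),
  then motif strings are copied in at stated positions — giving exact
  ground truth for scanner round trips.

What the generators do **not** emulate: phylogenetic correlation among
sequences, indels, codon-level fitness landscapes, amino-acid composition
bias, and database-scale length heterogeneity. Passing recovery tests
therefore demonstrates correctness of the statistics and the pipeline
plumbing under the stated model, not performance on real NCBI data.

# Problem sizes and determinism

The shipped analyses use desk-scale sizes chosen to exercise every code
path: ~5,000–6,000 exact pairwise alignments for cluster recovery
(109 sequences × 300 residues), 200 genes × 300 codons for the codon
suite, and a few hundred layout rounds in examples (the CLANS convention
of ≥ 100,000 rounds applies to visualizing thousand-sequence datasets;
the layout cost is linear in rounds and quadratic in nodes). Every
stochastic step takes an explicit integer seed, and `run_pipeline()` with
identical config and seeds produces byte-identical outputs.

# Known limitations

* E-value calibration targets specificity of the thresholded network, not
  agreement with NCBI BLAST E-values; absolute E-values differ from BLAST
  by a smooth factor.
* Motif-based domain calls are a proxy for conserved-domain searches;
  sequences with degenerate motifs will be under-called, and the
  completeness rules are operational stand-ins.
* NJ on local-alignment identities is a topological stand-in for ML
  phylogenetics; branch lengths are not interpretable as evolutionary
  distances.
* The codon suite's ENc variant (Wright's estimator with the documented
  imputation and capping rules) can differ by a few tenths from other
  implementations on the same data; the variant is stated in output
  metadata so published means can be compared knowingly.
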