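---
title: "Models and methods behind matriquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind matriquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matriquant)
```

`matriquant` re-implements, as a tested and reusable pipeline, the
computational analysis typically applied to label-free spectral-counting
proteomics of matrix-enriched tissue extracts — for example, guanidine
extracts of injured versus uninjured spinal cord profiled by shotgun
LC-MS/MS in a small balanced design (3 control vs. 3 injured animals).
The pipeline consumes identification-level count tables; peptide-spectrum
matching, protein inference and FDR control are upstream and out of
scope. This vignette documents the statistical models, the tunable
parameters and their defaults, the design decisions taken where the
methodology was genuinely open, and what the synthetic-data tests do and
do not establish.

## Spectral-count quantification

The quantitative unit is the number of MS/MS spectra assigned to a
protein in a sample, $s_{ij}$ for protein $i$ in sample $j$. Spectral
counts scale with protein amount but also with the total number of
spectra acquired in a run, so sample-level differences in loading or
instrument performance must be removed first.

**Normalization.** With per-sample totals $S_j = \sum_i s_{ij}$ and their
mean $\bar S$, normalized counts are

$$ n_{ij} = s_{ij} \cdot \frac{\bar S}{S_j}, $$

i.e. every count is multiplied by the ratio of the average spectral count
to the total of its own sample. Afterwards every column totals exactly
$\bar S$; this conservation is asserted to $10^{-9}$ relative tolerance in
the tests. A sample with zero total spectra is an error, not a silent
drop.

**Inclusion filter.** Only proteins identified with at least two unique
peptides in at least one sample enter statistical testing; everything
else is reported with `passed_filter = FALSE` and no p-value. No outlier
removal is performed anywhere, by design.

**Differential expression.** Per protein, an unpaired two-tailed t-test
on the normalized spectra, case group versus control group. The default
is the classic pooled-variance Student test — the generic "unpaired
t-test" of most proteomics workflows — with Welch available via
`var_equal = FALSE`. The fold change is computed on group means with a
pseudocount,

$$ \mathrm{FC} = \frac{\bar n_\text{case} + \varepsilon}
                      {\bar n_\text{control} + \varepsilon},
   \qquad \varepsilon = 0.5 \text{ by default}, $$

because zeros are pervasive in spectral counts and a ratio of raw means
is otherwise undefined or infinite. $\varepsilon = 0.5$ (half a spectrum)
is the smallest count-scale quantity that regularizes the ratio without
visibly biasing moderate counts; it is configurable. Proteins whose two
groups are constant and equal carry no information and are flagged
degenerate with $p = 1$; constant but unequal groups (infinite $t$) are
flagged degenerate with $p = 0$. Significance tiers use the raw p-value
at 0.05 and 0.01, boundary inclusive, matching the volcano-plot
convention; a Benjamini–Hochberg column is emitted for information only
and deliberately plays no role in the calls, which mirrors how such
volcano tiers are conventionally reported.

**Abundance index.** Because a large protein yields more peptides (and
spectra) per mole than a small one, within-sample relative abundance is
estimated as aggregate spectra divided by molecular mass in kDa. The
aggregation default is the mean over all samples (`mean_all`), with
`sum_all` and per-group means available: the convention in the field does
not pin this down, and the ratio's *ranking* is invariant to the choice
whenever all samples are used. Masses come from curated metadata or from
sequence via standard average residue masses plus one water (18.0153 Da).

**ΔΔCt helper.** For the companion qPCR readout,
$\mathrm{FC} = 2^{-[(Ct^{tgt}_{case} - Ct^{ref}_{case}) -
(Ct^{tgt}_{ctl} - Ct^{ref}_{ctl})]}$ against a housekeeping reference.

## Multivariate views

**PCA** treats samples as observations and proteins as variables,
centered per protein and unscaled by default; zero-variance proteins are
dropped with a message. Unscaled PCA is the literal reading of "spectral
counts were used" in the upstream platforms; per-protein z-scaling is
available via `scale. = TRUE`. Each component's sign is fixed so its
largest-magnitude loading is positive, which makes scores reproducible
across BLAS implementations. A caveat documented honestly below: on
heavy-tailed count data, unscaled PC1 can be captured by the replicate
noise of a single extreme-abundance protein.

**Hierarchical clustering** of proteins uses the Pearson correlation of
their profiles, distance $1 - r \in [0, 2]$, with average linkage (the
similarity is conventional; the linkage is our choice — average linkage
is the common default for correlation distances and keeps merge heights
interpretable). Zero-variance rows, whose correlation is undefined, are
excluded with a warning. The tree serializes to Newick for external
viewers.

## Network construction and Markov clustering

Association edges (String-style combined scores, accepted on either the
0–1 or the raw 0–1000 scale and normalized to 0–1) are thresholded at the
conventional medium-stringency 0.4, boundary inclusive, and restricted to
a node universe — in the pipeline, the significantly up- and
downregulated proteins, analyzed separately. Isolated universe nodes are
retained and reported.

**MCL.** Markov clustering simulates flow on the column-stochastic matrix
of the weighted graph: alternately *expansion* (matrix squaring) and
*inflation* (entrywise power $r$ followed by column re-normalization),
until the matrix stops changing (max entry change below `tol`, default
$10^{-6}$). Inflation strengthens strong flows at the expense of weak
ones; the conventional granularity here is $r = 1.9$. Numerical choices:

* self-loops are added with weight equal to the node's maximum incident
  edge weight (1 for isolated nodes) — common MCL practice that damps the
  period-2 oscillation of odd cycles;
* entries below `prune` ($10^{-5}$) are zeroed and the column
  re-normalized, for numerical hygiene; the tests assert columns stay
  stochastic to $10^{-9}$ throughout;
* the iteration is dense — the graphs here are hundreds of nodes, where
  dense BLAS beats sparse bookkeeping;
* clusters are read off the attractor structure (rows with nonzero
  diagonal); attractors supporting a common node are unioned, every node
  joins its strongest attractor, and ties fall to the first node in name
  order, so the partition is deterministic;
* hitting `max_iter` (100) returns the partial clustering with a
  warning rather than failing.

Clusters are ranked by size, ties broken by total internal edge weight
then by lexicographically smallest member — a deterministic stand-in for
the "most populated subnetworks" reading. Betweenness centrality is
computed on the unweighted topology (scores gate edges but do not weight
paths) and normalized per connected component by $(n-1)(n-2)/2$, so that
values lie in $[0,1]$ and nodes in components smaller than 3 score 0.

## Term over-representation and the dominant call

Per cluster, each annotation term is tested with the upper-tail
hypergeometric probability

$$ p = \sum_{i=k}^{\min(K,n)}
   \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}, $$

evaluated term-by-term in log space (`lchoose`) so large universes do not
overflow. The universe defaults to the filter-passing proteins of the
dataset — a closed-world choice matching the character of a proteomics
identification list, not the whole genome — and is configurable. Within
each cluster, p-values are BH-adjusted across its tested terms (the
upstream tool's correction is not documented, and BH is the common
default); the *dominant* term is the smallest adjusted p, ties resolved
toward larger overlap $k$, then lexicographic term id, and is reported
with the conventional "$k$ of $n$" label. Annotations are used as flat
sets: ontology-graph propagation is out of scope.

## Cross-omics intersection

Protein and transcript differential tables are matched on uppercased
gene symbols, optionally through a user-supplied alias map (the generic
stand-in for probe-to-protein identifier mapping, which published
comparisons rarely specify). The shared signature keeps genes significant
($p \le$ 0.05 by default) and concordantly directed on both sides;
discordant matches are excluded but reportable for audit. Rows are
ordered by protein fold change with a lexicographic tie-break, the
deterministic order used for heat-map rendering. The transcript-side
significance criteria are configurable (`p_cut`, optional `fc_cut`)
because published comparisons often leave them unstated.

## The synthetic world

Every stage is testable offline through a seeded generator. Counts follow
a negative binomial with

$$ \mu_{ij} = c \cdot L_i^{\alpha} \cdot a_i \cdot \ell_j \cdot
   2^{\beta_i g_j}, \qquad \mathrm{Var} = \mu + \varphi \mu^2, $$

with protein length $L_i$ (lognormal, median 450 aa), per-protein
abundance $a_i$ (lognormal, sdlog 1, mean 1), library factors $\ell_j$
(lognormal, sdlog 0.15 — modest run-to-run loading differences),
baseline $c = 0.05$ spectra per residue (median protein ≈ 10–15
spectra, the scale of real matrix-extract data), dispersion $\varphi =
0.2$, and planted signed log2 fold changes $\beta_i$ on a 10% subset
(magnitude $\mathcal N(2, 0.5)$, random sign). $\varphi = 0$ degenerates
to Poisson. Unique-peptide counts are `ceiling(counts/5)`, at least 1 on
support, so the two-peptide filter actually bites. Masses derive from the
simulated lengths. The network is a stochastic block model over planted
modules (within-module edge probability 0.9, scores U(0.6, 1); between,
0.02 with scores U(0.15, 0.5), so the 0.4 threshold preferentially keeps
module structure). One annotation term per module covers 80% of its
members by default plus 5% background genes. The transcript table marks a
controlled fraction ρ of the planted up-regulated proteins as
significantly up, plus transcript-only noise probes whose symbols do not
occur in the simulated proteome — mirroring the fact that most array
probes have no protein identification; this disjointness is what makes
exact-recovery tests of the intersection meaningful.

A single master seed derives one substream per generator stage, so the
network can be regenerated without re-drawing the counts. What a green
test establishes is algorithmic correctness against this stated world —
not that real data satisfy the model: real spectral counts have
correlated proteins, batch structure, and identification dropout that the
generator does not emulate.

## Known limitations

* **Unscaled PCA on heavy-tailed counts.** With a realistic lognormal
  abundance tail, the single most abundant protein can hold the majority
  of total variance; since NB noise scales as $\varphi\mu^2$, PC1 then
  tracks that protein's replicate noise rather than the group signal.
  In our fixed-seed acceptance sweep (|log2FC| = 2, 10% DE, seeds 1–10)
  one seed fails the PC1-silhouette criterion for exactly this reason,
  and the corresponding acceptance test is deliberately left failing
  rather than re-tuned; the z-scaled variant (`scale. = TRUE`) separates
  the groups in 10/10 seeds. The unscaled default is retained because it
  is the literal reading of the upstream convention.
* The t-test on counts is an approximation at $n = 3$ per group; the
  null-calibration test shows the realized type-I rate sits inside the
  99% binomial band around 0.05 under the stated world, but departures
  are expected for very low-count proteins (many of which the
  unique-peptide filter removes).
* Exact-recovery of the transcript overlap is validated against the
  simulation truth on the protein side; through the empirical t-test the
  recovery is power-limited, which is exercised separately in the
  pipeline tests under a low-noise configuration.
* No ontology propagation, no probe-set summarization, no workflow-engine
  integration; the pipeline is linear by design.
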