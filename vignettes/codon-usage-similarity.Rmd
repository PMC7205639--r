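---
title: "Comparing viral and host codon usage at the single-gene level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing viral and host codon usage at the single-gene level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Most RNA viruses use synonymous codons very differently from the average
usage of the genomes they infect, yet their proteins are translated
efficiently during infection. Genome-averaged comparisons hide the fact
that host genes themselves are heterogeneous: a genome contains genes
whose codon usage is close to "optimal" (GC3-rich, matching abundant
tRNAs) and genes whose usage is strongly non-optimal. `codonscape`
implements a single-gene-resolution comparison: it places every host gene
and every virus species in a common low-dimensional codon-usage map,
finds the host genes closest to each virus subgroup, and asks what those
genes have in common functionally.

## The statistics

**RSCU.** For codon $i$ in a synonymous family of $n$ codons
($1 \le n \le 6$) with observed counts $X$,

$$\mathrm{RSCU}_i = \frac{X_i}{\tfrac1n \sum_{j=1}^{n} X_j},$$

the observed count relative to the count expected under equal use.
A value of 1 means no bias; values above 1 mark abundant codons. The
three stop codons and the single-codon families Met (ATG) and Trp (TGG)
are excluded, giving a 59-dimensional profile per gene. Families absent
from a gene get zero entries and are flagged via `present_aa` rather than
an undefined $0/0$; every present family's values sum to its size $n$ by
construction, so the 59 columns carry at most $59 - 18$ free dimensions —
a rank deficiency that the ordination has to live with (below).

**CAI.** The codon adaptation index is the geometric mean, over all
occurrences of the 59 scoreable codons, of relative adaptiveness
$w_i = f_i / \max_{j \in \text{family}} f_j$ computed from a reference
usage table. It is evaluated in log space; a codon with zero reference
frequency is an error unless a pseudo-frequency is configured.

**GC3.** The percentage of non-stop codons whose third base is G or C.
ATG and TGG are included (the standard convention); stops are excluded as
they lie outside the 59-codon universe.

**CCCS.** The cell-cycle codon score of gene $g$ is
$\sum_{\text{codons of } g} \mathrm{CP}(c) / \mathrm{length}(g)$: the
length-normalised sum of per-codon preference values derived from a
designated gene set (for the biological application, cell-cycle-regulated
genes). Positive scores mean codon usage resembling that set. "Length" is
taken as the number of sense codons, so CP values read as per-codon
contributions; a `length_unit = "nt"` switch divides by nucleotide length
instead for cross-checks against conventions that normalise by cDNA
length.

## Ingest rules

Hosts are represented by one *major transcript variant* per gene: the
longest variant whose ORF is complete. Completeness is a single verdict
per sequence, checked in a fixed order (ambiguous base, bad length, no
ATG start, internal stop, no terminal stop) so each failure gets exactly
one diagnostic. Equal-length complete variants tie-break on the
lexicographically smallest record id, so the selection is deterministic
under any input order. U is mapped to T on input so
RNA-virus FASTA dialects are accepted, and the host gene-id position in
the FASTA header is configurable (header dialects vary between annotation
releases). Virus species are defined by a catalog file assigning each
species to a genome-polarity group and a subgroup and listing its CDS
records; a species RSCU is the unweighted mean of its per-CDS RSCU
vectors (a codon-count-weighted mean is available behind a flag).

## Ordination

The joint host + virus RSCU matrix (rows: host genes then virus species,
both blocks sorted by id; columns: the 59 codons in fixed TTT..GGG order)
is mean-centred and its **covariance** matrix eigendecomposed — the RSCU
columns already share a scale, so correlation-matrix PCA would discard
meaningful variance differences. Components with eigenvalue above 1 are
retained with a floor of two, so a 2-D map always exists. Retained
loadings (eigenvectors scaled by the square roots of their eigenvalues)
are **quartimax**-rotated: the orthogonal rotation maximising
$\sum a^4$, driving each codon's loading onto one component. Kaiser row
normalisation is on by default, matching the default of the classic
commercial factor-analysis software; both the normalisation and the
rotation are implemented by iterated closed-form pairwise planar
rotations and are checked in the tests against a brute-force grid search
over rotation angles.

Numerical points worth stating explicitly:

* The family-sum constraint makes the covariance matrix singular.
  Eigenvalues below `1e-10` are treated as exactly zero, degenerate
  retained components get zero loadings and zero scores rather than
  dividing by zero, and the KMO sampling-adequacy measure uses a
  Moore–Penrose pseudo-inverse for its partial correlations, so
  duplicated or linearly dependent columns cannot crash it.
* Component scores are **standardised** (unit variance over the fitted
  rows), the factor-score convention of the same software lineage.
  Projection of new vectors is `(x - column_means) %*% scores_coef`, and
  for fitted rows this reproduces the stored scores exactly. The pattern
  loadings are kept separately, so communalities are preserved by
  rotation (a tested invariant).
* Eigenvector signs are arbitrary, so maps would flip between runs. The
  package orients component 1 so that the loading-weighted third-base
  G/C direction is negative (GC3 falls as the first coordinate grows)
  and component 2 the opposite way; non-codon matrices fall back to
  making each component's largest absolute loading positive.
* KMO is reported with the fit; values at or above 0.5 are conventionally
  adequate. Zero-variance columns are dropped with a warning first.

Whether virus rows participate in the fit or are only projected post hoc
is configurable (`fit_universe = "all"` or `"host_only"`); the default
includes them, since the map is meant to be of hosts *and* viruses
jointly. Points on a quadrant boundary are counted by the closed rule
$x \ge 0 \rightarrow$ right, $y \ge 0 \rightarrow$ upper.

## Neighbourhoods

Each virus subgroup is summarised by the arithmetic mean of its members'
component coordinates (its centroid, the "mean vRSCU"). Host genes whose
Euclidean distance to a centroid is at most $r$ are selected; the disk is
closed (boundary included), which differs from the open disk only on a
measure-zero set. The pipeline default is the fixed $r = 0.3$ component
units. The informal rule behind that number — minimal, below the standard
deviation of gene distances, covering most subgroup members — is
under-specified ("most" could mean anything), so `auto_radius()`
formalises it as
$\min(\mathrm{sd}(\text{gene distances}),\; r_{\text{cover}})$ with an
explicit member-coverage fraction (default 0.5) and is provided for
sensitivity checks rather than as the default.

## Enrichment

Term overrepresentation in a selected gene set uses the hypergeometric
upper tail
$P(X \ge k) = \sum_{i=k}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}$
per term, over a flat gene-to-term map (no ontology DAG propagation —
structured ontologies are out of scope) with the whole analysed gene set
as background. Correction is Bonferroni by default — the conservative
choice of the classic enrichment tools — with Benjamini–Hochberg behind a
flag; significance is called on the corrected value at
$p_{\text{adj}} \le 0.01$, and both raw and corrected values are
reported, since thresholds quoted without naming a correction are
ambiguous. Terms absent from the background are skipped, not errors.

## The synthetic generator

Everything the pipeline consumes can be generated under a single seed, so
the whole analysis is testable without downloads. A `codon_profile` puts
third-base mass `gc3_target` on G/C-ending codons within every family,
split between purine (G/A) and pyrimidine (C/T) ends by
`purine3_target` — so a gene's expected GC3 tracks the target directly
(exactly, for 2-, 4- and 6-fold families; the 3-codon Ile family deviates
mildly through renormalisation), while the purine axis varies codon
preference at fixed GC3.

The default study conditions are 2,000 host genes in three populations:

* `optimal` (250 genes): tight cluster at GC3 0.85 — the reference-like,
  translationally optimal end;
* `gradient` (1,250 genes): each gene draws its own GC3 target uniformly
  from 0.32–0.92 and its purine preference from 0.25–0.75, a continuous
  cloud emulating the broad codon-usage heterogeneity of a real genome;
* `viral_like` (500 genes): tight cluster at GC3 0.30, the AT3-rich
  non-optimal end.

Ten virus species in three subgroups draw Dirichlet-jittered copies
(concentration 300 — small per-species jitter) of profiles at GC3
0.28–0.32 next to the viral-like cluster, each emitting several CDS.
Gene lengths are log-normal with median 400 codons (about the human CDS
median; the exact distribution is immaterial to the assertions), amino
acids come from one fixed realistic composition for every profile so that
codon-level — not protein-level — signal drives the ordination, the CP
table is $\log_2$ of the viral-like over the optimal within-family
probabilities clipped to $\pm 3$, the reference usage table is the codon
frequency implied by the optimal profile, and the annotation map plants
one term on viral-like genes at ten times the 5% baseline probability
plus uniform decoy terms.

Two geometric choices deserve their rationale. First, the bulk of the
host set is a *continuous* cloud rather than a few discrete clusters:
with equal-weight clusters at grid corners, the quartimax criterion is
maximised by a frame through the cluster diagonals rather than along the
GC3 gradient, which no real genome shows; a continuous gradient removes
those corners. Second, the two planted structure axes are deliberately
unequal (first and second structural eigenvalues roughly 12 and 2.4):
the GC3 axis must dominate for the rotated first component to be a clean
GC3 axis, while the secondary axis still carries enough variance that a
gene's position on the second coordinate is structure, not sampling
noise, keeping tight clusters tight in both map coordinates. Under these
conditions the pipeline recovers the planted chain — first component
anticorrelated with GC3 and CAI, viral-like genes selected at the default
radius with high sensitivity and specificity, the planted term
significant in every subgroup, CCCS positive for viral-like and negative
for optimal genes — and the acceptance script recomputes exactly these
quantities.

What the generator does **not** emulate: mutation pressure, dinucleotide
biases (e.g. CpG avoidance), amino-acid composition differences between
genes, isochore structure, tRNA pools, or untranslated regions. Passing
the recovery checks therefore shows that the statistical machinery works
under a known planted structure of realistic magnitude — not that real
host-virus codon similarity has any particular effect size.

## Worked analysis and reproduction

The `analysis/` directory runs the study as five numbered scripts
(simulate → metrics → ordination → neighbourhoods → enrichment), writing
their tables under `results/`; `run_pipeline()` performs the same chain
in one call and adds a JSON run manifest (configuration, a stable digest
of it, row counts, output list). The pipeline draws no random numbers,
so identical configuration and inputs give byte-identical outputs. The
published per-species component coordinates of 77 human RNA viruses in
11 multi-member subgroups ship in `inst/extdata/` as the deterministic
worked example for the centroid computation.

Problem sizes in the test suite are the package's own choices: the
acceptance checks run the full 2,000-gene, 10-virus study once (a few
seconds), unit tests use 100-instance oracle sweeps and small fixtures.

## Known limitations

* Flat annotation maps only; no GO DAG, evidence codes, or semantic
  de-duplication of terms.
* Euclidean disks only; no Mahalanobis or density-based neighbourhoods.
* No ENC, tAI, or dinucleotide statistics.
* The quartimax implementation rotates pairs to convergence of the
  criterion; for loading matrices with near-ties the attained frame can
  depend on column order (the criterion value itself is tested against a
  grid search).
* `auto_radius()` formalises an informal rule; its coverage default of
  0.5 is a judgement call, which is why the fixed 0.3 remains the
  pipeline default.
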