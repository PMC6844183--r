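---
title: "hicekit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hicekit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicekit)
```

`hicekit` takes coordinate-level Hi-C evidence — aligned paired-end reads —
through contact-matrix construction and the standard downstream analyses:
matrix balancing, A/B compartments, TAD calling, integration of other omic
tracks on the same bin grid, and gene-annotated interaction networks. This
vignette explains the models behind each stage, the parameters that matter,
and the design choices made where more than one reasonable convention
exists.

## Restriction digest and fragment index

Hi-C libraries are built by ligating restriction fragments, so artifacts
are diagnosed at fragment level. `digest_genome()` scans each chromosome
for the enzyme recognition site and places a cut at

    cut = p + (len(site) - overhang) / 2

for a match starting at 0-based position `p`. Sticky-end enzymes leave an
`overhang`-bp single-stranded end that, after fill-in, belongs to both
neighbouring fragments: fragment *k* ends at `cut + overhang` while
fragment *k + 1* starts at `cut`, so consecutive fragments overlap by
exactly the overhang (HindIII: site `AAGCTT`, overhang 4). All
coordinates are 0-based half-open throughout the package; BED output keeps
that convention and GTF input (1-based inclusive) is converted on read.

A read whose 5' base falls inside an overlap zone is ambiguous between two
fragments. We resolve the tie by read direction: a plus-strand read extends
rightwards into the downstream fragment, a minus-strand read leftwards into
the upstream one. This is the only assignment under which a read never
points out of its own fragment.

## Pair classification and filtering

For each intra-chromosomal pair the mates are ordered by position; the pair
is *inward* when the leftmost mate is on + and the rightmost on −,
*outward* in the converse case. Pairs whose mates fall on **different**
fragments are valid ligation products. Pairs on the **same** fragment are
artifacts: outward orientation indicates a circularized self-circle
fragment, inward an un-ligated dangling end; same-strand same-fragment
pairs fit neither signature and are accounted in their own category.

`estimate_fragment_length()` reconstructs the sequenced fragment: each
mate's distance from its 5' base to the cut position it reads toward, summed
over the two mates. Over-long estimates betray aberrant ligation products
and are removed by `max_frag_length`.

`filter_pairs()` applies removals in a fixed priority — duplicates (only
pre-marked flags are honored; the package never calls duplicates itself),
low mapping quality (default MAPQ < 10), same-fragment artifacts, the
orientation-distance thresholds `min_inward` / `min_outward`, then
`max_frag_length` — so that each pair lands in exactly one category and the
`FilterSummary` counts always sum to the input size. The distance
thresholds exist to catch artifact pairs that leak across a cut site (they
are then indistinguishable from short-range valid pairs except by their
insert length); because inward orientation is the dangling-end signature
and outward the self-circle one, those removals are counted with the
corresponding artifact class.

The two diagnostic distributions mirror standard practice: insert lengths
of intra-chromosomal pairs histogrammed on log2-spaced bins, overall and
split by orientation class. An artifact population shows up as a spike in
one orientation curve — classically near 2^8 = 256 bp for a standard
library — and the threshold that removes it can be read directly off the
log2 axis.

## Binning and the raw contact matrix

`make_bins()` tiles each chromosome at resolution `w_b`, snapping nominal
breakpoints (multiples of `w_b`) to the nearest restriction cut position,
because contact end points live on fragments. There is no default
resolution: it is an explicit analysis choice balancing statistical power
against detail. Snapped bins are stored disjoint — fragment-level overlap
bookkeeping is dropped at bin level so that every contact has exactly one
cell — and the final bin absorbs a trailing remainder shorter than
`w_b / 2`.

`count_contacts()` assigns each mate to the bin containing its 5' base. A
pair between bins *i ≠ j* increments `M[i, j]` and `M[j, i]`; a within-bin
pair increments the diagonal once. Under this convention the total stored
contacts (upper triangle plus diagonal) equal the retained pair count — an
invariant the tests check on every randomized run. Inter-chromosomal pairs
enter the global matrix; per-chromosome analyses slice diagonal blocks.
No bin-level outlier filtering is applied; the hook for it is the
matrix itself, which callers can mask before normalization.

## Normalization

### Iterative correction (ICE)

ICE assumes the observed contact factorizes as
`M[i,j] = b_i * b_j * Mhat[i,j]` with one visibility bias per bin.
`ice_normalize()` alternates dividing rows and columns by their relative
marginals until the coefficient of variation of the unmasked row sums drops
below `tolerance` (default 1e-8, capped at 200 iterations; both are
numerical choices, not model parameters). The output is rescaled to
preserve the mean unmasked row sum of the input, which fixes the otherwise
arbitrary scale of "relative contact probabilities", and the reported
biases satisfy the factorization identity to machine precision.

Two pre-treatments mitigate pathologies. `winsor_high` caps the top
fraction of upper-triangle entries at the corresponding quantile, damping
high-abundance bin pairs that would otherwise dominate the balancing
(0.02 is a practical default). `ignore_low` masks the lowest-coverage
fraction of bins; bins with *no* coverage are always masked, because an
all-zero row can never reach the common row sum. Masked bins yield NA
rows/columns; `na_policy = "set_min"` replaces every NA by the minimum
finite entry, which keeps downstream consumers that cannot handle NA
working at the cost of a small bias floor.

### Variance-stabilized wavelet denoising

`wavsis_normalize()` treats one chromosome's raw counts as Poisson
observations of a smooth intensity. Each row is variance-stabilized by the
Haar–Fisz transform (each Haar detail divided by the square root of its
smooth coefficient — the local intensity, which for Poisson data is also
the local variance), denoised by soft thresholding of an orthonormal Haar
decomposition at the universal threshold `sigma * sqrt(2 log n)` (noise
scale from the MAD of the finest details), inverse-transformed, and the
matrix re-symmetrized as `(X + t(X)) / 2` with negatives clamped at zero.
Rows are padded with zeros to the next power of two and cropped after
inversion. The transforms are implemented in the package (the Haar pyramid
is a dozen lines) and validated by exact round-trip tests; the procedure as
a whole is validated by its defining property — on planted piecewise-
constant intensities with Poisson noise it strictly reduces mean squared
error against the truth — rather than by equivalence to any particular
wavelet toolkit. It is a row-wise approximation of chromosome-level
wavelet denoising; `remove_uncovered` flags all-zero bins NA instead of
denoising them into pseudo-signal.

## Compartments

`compartment_pca()` extracts the leading eigenvectors of a per-chromosome
normalized block. The default `oe_correlation` mode divides each diagonal
by its mean (observed over expected at that genomic distance) before taking
the Pearson correlation matrix and its eigenvectors — this removes the
distance decay that otherwise dominates the first component; `direct` mode
performs plain PCA of the column-centered block. Eigenvector signs are
intrinsically arbitrary, so each vector is unit-normalized and flipped, if
needed, to correlate positively with per-bin coverage (active/A
compartments tend to be better covered). Whether PC1 or PC2 carries the
compartment signal depends on region size and resolution, so the component
choice is left to the caller (`compartment_labels(pca, component = )`).
Degenerate blocks (constant matrices) return all-NA tracks rather than
noise eigenvectors.

## TAD callers

Three callers with different strengths are provided; all operate
per-chromosome and return a `Segmentation` whose domains tile the block.

**Directionality index.** For each bin, `a` and `b` sum its contacts with
the `window` bins up- and downstream and

    d_i = sign(b - a) * ((a - e)^2 / e + (b - e)^2 / e),   e = (a + b) / 2.

Bins inside a domain away from its edges see balanced neighbourhoods
(d ≈ 0); bins near a boundary see strongly one-sided contacts, so sharp
sign changes demarcate domains. The 0/0 cases (a = b, including a = b = 0)
are defined as 0. The default window is the conventional 2 Mb converted to
bins (`di_window_bins()`); the index is computed on whichever matrix it is
given (raw counts by convention, since a and b are read counts).

**Window-signal caller (TopDom-style).** The boundary signal at bin *i* is
the mean contact frequency between the `window_size` bins ending at *i* and
the `window_size` bins starting at *i + 1* — a diamond across the gap.
Candidate boundaries are strict local minima (the leftmost bin of a minimal
plateau, a tie-break that keeps candidates deterministic), and each
candidate is retained only if a one-sided Wilcoxon rank-sum test — pooling
the within-side upper-triangle values against the cross-gap rectangle —
confirms at `p_threshold` (default 0.05) that within-domain contacts
exceed cross-boundary ones. We use the normal approximation with
continuity correction, which is well-behaved at these pooled sample sizes
and keeps the caller fast. `window_size` is the caller's only tuning
parameter.

**Likelihood segmentation (HiCseg-style).** Change points
`0 = t_0 < ... < t_K = n` are fitted so each diagonal block has its own
distribution parameter while all remaining cells share one background
parameter (`block_diagonal`), optionally giving the off-diagonal rectangle
between consecutive segments its own parameter too (`extended`). Gaussian
likelihood is appropriate for normalized matrices (the block is
standardized internally, which also makes boundary calls scale-invariant);
Poisson or negative-binomial for raw counts. The background parameter is
estimated once from the whole matrix rather than re-profiled per candidate
segmentation: profiling it would couple all segments and break the
additivity that lets dynamic programming find the *exact* optimum — a
property the tests verify against exhaustive enumeration at small n. Block
costs reduce to prefix sums for Gaussian and Poisson; the negative-binomial
dispersion needs the raw cells (with a Poisson fallback where it is not
identifiable, i.e. variance ≤ mean), so that model is intended for modest
matrix sizes. When `K` is not forced, the returned segmentation maximizes
a BIC-penalized likelihood, `loglik(K) - 0.5 * p_K * log(n^2)`, preferring
fewer segments on ties. A median-gain elbow rule was considered and
rejected: on homogeneous matrices roughly half of the (small, positive)
overfitting gains exceed their median, so an elbow at the median
systematically over-segments structureless data, whereas the BIC penalty
selects a single segment there and agrees with the elbow wherever the
likelihood curve has a real knee.

## Track integration

`bin_coverage()` counts primary aligned reads (5' base) of any SAM/BAM
into the Hi-C bins, reporting assigned/dropped totals so that count
conservation is checkable. `normalize_coverage()` offers RPM
(`count * 1e6 / total mapped reads` — the denominator is the whole file,
not just reads landing in the bin table) and ChIP/input ratio, with
zero-input bins set to NA rather than infinity. `bed_to_bin_track()`
converts interval tracks to per-bin occupancy, binary (any ≥1 bp overlap)
or maximum score. Multi-mapped, secondary and supplementary alignments are
excluded by flag.

## Interaction networks and enrichment

`map_genes_to_bins()` overlaps gene bodies (gene-level GTF features when
present, else the span of each gene's records) with bins, strand-blind; a
bin can carry several genes and a wide gene several bins.
`build_interaction_table()` seeds from the bins overlapping a region of
interest, pairs them with every bin (`global_scope`) or only the region
bins, and keeps pairs with normalized strength at least `norm_value`;
`intra_only` additionally drops inter-chromosomal pairs and pairs closer
than `min_bin_distance` bins, since near-diagonal contacts are trivially
strong. Both filters are monotone — raising either never adds a row.
`build_network()` renders the table as an undirected weighted graph
(vertices = bins with coordinates and gene lists, edge weight = strength)
exportable as JSON node/edge lists.

Functional enrichment is computed locally over user-supplied GMT
collections: for each set, the hypergeometric upper tail
`P(X >= k)` with k the query/set overlap, the annotation's bin-overlapping
genes as the default universe, and Benjamini–Hochberg adjustment across
sets. A local test keeps results reproducible — no remote database
version can shift the numbers between runs.

## Synthetic data: what it emulates, and what it does not

The generators exist so that every stage is testable against known truth
at toy scale (kilobase genomes, thousands of pairs, hundreds of bins —
the full suite runs in well under a minute):

* `simulate_genome()` plants the recognition site at approximately
  exponential spacing in screened random sequence, so digesting recovers
  exactly the planted cut list.
* `simulate_pairs()` draws valid products between distinct fragments and
  artifacts inside single fragments with the defining orientation, insert
  lengths log-normal around 256 bp — the canonical spike the orientation
  diagnostics are designed to expose — plus exact duplicate copies with
  the duplicate flag set. Truth labels ride along, and the SAM writer
  round-trips through the package's own reader.
* `simulate_contact_matrix()` builds
  `mu = base * (1 + |i - j|)^(-decay) * tad_factor * comp_factor` with
  planted domain boundaries and ±1 compartment labels, observed as
  Poisson counts or noiselessly.

These fixtures have sharp boundaries, uniform within-domain intensity,
no mappability structure, no translocations, no copy-number variation and
no restriction-site density bias. Passing tests therefore demonstrate
algorithmic correctness — conservation laws, exact optima, recovery of
planted structure under Poisson noise — not performance on the messier
signal of real libraries, where parameter choices (resolution, windows,
thresholds) matter far more.

## Pipeline, reproducibility, and problem sizes

`run_pipeline()` executes digest → filter → bin → normalize →
(compartments, TADs, coverage, BED tracks, network) from a YAML config into
`project/<sample>/<bin_size>/Results/<stage>/` with logs under `SysOut/`
and a JSON manifest recording each stage's parameters and output
checksums; unchanged stages are skipped on re-run unless forced, and a
fresh run with the same config and seed is byte-identical. The bundled
`hicekit` script (under `inst/scripts/`) exposes each stage as a
subcommand for shell use.

The verification suite works at deliberately small sizes — 20×20 balancing
oracles, n ≤ 12 exhaustive segmentation enumeration, 200-bin planted-TAD
matrices, 40-bin compartment replicates, 10,000-pair filtering runs, and a
two-chromosome (~200 bins each) end-to-end project — chosen so that exact
brute-force references are computable and the planted structure is
unambiguous.

## Known limitations

* The wavelet normalizer is row-wise, not a true 2-D transform, and its
  universal threshold can over-smooth weak, small-scale structure.
* The negative-binomial segmentation cost is O(block) per evaluation;
  use Poisson or Gaussian for large matrices.
* ICE assumes a single multiplicative bias per bin; copy-number structure
  violates this and is not modeled.
* Duplicate detection is delegated to upstream tools; only pre-set flags
  are honored.
* Coverage uses read 5' counts, not fragment-extension models.
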