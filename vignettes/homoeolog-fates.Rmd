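---
title: "Models and methods behind polyfate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polyfate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical models, the numerical choices, and the
design decisions behind `polyfate`, in the spirit of a methods supplement:
what is assumed, what is tunable, and what passing the test suite does and
does not demonstrate.

# The study design the package targets

The package analyses allopolyploids with (i) two extant diploid progenitor
species whose transcriptomes can be assembled independently, (ii) several
*independently formed* polyploid lineages, each with biological replicates,
and (iii) paired RNA-seq and target-capture DNA data for the polyploids. The
built-in synthetic design mirrors a realistic field sampling: five diploid
individuals of parent A and three of parent B, and four polyploid lineages
with three replicates each — twenty RNA samples in total. That sample count
matters downstream: the low-expression filter's default "at least 11
samples" rule is calibrated to a 20-sample matrix and generalizes as
`ceiling(0.55 * n)` otherwise.

# CORE delimitation

Ortholog pairs between the two parental assemblies are found by reciprocal
best hit (RBH) under Smith–Waterman local alignment with blastn-like
scoring (match +1, mismatch −3, gap open −5, gap extend −2; a gap of length
L costs 5 + 2L). The alignment engine is `Biostrings::pairwiseAlignment`;
the test suite cross-checks it against an independent dynamic-programming
implementation written for the tests alone. An exact k-mer seeding step
(default k = 11, at least 2 shared k-mers) restricts the all-vs-all search
the way seeded aligners do; at the SNP densities this design targets
(≤ 5% divergence) a true ortholog pair shares hundreds of intact 11-mers
while unrelated pairs share none beyond chance, so the screen is
effectively lossless, and sequences shorter than k fall back to exhaustive
alignment.

The *common orthologous region* (CORE) of a pair is the query/subject
interval of the single highest-scoring local alignment — no chaining of
multiple high-scoring segments. This is the simplest deterministic rule and
is adequate for ortholog pairs whose homologous cores are contiguous; it
will truncate COREs interrupted by large indels or rearrangements, which is
a deliberate conservatism (counting inside a too-short CORE is safe;
counting across a rearrangement is not). Thresholds `min_score = 80` and
`min_len = 100` bp are exposed; they are floors that keep alignment noise
out rather than biologically meaningful constants. Coordinates are 0-based
half-open everywhere, including the BED6 output, so interval arithmetic is
bit-exact. Local alignment trims terminal mismatches by construction, so a
recovered boundary can sit a few bases inside the planted homologous
interval when SNPs fall near its ends; the acceptance suite requires ±5 bp
agreement for ≥95% of loci at 2% divergence rather than exactness.

`validate_cores()` reports |length| and |GC| differences between the two
sides of each CORE (flags at >16 bp and >0.02 by default) but never deletes
— filtering at this stage is a reporting/QC concern, not an inference one.

# Read sorting against both parents

Reads are aligned to **both** complete parental references independently.
The comparison metric is the mismatch count (the package accepts SAM/BAM
with `NM` tags; its own toy mapper is ungapped, end-to-end, both strands,
discarding placements that tie at the best mismatch count — the behaviour
of a `-m 1`-style unique-mapping mode). Classification per read:

* unique on both sides: strictly fewer mismatches on one side →
  diagnostic for that parent; equal → shared;
* unique on exactly one side (other unmapped *or* multimapping): diagnostic
  for the mapped side;
* otherwise unusable.

Deferring to the unique side when the other side multimaps is a choice the
data cannot arbitrate (a multimapper carries no usable position); it
maximizes usable reads while honouring uniqueness where a position is
actually needed. A read contributes to a CORE only if its full alignment
interval is **contained** in the CORE on every side where it mapped
uniquely, and the COREs agree across sides; containment rather than overlap
keeps flank-contaminated reads out. These rules make the classification a
total function, which the tests verify by enumerating every
mapped/unique/multimapping combination.

# The homoeolog-proportion posterior

Let q be the proportion of a CORE's diagnostic expression originating from
the parent-A homoeolog. Modelling the two diagnostic counts as independent
Poisson draws with Gamma-distributed rates and conditioning on their total
reduces the likelihood to Binomial(n_A + n_B, q) — so with a Beta prior the
posterior is conjugate:

q | n_A, n_B ~ Beta(c·π₀ + n_A, c·(1−π₀) + n_B).

The prior concentration c = 2 contributes two pseudo-reads in total —
enough to regularize empty COREs, far too little to move a CORE with real
coverage. The decision rule is deliberately prior-robust: a call requires
the 95% equal-tailed credible interval to exclude 0.5 *on the same side*
under all three prior means π₀ ∈ {0.4, 0.5, 0.6}. The three-prior rule can
only remove calls relative to the central prior alone (a property the test
suite asserts), so it is conservative by construction. Equal-tailed rather
than highest-posterior-density intervals: they are reproducible from the
quantile function with no optimization and the posterior is unimodal in
every regime the rule is applied to.

Two numerical regimes:

* δ = 1 (no bias): closed form, `qbeta` quantiles.
* δ ≠ 1: the likelihood becomes Binomial(n, qδ/(qδ + 1 − q)) — an
  assignment-odds multiplier toward parent A — and the posterior is
  evaluated on a uniform 4001-point grid over [0, 1] with trapezoid
  weights, normalized, with equal-tailed quantiles by interpolating the
  cumulative distribution. Prior densities with shape < 1 are infinite at
  an endpoint; the endpoint ordinates are clamped, which affects nothing
  once a single read is observed. The acceptance suite requires grid and
  closed form to agree within 10⁻³ (posterior mean and both interval
  bounds) up to 10,000 reads per side.

Verdicts: `toward_A` / `toward_B` / `none`, plus `insufficient_data` below
`min_total = 10` diagnostic reads (an invented floor — with fewer than ten
informative reads a 95% interval can barely exclude anything, so the call
would be vacuous either way) and `excluded_biased` for COREs removed by the
bias filter. Opposite-side exclusions across priors are theoretically
possible at tiny counts and collapse to `none` with a warning.

A note on calibration: the frequentist type-I error of "95% credible
interval excludes 0.5" on Binomial data oscillates with depth because the
data are discrete, sitting below 5% at moderate counts and approaching the
nominal rate from either side as counts grow. The acceptance suite
measures the rule at roughly 100–400 pooled diagnostic reads per CORE —
the depth band the capture/RNA designs this package targets actually
produce — and requires ≤5% calls on truly balanced COREs.

# Mapping-bias filtering

Mapping bias — reads from one homoeolog aligning systematically better to
the other parent's reference — would masquerade as HSE. The diploids
measure it directly: a read from a parent-A individual *must* originate
from A, so any diagnostic read of theirs assigned to B (and vice versa) is
a mis-assignment. Per CORE the package builds a library-size-equalized
in-silico mixture: each species' pooled diagnostic counts are scaled to
equal totals (the smaller total, rounded) and summed. Under no bias the
mixture's expected parent-A proportion is exactly 0.5, which is what makes
the same three-prior 0.5-exclusion rule coherent here; any credible
departure flags the CORE. Flagged COREs are excluded from HSE calling and
from fate classification. COREs where one species contributes zero
diagnostic reads cannot be assessed and are retained with a `low_power`
flag rather than silently trusted or dropped.

`delta_hat`, the reported bias size, is the smoothed mixture assignment
odds (n_A + ½)/(n_B + ½). On a balanced mixture this estimates exactly the
odds multiplier δ that the bias-aware likelihood uses, and equals 1 for an
unbiased CORE.

# HSE calling granularity

Replicates are **pooled within lineage** before calling: the reported
science is per independently formed lineage, the replicates are biological
copies of the same lineage, and pooling triples the diagnostic depth where
the binomial information lives. A hierarchical replicate model would add a
dispersion parameter the three-replicate design cannot estimate stably;
this is a known simplification, listed under limitations.

# Mid-parent additivity

The expression matrix (total CORE counts, homoeolog-agnostic) is filtered —
a locus needs ≥10 counts-per-million, evaluated against the *average*
library size, in ≥11 of the 20 samples — then transformed to
log2((count + 0.5)/(lib + 1)·10⁶) with per-observation precision weights
from the mean–variance trend (limma-voom, loess span 0.5), and fit with
weighted least squares per locus. Residual variances are shrunk by
empirical Bayes and contrasts tested with moderated t-statistics
(`limma::eBayes`); with a single locus, or on request, ordinary t-tests are
used instead (the single-locus case equals the textbook contrast t-test,
which the suite checks).

Two contrast families, each BH-adjusted separately at FDR 0.05:

* `parent_A − parent_B` across loci → parents same/different;
* per lineage, `poly − ½·parent_A − ½·parent_B` → consistent-with-additive
  / not-additive.

"Arithmetic mean of the parents" is tested **on the log2-CPM scale** — the
scale the weighted linear model lives on, so the moderated inference is
exact; a `scale = "linear"` option applies the same contrast to unlogged
fitted means with a delta-method standard error, but that route is
approximate and off by default. Separate BH families mirror per-lineage
reporting and keep one lineage's signal from borrowing significance for
another. The `power_flag` marks loci where the parents differ and the
lineage mean lies strictly between the parental means: there the mid-parent
test is intrinsically underpowered (the effect is bounded by half the
parental difference), so "consistent with additive" is weaker evidence.
Report percentages are rounded half away from zero to one decimal — the
rule that reproduces published classification tables exactly, which the
acceptance suite asserts against all sixteen printed cells.

# Fates and convergence

Per homoeolog per lineage: DNA and RNA evidence present → expressed; DNA
only → silenced; neither → lost; RNA only → failed (capture failure or
mismapping — kept as its own category rather than folded into "expressed"
because it is a QC signal). Presence thresholds default to one read, the
most literal reading of "mapped reads", and are configurable for
robustness analysis; fates are computed on the unbiased CORE set and pool
replicates per lineage.

Convergence across lineages reports, per fate state and parent of origin,
the per-lineage set sizes, the all-lineage intersection, the union, and
*two* overlap fractions — intersection/union and intersection/min(size) —
because "percent shared" is ambiguous between those denominators and the
choice changes the number materially. Exclusive (UpSet-semantics)
intersections are computed by membership pattern and checked against a
brute-force enumeration. Network summaries only verify degree (2E/N) and
mean local clustering arithmetic (0 for degree < 2 nodes) on a
user-supplied edge list; database retrieval and enrichment statistics are
out of scope.

# The synthetic-data generator

The generator is the package's ground truth and defines its study
conditions; its defaults are fixed once and are not tuned per analysis.

| parameter | default | meaning |
|---|---|---|
| `n_loci` | 2000 | ortholog pairs |
| `contig_len_range` | 400–800 bp | homologous core length (contig = core + 2 flanks) |
| `snp_rate` | 0.02 | per-base ortholog divergence |
| `flank_len` | 100 bp | non-homologous contig ends |
| `read_len` | 100 bp | read length |
| `seq_error_rate` | 0.005 | per-base error (read-level path) |
| `n_lineages`, `n_reps` | 4, 3 | independent polyploid origins, replicates |
| `n_diploid_A`, `n_diploid_B` | 5, 3 | diploid individuals |
| `lib_size_mean` | 10⁶ | expected reads per sample |
| `dispersion` | 0.05 | NB dispersion φ (variance μ + φμ²) |
| `frac_hse`, `q_alt` | 0.3, 0.8 | HSE frequency and effect |
| `frac_bias`, `delta` | 0.1, 1.5 | mapping-bias frequency and odds ratio |
| `frac_nonadditive`, `beta_na` | 0.3, 1 | non-additivity frequency, log2 effect |
| `frac_parents_diff`, `parent_lfc` | 0.22, 1.5 | parental DE frequency, log2 effect |
| `frac_lost`, `frac_silenced` | 0.03, 0.03 | per-homoeolog state rates |
| `dna_depth_mean` | 50 | capture reads per retained homoeolog |

Rates without a published analogue (library sizes per sample, capture
depth, effect sizes) are invented and documented as such; the fractions
echo the proportions a mesopolyploid system of this kind exhibits (a few
percent loss/silencing, roughly a fifth of loci parentally differential).

Mechanics worth knowing when interpreting test results:

* **Two separate paths.** Count-level simulation feeds the statistical
  modules directly (fast, no alignment); sequence-level simulation
  (transcriptomes + reads with errors, origin-encoded read IDs) exercises
  CORE delimitation and the mapper. This decouples alignment fidelity from
  inference testing on purpose.
* **Diagnostic fraction.** In the count-level path, the probability a read
  covers ≥1 SNP is taken as 1 − (1 − snp_rate)^read_len for every CORE —
  the expected value, not the per-CORE realized SNP density.
* **Bias mechanism.** δ is realized per read: a diagnostic read from the
  disfavoured parent is mis-assigned with probability
  (δ − 1)/(δ + 1) (δ ≥ 1; mirrored below 1), so a balanced mixture has
  assignment odds exactly δ — the same quantity the bias-aware likelihood
  multiplies in and that `delta_hat` estimates.
* **Loss is ancestral, silencing is not.** Loss events are drawn once per
  homoeolog and shared by all lineages (planted before the lineage split);
  silencing is drawn independently per lineage (among retained homoeologs,
  at a conditional rate that keeps the marginal at `frac_silenced`). This
  is the structural contrast — convergent fractionation versus stochastic
  silencing — that the convergence statistics are designed to expose, and
  it is an *assumption* of the generator, not a finding.
* **Non-additivity acts on the log2 scale.** The polyploid mean is the
  mid-parent log2 mean plus `beta_na`, matching the scale the additivity
  test operates on. Lost/silenced homoeologs scale the polyploid total by
  the active homoeolog share, so fate and additivity effects interact the
  way they would in real data; tests of one module therefore switch the
  other effects off.
* **Determinism.** Every operation takes a seed (default from the config);
  identical seeds give byte-identical FASTA/TSV outputs, which the suite
  checks.

What the generator does **not** emulate: paired-end inserts, isoforms,
adapter contamination, GC- or position-dependent coverage, genuinely
hierarchical replicate effects (replicates are i.i.d. NB draws), gene
conversion between homoeologs, or reference assembly errors. Passing tests
show the inference machinery is correct under the stated noise model; they
do not show robustness to artifacts the generator cannot produce.

# Problem sizes used by the checks

The test and acceptance runs use 200–1200 simulated loci, library sizes of
6×10⁴–5×10⁵ reads, and 200 ortholog pairs for sequence-level recovery —
sizes at which every planted effect is comfortably identified and the full
suite runs in about a minute on a single core. These are the package's
reference problem sizes; all of them scale linearly.

# Known limitations

* RBH + single-best-alignment CORE delimitation assumes contiguous
  orthologous cores; paralog-rich families yield at most one pair per
  contig by construction.
* Replicate pooling forgoes replicate-level dispersion in HSE calls.
* The bias filter needs diploid coverage in a CORE to protect it;
  `low_power` COREs pass through unfiltered and are flagged instead.
* The linear-scale additivity option uses a delta-method approximation.
* The toy mapper is for fixtures: ungapped, no quality scores, no splicing;
  production alignments should come in as SAM/BAM with `NM` tags.
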