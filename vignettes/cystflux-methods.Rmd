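---
title: "Methods: V9 metabarcode assignment and sediment-trap strontium fluxes"
author: "cystflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: V9 metabarcode assignment and sediment-trap strontium fluxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cystflux)
```

`cystflux` analyses two data streams that carry the signal of cyst-forming
Acantharia — protists with celestite (SrSO₄) skeletons whose reproductive
cysts sink from the surface ocean to depth: V9 18S rRNA amplicon reads, and
sediment-trap bottle series in which dissolving celestite elevates strontium
far above the seawater background. This vignette documents the models and
procedures, the parameters that matter, the numerical choices, and what the
simulators do and do not emulate.

## Amplicon quality control

Reads are screened by two rules, applied in order.

**Exact primer matching.** The forward primer must match at position 1 and
the reverse complement of the reverse primer at the 3′ end, exactly. IUPAC
degeneracy is honoured in the *primer* only: a primer `Y` accepts a read `C`
or `T`, but an ambiguous base in the *read* (`N` or any other IUPAC code)
matches nothing — the conservative reading, since a read-side `N` carries no
evidence of a primer. Both primer spans and their quality values are removed
on success. The defaults are the general-eukaryote V9 primers
1389F (`TTGTACACACCGCCC`) and 1510R (`CCTTCYGCAGGTTCACCTAC`); reads are
assumed already merged and oriented, so both primers are sought on the one
merged sequence.

**Windowed expected error.** Each Phred score becomes an error probability
$p_i = 10^{-Q_i/10}$, and every window of `window_length` (default 50)
consecutive bases — sliding, step 1 — is summarised by its mean $p_i$. A read
is discarded only when some window mean is *strictly* greater than
`max_window_error` (default 0.01). "1% error in a 50-bp section" is thus read
as expected error from the quality values, not as a count of low-quality
bases: the expected-error reading is the standard quality-aware
interpretation and uses the full quality string. Reads shorter than the
window are evaluated as one full-length window. Two numerical details:

* the strict inequality is applied with a $10^{-12}$ guard, so a window
  sitting exactly at the limit (30 bases at Q20, mean exactly 0.01) passes
  regardless of floating-point summation order;
* window means are computed from a cumulative sum, making the filter $O(n)$
  per read.

Raising every quality score can therefore never flip a read from pass to
fail, and the per-reason rejection counts partition the input exactly. A
chimera-filter hook exists in `run_qc()` but defaults to a no-op: chimera
detection is deliberately out of scope.

## Taxonomic assignment

Each retained read is aligned **end-to-end against every reference** with an
exact Needleman–Wunsch/Gotoh global alignment: affine gap costs (a gap of
length $L$ costs `gap_open` $+ L\,\cdot$ `gap_extend`), terminal gaps
penalised, implemented in C++. The defaults +5/−4/−12/−2 are common DNA
global-search parameters; all four are configurable, and the gap convention
matches `Biostrings::pairwiseAlignment`, which the test suite uses as an
independent cross-check of alignment scores (the brute-force enumeration
oracle over all global alignments of short pairs is the primary check).

**Percent identity** is `n_matches / n_columns` over *all* alignment columns:
gap columns and `N` columns count in the denominator only, and a column
matches only when both symbols are the same unambiguous A/C/G/T. The
all-columns denominator is the natural choice for an end-to-end alignment —
it is reproducible, symmetric, and penalises length differences rather than
hiding them.

**Tie handling.** Score ties are resolved inside the dynamic program
lexicographically — maximal score, then maximal match count, then minimal
column count, then diagonal > up > left — so the reported
(score, matches, columns) triple is unique, byte-reproducible, and symmetric
in the two sequences. Identities are compared across references as exact
rationals (integer cross-multiplication), so equal identities are detected
without floating-point artifacts. A read with a single nearest neighbour
takes that reference's full lineage; tied nearest neighbours contribute the
longest root-first common prefix of their lineages (the last common
ancestor). The LCA of identical lineages is that lineage, and lineages with
no common rank fall back to a designated `"Unassigned-root"` — a case a
well-formed reference database never produces.

**Thresholds.** Assignment requires identity *strictly above* 0.85, and the
cyst-similarity screen strictly above 0.97, following the "more than"
wording both rules come from. Comparison against a decimal threshold treats
agreement within $10^{-9}$ as equality (distinct read identities differ by at
least one part in `n_columns`², far larger), so a read at exactly 17/20 =
0.85 is unassigned. Nearest neighbours are ranked by identity, not raw
score, because the retention criterion itself is identity-based; with the
default scoring the two rankings agree except in contrived cases.

## Community summaries

Samples are binned into half-open depth zones `[0, 100)`, `[100, 1000)` and
`[1000, 3000]` metres (closed top, anything deeper is `below-3000 m`).
Assigned reads are counted per (sample, clade), where the clade label is the
lineage element at a configurable rank (default 2, matching the two-rank
`Acantharea;Clade<X>` convention of the simulator); LCA-assigned reads whose
lineage is too shallow for that rank are kept in the denominator as
`unresolved`. Fractions normalise to 1 per sample before any masking; clades
below the 1% display floor are flagged, never dropped. Unassigned reads are
excluded from composition denominators and reported separately — a choice,
documented here, since conventions differ.

## Sediment-trap strontium fluxes

Per trap — never pooled — the background is the mean of all bottles strictly
below the 9 µg mL⁻¹ cutoff, with the *sample* standard deviation (n−1; the
plain reading of "standard deviation" for an empirical scatter estimate,
requiring at least two sub-cutoff bottles). A bottle is significantly
elevated when its concentration is strictly above mean + 2·sd; a bottle
exactly at the threshold is not significant. A zero-sd background is allowed
but warns, since the threshold then degenerates to "> mean".

For significant bottles,

$$F_\mathrm{Sr} = \frac{(c - \bar{c}_\mathrm{bg})\, V / 1000}{A\,T}
\quad \left[\mathrm{mg\,Sr\,m^{-2}\,d^{-1}}\right],$$

with $c$ in µg mL⁻¹, bottle volume $V$ in mL, collection area $A$ in m²
(default 0.66 — the printed "0.66 m⁻²" is taken as a typographical inversion
of an area) and period $T$ in days. The uncertainty combines a 1% relative
analytical uncertainty on the measured concentration with the background
standard deviation, in quadrature, scaled like the flux:
$\sigma_F = \sqrt{(0.01c)^2 + s_\mathrm{bg}^2}\; V/1000/(AT)$. Using
$s_\mathrm{bg}$ itself rather than $s_\mathrm{bg}/\sqrt{n}$ is the
conservative reading: the background subtracted from a single bottle is
uncertain at the scatter of single bottles. Carbon fluxes follow from the
cyst C:Sr ratio (default 0.120 ± 0.022 mg C per mg Sr) with relative errors
combined in quadrature, and a zero Sr flux maps to zero carbon flux with
zero uncertainty. The percent-of-POC contribution needs an externally
measured total POC flux and is plain percentage arithmetic.

The carbonate bound answers "could dissolving CaCO₃, rather than celestite,
explain the Sr excess?": a Ca elevation of $E$ µg mL⁻¹ at ~1 mg Sr per g
bounds the carbonate-derived Sr at $E/1000$ µg mL⁻¹. The per-gram basis is
applied to the measured Ca elevation, which reproduces the conventional
0.3 µg mL⁻¹ bound for a 300 µg mL⁻¹ elevation; a per-gram-of-CaCO₃ basis
would give ≈0.75, so the basis is exposed as the `sr_per_g` parameter rather
than hard-coded.

Core functions return full precision. `format_flux_report()` truncates
*toward zero* — 2 decimals for Sr fluxes, 3 for carbon fluxes — because that
is the rounding that maps 0.0156 → 0.015 and 0.0276 → 0.027, i.e. the
convention of the printed flux tables this layer mirrors; a $10^{-9}$ guard
keeps products like 0.23 × 0.120 on the correct side of a decimal boundary.

## The simulators

`generate_reference_set()` draws a random root sequence, derives one
ancestor per clade by mutating the root at `between_clade_divergence`
(default 0.2), and each reference by mutating its ancestor at
`within_clade_divergence` (default 0.02). A shared root with independent
per-clade mutations uses both divergence parameters and guarantees that
within-clade identity exceeds between-clade identity whenever the two rates
are separated; fully independent clade ancestors would have left the
between-clade parameter meaningless. Defaults — 4 clades × 5 references of
130 bp — emulate the size and spacing of the acantharian V9 clades (well
separated clades, a few percent within-clade diversity, ~130-bp V9 region).

`simulate_reads()` builds each read as
`fwd_primer + mutated insert + revcomp(rev_primer)` with a substitution-only
error model (default 0.01 per base; an indel rate exists but defaults to 0
because the quality filters are substitution-oriented and the V9 region is
short). Degenerate primer positions are instantiated to their alphabetically
first compatible base so reads are concrete and deterministic yet still
match the degenerate primer exactly. Miscalled bases get the `error` Phred
score of the quality model (default Q20), all others the `correct` score
(Q40) — a two-state caricature of real quality strings in which errors are
*flagged* by low quality; real miscalls are only statistically associated
with low Q. Truth lineages travel in a sidecar table, keeping the FASTQ
standard-clean.

`simulate_trap_series()` draws bottle concentrations from
N(8, 0.2) µg mL⁻¹ — seawater Sr is ~8 µg mL⁻¹, and 0.2 keeps the simulated
range inside the few-tenths scatter reported for real preservative
backgrounds — and adds `mass / volume` to spiked bottles. Negative draws are
resampled rather than truncated, preserving approximate Gaussianity.
Defaults: 21 bottles (the bottle count of the McLane time-series traps this
emulates), 500 mL, 0.66 m², 14-day periods, three spikes of 2000–4500 µg
(elevations of 4–9 µg mL⁻¹, the "several µg mL⁻¹ above background" regime).
Truth fluxes are recorded per spiked bottle.

Everything is seeded and byte-deterministic; reference and read generation
use offset seed streams so one configuration can drive both.

**What passing tests do and do not show.** The simulators omit chimeras,
amplification bias, indel-rich error modes, length variation in the V9
region, taxonomic overlap between clades, seasonality in trap series, and
non-Gaussian background excursions. Recovery rates on these simulations
therefore validate the *logic* of the pipeline (filters, alignment,
tie-breaking, flagging, propagation) under controlled conditions — they are
not performance estimates for field data.

## Known behaviour of the significance screen

One property of the mean + 2·sd rule deserves emphasis: with ~18 Gaussian
background bottles per 21-bottle series, the per-bottle probability of a
chance exceedance is ≈2%, so roughly a third of simulated series flag at
least one unspiked bottle. The replicate study in
`analysis/04_strontium_flux.R` and the acceptance script measure exactly
this (≈30% of replicates with a false-positive bottle, 100% spike detection,
≈98% coverage of truth fluxes by ±2 propagated SDs). The false-positive rate
is a property of the published decision rule at this series length, not an
implementation artifact; a practitioner wanting fewer chance flags must
raise the multiplier or correct for multiplicity, at the cost of sensitivity
to small fluxes.

## Problem sizes and other choices

The bundled tests and the acceptance script use 2,000 simulated reads
against 20 references for recovery, 500 random short pairs for the
brute-force alignment oracle, and 200 simulated trap series for the
significance-screen study — sizes at which the checks are statistically
meaningful while a full run stays in the minutes range on one core.
The exhaustive oracle enumerates every global alignment of sequences up to
length 6, which is feasible (≤ ~9,000 alignments per pair) and completely
independent of the dynamic program it checks.

Open choices resolved here, beyond those noted above: reference databases
merge by id with duplicate ids rejected outright (how overlapping source
databases were merged is not standardised anywhere); sliding rather than
tiled quality windows (every 50-bp section, not disjoint blocks); and
bottles between the background cutoff and the significance threshold are
simply non-significant.

## Limitations

The aligner is exact and therefore quadratic per pair — appropriate for
reference panels of tens to thousands of sequences, not for millions of
reads against large databases without a pre-filter. The pipeline assumes
merged, oriented reads; it does not merge pairs, trim by quality, or detect
chimeras. Flux uncertainties ignore volume and area measurement error, and
the C:Sr conversion inherits the single published cyst ratio with its
uncertainty.
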