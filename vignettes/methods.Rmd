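---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axescreen)
```

This vignette explains the science behind each pipeline stage, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the design choices made where the procedure left room
for interpretation. No empirical number appears here that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The screening problem

A haploid amoeba is selected in liquid medium until spontaneous mutants
able to grow axenically take over. Several independently selected strains
are resequenced. Any gene mutated in *every* independent isolate — but by a
*different* lesion in each — is a strong causal candidate. The pipeline
encodes the three filters that make this work:

1. **Quality triage** removes alignment artefacts: a call is kept iff read
   depth > 3, mapping quality > 20 and call quality > 20 (all strict, as
   "greater than" demands) and the genotype is a clean homozygous ALT. In a
   haploid genome a "heterozygous" call can only be a mixed-alignment
   artefact, so it is dropped (switchable via `drop_heterozygous`).
2. **Common-variant subtraction** removes real differences between the
   parental laboratory strain and the reference assembly: any key
   (chrom, pos, ref, alt) present in *all* strains is excluded everywhere.
   With more than four strains one may wish to relax "all" to "at least
   n"; the rule is exposed as `require_n` but defaults to all, the
   published behaviour. Variant identity is exact-key; indel
   representations are not re-normalised (no normalisation rule was
   stated), but indels of different representation at the same position
   are surfaced via the `position_collisions` attribute for manual review.
3. **Coding flags** by interval overlap between the altered genomic span
   (1 bp for a SNV; `[pos, pos + nchar(ref) - 1]` for anchored indels) and
   the CDS interval.

## 2. Coding-effect annotation

The gene model is a bare CDS plus optional upstream sequence; c. position 1
is the A of ATG, position −1 the base 5' of it, and position 0 does not
exist. Span lengths therefore equal `end − start + 1` within one sign and
`end − start` across the sign change — the upstream-into-CDS deletion
`c.-1954_6926delins…` removes 1954 + 6926 = 8880 nt, "almost nine
kilobases". External-reference delins inserts (`CM000150.2:1390060_1390808`)
are carried as opaque tokens with a declared length; applying such a
variant fills the insert with `N`, which suffices because its
classification (start codon removed → `start_lost`) is content-free.

Classification precedence: entirely-upstream → `upstream_noncoding`; start
codon disrupted → `start_lost`; net length change within the CDS ≢ 0
(mod 3) → `frameshift` (the codon index of the downstream stop in the
shifted frame is reported as a supplementary field, not as part of the
class); an in-frame stop arriving before the *expected mutant length*
(reference length + net/3 codons) → `nonsense`; otherwise substitutions
split into `missense`/`silent` and in-frame indels/inversions/delins into
`inframe_deletion`/`inframe_substitution`, with the changed peptide
reported by trimming the common prefix then suffix of the two
translations. The expected-length rule matters: a clean in-frame deletion
shortens the protein and so reaches its (original) stop earlier in
sequence position — that is not a premature stop.

`name_variant()` inverts `apply_variant()` and normalises per the HGVS
3'-rule by maximising the common prefix before trimming the common suffix,
so deletions/insertions inside repeats take their most-3' representation.
An equal-length changed block that is the reverse complement of its
reference is reported as an inversion. Two edits are declared disjoint (and
rejected, with both loci named) only when the changed block contains an
internal unchanged run of ≥ 8 nt; shorter internal matches arise routinely
inside genuine delins and inversion edits and must not trigger rejection.

Translation uses the standard genetic code only.

## 3. Duplication scanning

Per-position depth is smoothed with a centred rolling median (window 999,
odd by construction) — a single outlier spike cannot move a 999-point
median — then sampled every 1000th position. At the chromosome ends the
window is truncated to the available positions (the original procedure is
silent on edges; `edge = "drop"` blanks them instead). Interior positions
use the C running median in `stats::runmed`; the truncated ends are
recomputed explicitly, and a brute-force oracle test covers both regimes.

The original analysis called duplications by visual inspection of these
profiles. The numeric rule here is a formalisation, and its defaults are
package decisions, not published facts: background = chromosome-wide
median of the sampled profile (robust while duplications occupy < 50% of
the chromosome); "approximately double" = point ratio in [1.75, 2.25];
minimum run = 50 sampled points (50 kb at the default step), consistent
with duplications "spanning hundreds of kilobases". Because only ratios
enter, the caller is invariant under uniform depth scaling.

## 4. Homology profiling

Both aligners are implemented internally (Rcpp, Gotoh three-state DP with
traceback). Scoring defaults are the classic EMBOSS `water`/`needle`
defaults — BLOSUM62, gap open 10, gap extend 0.5 — since the original
analysis names the tools but not the parameters; a gap of length L costs
`open + extend·(L−1)`, and ambiguity residues (B, Z, X) score 0 against
everything. Because the exact matrix/penalties used originally are
unknowable, the published homology curves and percentages are *not*
reproduced bit-for-bit and are excluded from acceptance; what is tested is
the machinery, against independent brute-force oracles.

The window profile cuts the query into 200-residue windows ("split into
segments" and "sliding window" are both honoured: the default step 100
gives half-overlapping windows, `step = window` reproduces the disjoint
split). Each window is locally aligned to each target and to the **full
query**, and normalised by that self score — the only reading under which
every self-comparison window "gives a value of one" exactly, since a
window's perfect match is a substring of the query. This also bounds every
normalised score in [0, 1]. The tail window is shortened, never discarded.

Global percentages count gap columns in the denominator (the explicit
point of using a global aligner: indels count against homology);
similarity = strictly positive substitution score, so similarity ≥
identity always. `map_aligned_position()` projects residue indices through
an alignment (for "approximate corresponding location in the human
orthologue" annotations), returning the nearest 5' aligned position,
flagged, when the query residue faces a gap.

## 5. Membrane patch quantification

Cells arrive as outline polygons over a grayscale image. The perimeter is
resampled at equidistant arc-length points 2 px apart; at each point a
3-px normal is read by nearest-pixel lookup and its maximum intensity
taken. The normal is centred by default (one pixel inside, one on, one
outside); inward/outward placement is a flag, since the original
description fixes only the length. Cytosol statistics use the interior
eroded by the normal reach (3 px, 8-neighbour erosion, which guarantees
Euclidean clearance) so membrane pixels never contaminate them; the SD is
the population form, and the threshold is mean + 3·SD with a strict `>`
(both the SD form and the mask construction are package decisions — the
original states only "3 standard deviations above the mean intensity of
the cytosol"). The patch fraction is computed over non-missing points
only; points whose normals fall wholly outside the image are flagged and
leave the denominator. The whole statistic is exactly invariant under
affine intensity transforms `a·I + b`, `a > 0`.

Per-cell values are reported as-is; aggregation across cells (the original
compared > 100 cells per strain) is left to the caller beyond a mean ±
SEM summary, since the comparison statistic used originally is unstated.

## 6. The synthetic world

The generator's defaults state the conditions under which the pipeline is
validated:

* **Genomes**: AT-rich (A = T = 38.8%), matching the ~77.6% AT content of
  the *Dictyostelium* nuclear genome; CDS assembled from sense codons,
  ATG…stop. Default test geometry uses tens-of-kb genomes purely for
  speed; coordinates, not length, are what the triage exercises.
* **Strains**: each private mutation is an HGVS c. description converted
  to an anchored VCF record with qualities drawn well above every
  threshold (depth 10–30, MQ 45–60, QUAL 100–220). Shared parental
  variants (default 10) are likewise above-threshold **by design**, so
  that only the subtraction step can remove them — isolating that step
  for testing. Noise records (default 5 per strain; the real
  false-positive rate per strain is unpublished, so this is a free
  parameter) each fail at least one threshold, drawn uniformly among the
  four failure modes.
* **Coverage**: independent Poisson draws per position, mean 20 (the
  published 17–20×), doubled inside planted duplications; a
  negative-binomial switch (`dispersion`) adds overdispersion when
  desired. Default acceptance geometry: 2-Mb chromosome, one 300-kb
  duplication — "large, spanning hundreds of kilobases".
* **Proteins**: per-site substitutions to one of the other 19 residues
  and optional per-site indels, giving homologue pairs of known
  divergence.
* **Cells**: an axis-aligned ellipse (semi-axes 60 × 45 px in a 192-px
  field, cell-scale at usual confocal sampling), truncated-Normal cytosol
  (mean 100, SD 10), 1-px membrane ring at the cytosol mean, one
  contiguous patch arc raised by 10 SD, intensities rounded to integer
  grey levels. The outline is the ordered ring pixel trace,
  counter-clockwise by shoelace sign on raw coordinates (visually
  clockwise under the image's downward y axis).

All randomness flows from one seed through independent named substreams
(`substream_seed`), so adding a generator never perturbs another's draws.

What the synthetic world does **not** emulate — and hence what a green
test does not establish: read-level error and mapping bias (call sets are
generated, not called), GC-coverage coupling, indel representation
ambiguity across strains, multi-cell crowding or uneven illumination in
images, and any biology (growth rates, endocytosis, Ras signalling). A
passing recovery test says the *procedure* is implemented correctly, not
that it would be robust to every artefact of real data. Pixel-trace
outlines also have a jagged-staircase perimeter ~20% longer than the
underlying ellipse's circumference; patch *fractions* are unaffected
(numerator and denominator scale together), but absolute point counts per
cell are higher than smooth clicked outlines would give.

## 7. Numerical and degenerate-input choices

* Thresholds are strict inequalities throughout (filtering, patch
  threshold).
* `rolling_median` rejects even windows; `detect_duplications` rejects
  zero-coverage backgrounds; empty subsampled profiles are legal.
* Local alignment of anything with an empty sequence scores 0 with an
  empty alignment (the local floor); global alignment of an empty
  sequence is an error.
* Alignment ties are broken deterministically (diagonal > gap-in-target >
  gap-in-query; opening preferred to extending at equal score), which
  fixes the reported traceback but never the score.
* Image I/O uses plain-text intensity grids (one tab-separated row per
  pixel row) rather than binary PNG/TIFF, keeping fixtures text-only and
  dependency-free; the in-memory contract is an integer matrix either
  way.
* The CLI refuses to run stochastic stages without `--seed` unless
  `--no-seed` is explicit, and identical argv + seed give byte-identical
  outputs.

## 8. Known limitations

* HGVS coverage is the dialect the screen needs (substitution, del, ins,
  delins, inv on a bare CDS, negative upstream coordinates); `dup`,
  protein-level (p.) and genomic (g.) notations, and splice-aware gene
  models are out of scope.
* The duplication caller reports sampled-grid resolution (±1 kb at
  defaults); no base-pair breakpoint refinement, no deletion calling.
* `subtract_shared` treats representation-identical keys only; a real
  cross-strain indel-normalisation pass would need left/right alignment
  of alternate representations.
* The normal-direction estimate at perimeter points assumes a roughly
  convex outline (orientation is resolved against the centroid); deeply
  concave manual outlines could flip isolated normals.
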