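# axescreen

Tools for the computational half of a classic forward genetic screen in a
haploid microbe: given whole-genome resequencing of several independently
selected mutant strains, find the one gene they all break. The package
re-implements, as tested and reusable R functions, the analysis route that
mapped axenic (liquid-medium) growth of *Dictyostelium discoideum* to loss
of its NF1 (RasGAP) orthologue — and pairs every stage with a synthetic-data
generator that knows the ground truth, so each step can be validated by
parameter recovery.

## What is in the box

| stage | functions | idea |
|---|---|---|
| variant triage | `filter_calls()`, `subtract_shared()`, `flag_coding()`, `triage_strains()` | keep calls with depth > 3, MQ > 20, QUAL > 20, homozygous only; then drop every variant present in *all* strains (parental background vs. reference); flag CDS overlaps |
| effect annotation | `parse_hgvs_c()`, `apply_variant()`, `classify_effect()`, `codons_spanned()`, `name_variant()` | HGVS c.-notation on a bare CDS model; frameshift iff net inserted−deleted length ≢ 0 (mod 3); nonsense/missense/silent; inversions as in-frame peptide substitutions; 3'-normalised naming |
| duplication scan | `rolling_median()`, `subsample()`, `detect_duplications()`, `cnv_scan()` | per-position depth → centred rolling median (window 999) → every 1000th position → maximal runs of ≥ 50 points at ~2× the chromosome median |
| homology profile | `local_align()`, `global_align()`, `window_profile()`, `map_aligned_position()` | internal Smith–Waterman / Needleman–Wunsch with affine gaps (BLOSUM62, open 10, extend 0.5); 200-residue windows scored against targets and divided by the window-vs-self score; global %identity/%similarity with gap columns in the denominator |
| membrane patches | `resample_perimeter()`, `sample_normals()`, `cytosol_stats()`, `patch_fraction()`, `quantify_patches()` | perimeter points every 2 px, 3-px normals, peak intensity per normal, patch threshold = cytosol mean + 3 SD |
| synthetic data | `make_reference()`, `plant_mutations()`, `simulate_depth()`, `mutate_protein()`, `render_cells()` | AT-rich genomes with an embedded CDS, strains with planted private/shared/noise variants, Poisson coverage with 2× duplications, diverged proteins, cells with planted membrane-patch arcs |
| CLI | `main()` | `simulate {strains,depth,proteins,cells}`, `triage`, `annotate`, `cnv-scan`, `homology`, `patches` |

The statistic at the heart of each stage, in the field's notation:

* a call survives triage iff DP > 3 ∧ MQ > 20 ∧ QUAL > 20 ∧ GT = 1/1, and
  its key (chrom, pos, ref, alt) is not shared by every strain;
* frameshift ⟺ (n_ins − n_del) mod 3 ≠ 0; codon of CDS base p is ⌈p/3⌉;
* duplication call: maximal runs with v_i / median(v) ∈ [1.75, 2.25], length
  ≥ 50 sampled points; copy ratio = median(segment)/median(chromosome);
* window profile: s(w, t) / s(w, q) with s the affine-gap local alignment
  score, q the query and w ⊂ q, hence self-profiles are exactly 1;
* patch fraction: #{max-normal intensity > μ_cyt + 3σ_cyt} / #points.

## Worked example

```r
library(axescreen)

## effect annotation: a 6-nt in-frame inversion substitutes two residues
m <- cds_model("ATGAAACCCGGGTAA")
classify_effect(m, "c.4_9inv")
#> <effect_call> c.4_9inv: inframe_substitution at codon 2 (KP > GF)
codons_spanned("c.6393_6413inv")$count   # the 21-nt inversion
#> [1] 8                                  # eight consecutive codons

## four synthetic strains, one private coding SNV each,
## 10 shared parental variants, 5 sub-threshold noise calls
ref <- make_reference(1, genome_length = 30000, cds_length = 900,
                      cds_start = 10001)
cds <- as_cds_model(ref)
specs <- lapply(c(HM01 = 101L, HM02 = 205L, HM03 = 307L, HM04 = 411L),
  function(p) {
    rb <- substr(cds$cds_seq, p, p)
    sprintf("c.%d%s>%s", p, rb, setdiff(c("A","C","G","T"), rb)[1])
  })
st <- plant_mutations(ref, specs, n_shared = 10, n_noise = 5, seed = 1)
triage_strains(lapply(st, `[[`, "callset"), cds_region = ref)$report
#>    strain n_input n_post_filter n_post_subtraction n_coding
#> 1:   HM01      16            11                  1        1
#> 2:   HM02      16            11                  1        1
#> 3:   HM03      16            11                  1        1
#> 4:   HM04      16            11                  1        1
```

Reading: each strain starts with 16 calls (1 private + 10 shared + 5
noise); quality filtering removes the 5 noise calls, subtraction removes
the 10 shared parental variants, and exactly the planted private coding
variant survives in each strain — the in-silico analogue of finding one
mutated gene in every independently selected mutant.

```r
## duplication scan: one 300-kb two-copy segment in 2 Mb of 20x coverage
tr <- simulate_depth(2e6, list(c(1000001L, 1300000L)), mean_depth = 20,
                     seed = 1)
cnv_scan(tr)$segments
#>    chrom start_pos end_pos n_points copy_ratio
#> 1:  chr1   1001000 1299000      299          2

## membrane patches: planted arc over 25% of the perimeter, 10-SD gain
cell <- render_cells(synthetic_image_spec(patch_fraction = 0.25, seed = 1))
quantify_patches(cell$image, cell$outline)
#> <patch_result> 202 points (0 missing), threshold 130.76, patch fraction 0.252
```

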