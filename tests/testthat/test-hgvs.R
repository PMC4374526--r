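test_that("parse_hgvs_c handles the screen's mutation vocabulary", {
  cases <- list(
    list("c.7137_7143del", "deletion", 7137L, 7143L, 7L),
    list("c.1015A > T", "substitution", 1015L, 1015L, 1L),
    list("c.6393_6413inv", "inversion", 6393L, 6413L, 21L),
    list("c.3508del", "deletion", 3508L, 3508L, 1L),
    list("c.226_230del", "deletion", 226L, 230L, 5L))
  for (cs in cases) {
    v <- parse_hgvs_c(cs[[1]])
    expect_s3_class(v, "hgvs_variant")
    expect_identical(v$kind, cs[[2]])
    expect_identical(v$start, cs[[3]])
    expect_identical(v$end, cs[[4]])
    expect_identical(hgvs_span_length(v$start, v$end), cs[[5]])
  }
  expect_identical(parse_hgvs_c("c.1015A>T")$alt, "T")
})

test_that("delins with an external-reference insert parses opaquely", {
  v <- parse_hgvs_c("c.-1954_6926delinsCM000150.2:1390060_1390808")
  expect_identical(v$kind, "delins")
  expect_identical(v$start, -1954L)
  expect_identical(v$end, 6926L)
  expect_identical(v$insert_ext, "CM000150.2:1390060_1390808")
  expect_identical(v$insert_len, 1390808L - 1390060L + 1L)
  # span crosses the missing zero: 1954 upstream + 6926 coding bases
  expect_identical(hgvs_span_length(v$start, v$end), 8880L)
})

test_that("malformed descriptions are rejected with the offending token", {
  expect_error(parse_hgvs_c("g.100A>T"), "not a c")
  expect_error(parse_hgvs_c("c.0A>T"), "position 0|unparseable")
  expect_error(parse_hgvs_c("c.10_5del"), "start > end")
  expect_error(parse_hgvs_c("c.10A>A"), "identical alleles")
  expect_error(parse_hgvs_c("c.banana"), "unparseable")
})

test_that("formatting round-trips the normalised string", {
  for (s in c("c.7137_7143del", "c.1015A>T", "c.6393_6413inv", "c.3508del",
              "c.12_13insTTA", "c.4_9delinsAT",
              "c.-1954_6926delinsCM000150.2:1390060_1390808"))
    expect_identical(format_hgvs(parse_hgvs_c(s)), s)
  # internal whitespace is normalised away
  expect_identical(format_hgvs(parse_hgvs_c("c.1015A > T")), "c.1015A>T")
})

test_that("apply_variant performs the edit stated on the coding strand", {
  m <- cds_model("ATGAAACCCGGGTAA")
  expect_identical(as.character(apply_variant(m, "c.4_9inv")),
                   "ATGGGGTTTGGGTAA")
  expect_identical(as.character(apply_variant(m, "c.4A>T")),
                   "ATGTAACCCGGGTAA")
  expect_identical(as.character(apply_variant(m, "c.4_5del")),
                   "ATGACCCGGGTAA")
  expect_error(apply_variant(m, "c.4C>T"), "reference mismatch")
  expect_error(apply_variant(m, "c.40A>T"), "outside")
})

test_that("upstream coordinates address the sequence 5' of the ATG", {
  m <- cds_model("ATGAAACCCGGGTAA", upstream_seq = "TTTTTC")
  # c.-1 is the base immediately before the ATG
  out <- as.character(apply_variant(m, "c.-1C>G"))
  expect_identical(substr(out, 6, 6), "G")
  expect_identical(substr(out, 7, 9), "ATG")
})

test_that("codons_spanned uses ceiling(p / 3) arithmetic", {
  cs <- codons_spanned("c.6393_6413inv")
  expect_identical(cs$first_codon, 2131L)
  expect_identical(cs$last_codon, 2138L)
  expect_identical(cs$count, 8L)
  expect_identical(codons_spanned("c.1_3del")$count, 1L)
  expect_identical(codons_spanned("c.3_4del")$count, 2L)
  expect_true(codons_spanned(parse_hgvs_c("c.-2_4del"))$truncated)
  expect_error(codons_spanned(parse_hgvs_c("c.-10_-2del")), "upstream")
})

test_that("classify_effect reproduces the canonical effect classes", {
  m <- cds_model("ATGAAACCCGGGTAA")
  expect_identical(classify_effect(m, "c.4A>T")$effect_class, "nonsense")
  inv <- classify_effect(m, "c.4_9inv")
  expect_identical(inv$effect_class, "inframe_substitution")
  expect_identical(inv$ref_residues, "KP")
  expect_identical(inv$alt_residues, "GF")
  expect_identical(inv$first_affected_codon, 2L)
  expect_identical(classify_effect(m, "c.4_5del")$effect_class, "frameshift")
  expect_identical(classify_effect(m, "c.4_6del")$effect_class,
                   "inframe_deletion")
  sil <- cds_model("ATGCTACCCGGGTAA")  # CTA -> CTG both Leu
  expect_identical(classify_effect(sil, "c.6A>G")$effect_class, "silent")
})

test_that("start-disrupting and upstream variants are classed separately", {
  m <- cds_model("ATGAAACCCGGGTAA", upstream_seq = strrep("T", 20))
  expect_identical(classify_effect(m, "c.-5_-2del")$effect_class,
                   "upstream_noncoding")
  expect_identical(classify_effect(m, "c.2T>A")$effect_class, "start_lost")
  expect_identical(classify_effect(m, parse_hgvs_c("c.-4_5del"))$effect_class,
                   "start_lost")
})

test_that("the 11 tabulated mutation strings classify as published", {
  m <- fixture_t1_cds()
  expect_cls <- function(s, cls) {
    expect_identical(classify_effect(m, s)$effect_class, cls, label = s)
  }
  expect_cls("c.-1954_6926delinsCM000150.2:1390060_1390808", "start_lost")
  expect_cls("c.226_230del", "frameshift")     # 5 nt
  expect_cls("c.1015A>T", "nonsense")          # AAA -> TAA
  expect_cls("c.3033_3040del", "frameshift")   # 8 nt
  expect_cls("c.3508del", "frameshift")        # 1 nt
  expect_cls("c.4227_4459del", "frameshift")   # 233 nt
  expect_cls("c.6833_7077del", "frameshift")   # 245 nt
  expect_cls("c.7137_7143del", "frameshift")   # 7 nt
  mis <- classify_effect(m, "c.4113G>T")       # codon 1371 AAG -> AAT
  expect_identical(mis$effect_class, "missense")
  expect_identical(mis$first_affected_codon, 1371L)
  expect_identical(mis$ref_residues, "K")
  expect_identical(mis$alt_residues, "N")
  inv <- classify_effect(m, "c.6393_6413inv")  # 21 nt, 8 codons
  expect_false(inv$effect_class == "frameshift")
  expect_true(inv$first_affected_codon >= 2131L &&
              inv$first_affected_codon <= 2138L)
})

test_that("name_variant returns the 3'-most single-edit description", {
  m <- cds_model("ATGAAACCCTAA")
  expect_identical(format_hgvs(name_variant(m, "ATGACCCTAA")), "c.5_6del")
  expect_identical(format_hgvs(name_variant(m, "ATGAAAGCCTAA")), "c.7C>G")
  expect_null(name_variant(m, m$cds_seq))
  expect_error(name_variant(m, "TTGAAACCCTAG"), "disjoint")
})

test_that("apply/name round-trips 500 seeded random in-CDS variants", {
  m <- fixture_small_cds()
  set.seed(101)
  for (i in 1:500) {
    v <- random_cds_variant(m)
    mut <- as.character(apply_variant(m, v))
    named <- name_variant(m, mut)
    if (is.null(named)) {
      expect_identical(mut, m$cds_seq)  # edit was a no-op representation
      next
    }
    # the named form reproduces the same mutant sequence...
    expect_identical(as.character(apply_variant(m, named)), mut,
                     label = sprintf("iter %d: %s -> %s", i, format_hgvs(v),
                                     format_hgvs(named)))
    # ...and naming is stable (idempotent normal form)
    renamed <- name_variant(m, as.character(apply_variant(m, named)))
    expect_identical(format_hgvs(renamed), format_hgvs(named))
  }
})

test_that("frameshift law: class is frameshift iff net change mod 3 != 0", {
  m <- fixture_small_cds(seed = 11)
  set.seed(202)
  for (i in 1:200) {
    v <- random_cds_variant(m)
    if (!v$kind %in% c("deletion", "delins", "insertion")) next
    net <- switch(v$kind,
      deletion = -hgvs_span_length(v$start, v$end),
      insertion = v$insert_len,
      delins = v$insert_len - hgvs_span_length(v$start, v$end))
    cls <- classify_effect(m, v)$effect_class
    expect_identical(cls == "frameshift", net %% 3L != 0L,
                     label = format_hgvs(v))
  }
})

test_that("applying the same inversion twice restores the reference", {
  m <- fixture_small_cds(seed = 3)
  set.seed(303)
  for (i in 1:50) {
    s <- sample(4:300, 1L); e <- s + sample(1:20, 1L)
    v <- parse_hgvs_c(sprintf("c.%d_%dinv", s, e))
    once <- as.character(apply_variant(m, v))
    m2 <- m; m2$cds_seq <- once
    expect_identical(as.character(apply_variant(m2, v)), m$cds_seq)
  }
})
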