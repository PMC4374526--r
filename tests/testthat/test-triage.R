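test_that("filter_calls applies strict thresholds and drops heterozygotes", {
  d <- make_records(pos = 1:5,
                    ref = "A", alt = "T",
                    depth = c(4L, 3L, 50L, 10L, 10L),
                    mq = c(21, 99, 60, 20, 50),
                    qual = c(21, 99, 60, 99, 20),
                    gt = c("hom", "hom", "het", "hom", "hom"))
  cs <- filter_calls(callset("s", d))
  # row 1: all strict thresholds exceeded; rows 2-5 each fail exactly one
  expect_identical(cs$records$pos, 1L)
  # strictness: depth == 3 dropped even at perfect qualities
  expect_false(2L %in% cs$records$pos)
  # heterozygous dropped regardless of quality
  expect_false(3L %in% cs$records$pos)
  # keep-het switch
  keep <- filter_calls(callset("s", d),
                       triage_thresholds(drop_heterozygous = FALSE))
  expect_identical(keep$records$pos, c(1L, 3L))
  # idempotence
  expect_identical(filter_calls(cs)$records, cs$records)
  # output is a subset, records unmodified
  expect_true(all(axescreen:::variant_key(cs$records) %in%
                  axescreen:::variant_key(d)))
})

test_that("malformed records are tallied and dropped, run continues", {
  d <- make_records(pos = 1:3, ref = "A", alt = "T",
                    depth = c(10L, NA, 10L))
  expect_warning(cs <- filter_calls(callset("s", d)), "malformed")
  expect_identical(cs$records$pos, c(1L, 3L))
})

test_that("subtract_shared removes exactly the variants common to all", {
  v <- function(pos) make_records(pos = pos, ref = "A", alt = "T")
  sets <- list(
    callset("A", rbind(v(1), v(2))),
    callset("B", v(1)), callset("C", v(1)), callset("D", v(1)))
  out <- subtract_shared(sets)
  expect_identical(out[[1]]$records$pos, 2L)
  for (k in 2:4) expect_identical(nrow(out[[k]]$records), 0L)
  # common to 3 of 4 is retained in those 3
  sets2 <- list(callset("A", v(5)), callset("B", v(5)),
                callset("C", v(5)), callset("D", v(9)))
  out2 <- subtract_shared(sets2)
  expect_identical(vapply(out2, function(cs) nrow(cs$records), 0L),
                   c(1L, 1L, 1L, 1L))
  # ... but removable with require_n = 3
  out3 <- subtract_shared(sets2, require_n = 3)
  expect_identical(vapply(out3, function(cs) nrow(cs$records), 0L),
                   c(0L, 0L, 0L, 1L))
  # empty inputs pass through; single callset rejected
  empty <- lapply(out[[2]], identity)
  out4 <- subtract_shared(list(out[[2]], out[[3]]))
  expect_identical(nrow(out4[[1]]$records), 0L)
  expect_error(subtract_shared(list(sets[[1]])), "at least 2")
  # after subtraction the intersection of all outputs is empty
  keys <- lapply(out2, function(cs) axescreen:::variant_key(cs$records))
  expect_length(Reduce(intersect, keys), 0L)
})

test_that("flag_coding uses interval overlap including anchored deletions", {
  d <- make_records(pos = c(1010L, 500L, 999L, 2000L),
                    ref = c("A", "A", "AAAA", "A"),
                    alt = c("T", "T", "A", "T"),
                    chrom = c("chr1", "chr1", "chr1", "chr9"))
  expect_warning(cs <- flag_coding(callset("s", d), "chr1", 1000L, 1900L),
                 "absent")
  rec <- cs$records
  expect_true(rec[rec$pos == 1010L]$coding)            # SNV inside CDS
  expect_false(rec[rec$pos == 500L]$coding)            # 500 bp upstream
  expect_true(rec[rec$pos == 999L]$coding)             # deletion spans edge
  expect_false(rec[rec$pos == 2000L]$coding)           # other chromosome
})

test_that("multi-allelic lines are split before filtering", {
  d <- make_records(pos = 10L, ref = "A", alt = "T,G")
  cs <- callset("s", d)
  expect_identical(nrow(cs$records), 2L)
  expect_setequal(cs$records$alt, c("T", "G"))
})

test_that("triage recovers exactly the planted privates across seeds", {
  for (seed in 1:10) {
    ref <- make_reference(seed, genome_length = 30000, cds_length = 900,
                          cds_start = 10001)
    cds <- as_cds_model(ref)
    specs <- lapply(c(A = 101L, B = 205L, C = 307L, D = 411L), function(p) {
      rb <- substr(cds$cds_seq, p, p)
      sprintf("c.%d%s>%s", p, rb, setdiff(BASES, rb)[1])
    })
    st <- plant_mutations(ref, specs, n_shared = 10, n_noise = 5, seed = seed)
    res <- triage_strains(lapply(st, `[[`, "callset"), cds_region = ref)
    surv <- data.table::rbindlist(lapply(res$callsets, function(cs)
      data.table::data.table(strain = cs$strain_id, cs$records)))
    tt <- truth_table(st)
    expect_identical(res$report$n_post_subtraction, rep(1L, 4L))
    expect_setequal(paste(surv$strain, surv$pos, surv$ref, surv$alt),
                    paste(tt$strain, tt$pos, tt$ref, tt$alt))
    expect_true(all(surv$coding))
  }
})

test_that("noise-only strains triage to empty call sets", {
  ref <- make_reference(3, genome_length = 20000, cds_length = 300,
                        cds_start = 5001)
  cds <- as_cds_model(ref)
  rb <- substr(cds$cds_seq, 50, 50)
  # one strain still needs a valid spec; give all strains the same private
  # variant so that subtraction removes it too
  spec <- sprintf("c.50%s>%s", rb, setdiff(BASES, rb)[1])
  st <- plant_mutations(ref, list(A = spec, B = spec), n_shared = 0,
                        n_noise = 5, seed = 6)
  res <- triage_strains(lapply(st, `[[`, "callset"))
  expect_identical(res$report$n_post_subtraction, c(0L, 0L))
})
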