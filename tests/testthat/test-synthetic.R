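test_that("make_reference builds a valid seeded genome + CDS", {
  ref <- make_reference(1, genome_length = 10000, cds_length = 300,
                        cds_start = 2001)
  cds <- as_cds_model(ref)
  pep <- sub("\\*$", "", axescreen:::translate_dna(cds$cds_seq))
  expect_identical(nchar(pep), 99L)  # 300/3 - 1 residues + stop
  expect_false(grepl("\\*", pep))
  ref2 <- make_reference(1, genome_length = 10000, cds_length = 300,
                         cds_start = 2001)
  expect_identical(ref$genome, ref2$genome)
  ref3 <- make_reference(2, genome_length = 10000, cds_length = 300,
                         cds_start = 2001)
  expect_false(identical(ref$genome, ref3$genome))
  expect_error(make_reference(1, 10000, 301, 2001), "multiple of 3")
  expect_error(make_reference(1, 1000, 900, 500), "fit")
})

test_that("plant_mutations composes private + shared + noise with truth", {
  ref <- make_reference(5, genome_length = 30000, cds_length = 900,
                        cds_start = 10001)
  cds <- as_cds_model(ref)
  specs <- lapply(c(A = 101L, B = 205L, C = 307L, D = 411L), function(p) {
    rb <- substr(cds$cds_seq, p, p)
    sprintf("c.%d%s>%s", p, rb, setdiff(BASES, rb)[1])
  })
  st <- plant_mutations(ref, specs, n_shared = 10, n_noise = 5, seed = 2)
  expect_named(st, c("A", "B", "C", "D"))
  # shared records identical in every strain
  for (s in st[-1])
    expect_identical(s$shared, st[[1]]$shared)
  # every noise record fails at least one threshold
  for (s in st) {
    nz <- s$noise
    fails <- nz$depth <= 3 | nz$mq <= 20 | nz$qual <= 20 | nz$gt == "het"
    expect_true(all(fails))
    expect_identical(nrow(s$callset$records), 1L + 10L + 5L)
  }
  # each private mutation appears in exactly one strain
  tt <- truth_table(st)
  expect_identical(nrow(tt), 4L)
  expect_identical(anyDuplicated(tt$pos), 0L)
  expect_error(plant_mutations(ref, list(), seed = 1), "non-empty")
  expect_error(plant_mutations(ref, list(A = character(0)), seed = 1),
               "empty variant spec")
  expect_error(plant_mutations(ref, list(A = "c.99999A>T"), seed = 1))
})

test_that("simulate_depth draws Poisson coverage with 2x duplications", {
  n <- 1e6
  tr <- simulate_depth(n, mean_depth = 20, seed = 9)
  # CLT 3-sigma band: 20 +- 3 * sqrt(20 / n)
  expect_lt(abs(mean(tr$depths) - 20), 3 * sqrt(20 / n))
  # Poisson: variance ~ mean
  expect_lt(abs(var(tr$depths) / mean(tr$depths) - 1), 0.02)
  tr2 <- simulate_depth(1e5, list(c(1L, 100000L)), mean_depth = 20, seed = 9)
  expect_lt(abs(mean(tr2$depths) - 40), 3 * sqrt(40 / 1e5))
  expect_identical(simulate_depth(1000, seed = 4)$depths,
                   simulate_depth(1000, seed = 4)$depths)
  expect_error(simulate_depth(1000, mean_depth = 0, seed = 1), "> 0")
  expect_error(simulate_depth(1000, list(c(10L, 50L), c(40L, 80L)), seed = 1),
               "overlap")
  expect_error(simulate_depth(1000, list(c(10L, 2000L)), seed = 1), "within")
})

test_that("depth mean and variance differ by factor 2 inside duplications", {
  dup <- c(200001L, 500000L)
  tr <- simulate_depth(1e6, list(dup), mean_depth = 20, seed = 31)
  inside <- tr$depths[dup[1]:dup[2]]
  outside <- tr$depths[-(dup[1]:dup[2])]
  n_in <- length(inside); n_out <- length(outside)
  expect_lt(abs(mean(inside) / mean(outside) - 2),
            3 * sqrt(40 / n_in + 4 * 20 / n_out) / 20)
  expect_lt(abs(var(inside) / var(outside) - 2), 0.1)
})

test_that("mutate_protein hits the expected substitution count", {
  p <- random_protein(500, seed = 1)
  expect_identical(mutate_protein(p, 0, 0, seed = 2), p)
  full <- mutate_protein(p, 1, 0, seed = 3)
  expect_identical(nchar(full), nchar(p))
  expect_false(any(strsplit(full, "")[[1]] == strsplit(p, "")[[1]]))
  q <- random_protein(1000, seed = 4)
  counts <- vapply(1:100, function(s) {
    m <- mutate_protein(q, 0.1, 0, seed = s)
    sum(strsplit(m, "")[[1]] != strsplit(q, "")[[1]])
  }, 0)
  expect_lt(abs(mean(counts) - 100), 10)  # binomial CI on the mean
  expect_error(mutate_protein("", 0.1), "non-empty")
  expect_error(mutate_protein(q, 1.5), "\\[0, 1\\]")
})

test_that("render_cells plants a recoverable membrane patch arc", {
  sp0 <- synthetic_image_spec(patch_fraction = 0, seed = 5)
  cell0 <- render_cells(sp0)
  ring <- cell0$image[cbind(cell0$outline[, "y"], cell0$outline[, "x"])]
  expect_true(all(ring == round(sp0$membrane_mean)))
  sp1 <- synthetic_image_spec(patch_fraction = 1, seed = 5)
  cell1 <- render_cells(sp1)
  ring1 <- cell1$image[cbind(cell1$outline[, "y"], cell1$outline[, "x"])]
  expect_true(all(ring1 == round(sp1$membrane_mean + sp1$patch_gain)))
  # determinism
  expect_identical(render_cells(sp1)$image, cell1$image)
  # outline is counter-clockwise by the shoelace sign
  o <- cell0$outline
  x <- o[, 1]; y <- o[, 2]
  expect_gt(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y), 0)
  expect_error(synthetic_image_spec(patch_fraction = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_image_spec(rx = 200), "fit")
})

test_that("planted patch fraction is recovered end to end", {
  sp <- synthetic_image_spec(patch_fraction = 0.25, patch_gain = 100,
                             seed = 17)
  cell <- render_cells(sp)
  pr <- quantify_patches(cell$image, cell$outline)
  expect_lt(abs(pr$patch_fraction - 0.25), 0.05)
})

test_that("generator substreams are independent of one another", {
  # drawing a depth track between two cell renders must not change them
  a <- render_cells(synthetic_image_spec(seed = 8))
  invisible(simulate_depth(1000, seed = 8))
  b <- render_cells(synthetic_image_spec(seed = 8))
  expect_identical(a$image, b$image)
})
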