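#' Generate a haploid reference genome with one embedded CDS
#'
#' The genome emulates an AT-rich amoebal chromosome (A/T at 38.8% each,
#' matching the ~77.6% AT content of the *D. discoideum* nuclear genome);
#' the CDS is assembled from sense codons only, starts `ATG` and ends with a
#' stop codon drawn by base composition (so usually `TAA`).
#'
#' @param seed integer seed; generation is deterministic per seed.
#' @param genome_length total genome length in nt.
#' @param cds_length CDS length in nt; must be a multiple of 3 and >= 9.
#' @param cds_start 1-based genomic position of CDS base 1.
#' @param chrom chromosome label.
#' @return A `reference_bundle`: list(genome, chrom, cds_start, cds_length,
#'   upstream_len).
#' @export
make_reference <- function(seed, genome_length = 100000L, cds_length = 1500L,
                           cds_start = 20001L, chrom = "chr1") {
  genome_length <- as.integer(genome_length)
  cds_length <- as.integer(cds_length); cds_start <- as.integer(cds_start)
  if (cds_length %% 3L != 0L)
    abort2("cds_length %d is not a multiple of 3", cds_length)
  if (cds_length < 9L) abort2("cds_length must be >= 9 (start + codon + stop)")
  if (cds_start < 1L || cds_start + cds_length - 1L > genome_length)
    abort2("CDS [%d, %d] does not fit in genome of length %d",
           cds_start, cds_start + cds_length - 1L, genome_length)
  set.seed(substream_seed(seed, "reference"))
  base_p <- c(A = 0.388, C = 0.112, G = 0.112, T = 0.388)
  genome <- sample(names(base_p), genome_length, replace = TRUE, prob = base_p)

  codons <- apply(expand.grid(names(base_p), names(base_p), names(base_p),
                              stringsAsFactors = FALSE), 1L, paste0,
                  collapse = "")
  w <- apply(expand.grid(base_p, base_p, base_p), 1L, prod)
  stops <- c("TAA", "TAG", "TGA")
  sense <- !(codons %in% stops)
  n_mid <- cds_length %/% 3L - 2L
  mid <- sample(codons[sense], n_mid, replace = TRUE, prob = w[sense])
  stop_codon <- sample(stops, 1L, prob = w[codons %in% stops])
  cds <- paste0("ATG", paste(mid, collapse = ""), stop_codon)
  idx <- cds_start:(cds_start + cds_length - 1L)
  genome[idx] <- strsplit(cds, "")[[1]]
  structure(list(genome = paste(genome, collapse = ""), chrom = chrom,
                 cds_start = cds_start, cds_length = cds_length,
                 upstream_len = cds_start - 1L),
            class = "reference_bundle")
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat(sprintf("<reference_bundle> %s: %d nt, CDS at %d..%d\n", x$chrom,
              nchar(x$genome), x$cds_start, x$cds_start + x$cds_length - 1L))
  invisible(x)
}

#' Extract the `cds_model` of a reference bundle
#' @param ref a `reference_bundle`.
#' @param upstream_len how much upstream sequence to carry (default: all).
#' @return A [cds_model()].
#' @export
as_cds_model <- function(ref, upstream_len = ref$upstream_len) {
  stopifnot(inherits(ref, "reference_bundle"))
  cds_end <- ref$cds_start + ref$cds_length - 1L
  cds_model(substr(ref$genome, ref$cds_start, cds_end),
            substr(ref$genome, ref$cds_start - upstream_len,
                   ref$cds_start - 1L),
            id = paste0(ref$chrom, ":", ref$cds_start, "-", cds_end))
}

ref_base_at <- function(ref, pos, len = 1L) substr(ref$genome, pos, pos + len - 1L)

#' Plant mutations into synthetic strains
#'
#' Builds one call set per strain from three components with known truth:
#' (i) the strain's private mutations, supplied as HGVS c. descriptions
#' converted to genomic VCF-style records with qualities above every filter
#' threshold; (ii) `n_shared` parental SNVs identical across all strains
#' (also above-threshold, so only common-variant subtraction can remove
#' them); (iii) `n_noise` per-strain artefact records, each failing at least
#' one quality threshold (sub-threshold depth, mapping quality or call
#' quality, or a heterozygous genotype).
#'
#' @param ref a [make_reference()] bundle.
#' @param specs named list: strain id -> character vector of HGVS c. strings
#'   (or list of `hgvs_variant`); every spec must apply cleanly to the CDS /
#'   upstream span.
#' @param n_shared,n_noise counts of shared parental and noise records.
#' @param seed integer seed.
#' @return List of `strain_truth` objects, each with `$strain_id`,
#'   `$private`, `$shared`, `$noise` (data.tables of records) and `$callset`
#'   (a [callset()] merging all three, position-sorted).
#' @export
plant_mutations <- function(ref, specs, n_shared = 10L, n_noise = 5L, seed = 1L) {
  stopifnot(inherits(ref, "reference_bundle"))
  if (!is.list(specs) || length(specs) == 0L || is.null(names(specs)))
    abort2("specs must be a non-empty named list (strain id -> variants)")
  set.seed(substream_seed(seed, "plant"))
  glen <- nchar(ref$genome)
  cdsm <- as_cds_model(ref)

  private <- lapply(names(specs), function(sid) {
    vs <- specs[[sid]]
    if (length(vs) == 0L) abort2("strain %s has an empty variant spec", sid)
    recs <- lapply(vs, function(v) {
      if (is.character(v)) v <- parse_hgvs_c(v)
      apply_variant(cdsm, v)   # validates span + reference bases
      hgvs_to_genomic_record(ref, v)
    })
    data.table::rbindlist(recs)
  })
  names(private) <- names(specs)
  taken <- unique(unlist(lapply(private, function(d) d$pos)))

  pool <- setdiff(seq_len(glen - 1L)[-1L], taken)
  shared_pos <- sort(sample(pool, n_shared))
  shared <- snv_records(ref, shared_pos, depth = 8:30, mq = c(40, 60),
                        qual = c(50, 200), gt = "hom")

  strains <- lapply(names(specs), function(sid) {
    noise_pos <- sample(setdiff(pool, shared_pos), n_noise)
    noise <- snv_records(ref, sort(noise_pos), depth = 8:30, mq = c(40, 60),
                         qual = c(50, 200), gt = "hom")
    if (n_noise > 0L) {
      mode <- sample(c("depth", "mq", "qual", "het"), n_noise, replace = TRUE)
      noise[mode == "depth", "depth"] <- sample(0:3, sum(mode == "depth"), TRUE)
      noise[mode == "mq", "mq"] <- runif(sum(mode == "mq"), 0, 20)
      noise[mode == "qual", "qual"] <- runif(sum(mode == "qual"), 0, 20)
      noise[mode == "het", "gt"] <- "het"
    }
    all <- data.table::rbindlist(list(private[[sid]], shared, noise))
    structure(list(strain_id = sid, private = private[[sid]],
                   shared = shared, noise = noise,
                   callset = callset(sid, all)),
              class = "strain_truth")
  })
  names(strains) <- names(specs)
  strains
}

# genomic VCF-style (anchored-indel) record for a c. variant
hgvs_to_genomic_record <- function(ref, v) {
  up <- ref$upstream_len
  gpos <- function(p) ref$cds_start - 1L + (if (p > 0L) p else p + 1L)
  i <- gpos(v$start); j <- gpos(v$end)
  rec <- switch(v$kind,
    substitution = list(pos = i, ref = ref_base_at(ref, i),
                        alt = v$alt),
    deletion = list(pos = i - 1L, ref = ref_base_at(ref, i - 1L, j - i + 2L),
                    alt = ref_base_at(ref, i - 1L)),
    insertion = list(pos = i, ref = ref_base_at(ref, i),
                     alt = paste0(ref_base_at(ref, i), v$alt)),
    delins = list(pos = i, ref = ref_base_at(ref, i, j - i + 1L),
                  alt = if (!is.na(v$insert_ext)) strrep("N", v$insert_len)
                        else v$alt),
    inversion = list(pos = i, ref = ref_base_at(ref, i, j - i + 1L),
                     alt = revcomp_dna(ref_base_at(ref, i, j - i + 1L))))
  data.table::data.table(chrom = ref$chrom, pos = rec$pos, id = ".",
                         ref = rec$ref, alt = rec$alt,
                         qual = round(runif(1L, 100, 220), 1),
                         depth = sample(10:30, 1L),
                         mq = round(runif(1L, 45, 60), 1), gt = "hom")
}

snv_records <- function(ref, pos, depth, mq, qual, gt) {
  n <- length(pos)
  if (n == 0L)
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  id = character(), ref = character(),
                                  alt = character(), qual = numeric(),
                                  depth = integer(), mq = numeric(),
                                  gt = character()))
  rb <- vapply(pos, function(p) ref_base_at(ref, p), "")
  ab <- vapply(rb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  data.table::data.table(chrom = ref$chrom, pos = as.integer(pos), id = ".",
                         ref = rb, alt = unname(ab),
                         qual = round(runif(n, qual[1], qual[2]), 1),
                         depth = sample(depth, n, replace = TRUE),
                         mq = round(runif(n, mq[1], mq[2]), 1), gt = gt)
}

#' Truth table of planted private mutations
#' @param strains output of [plant_mutations()].
#' @return data.table: strain, chrom, pos, ref, alt.
#' @export
truth_table <- function(strains) {
  data.table::rbindlist(lapply(strains, function(s)
    data.table::data.table(strain = s$strain_id,
                           s$private[, c("chrom", "pos", "ref", "alt")])))
}

#' Simulate a per-position read-depth track
#'
#' Depth at every position is drawn independently from a Poisson distribution
#' with mean `mean_depth` outside planted duplications and `2 * mean_depth`
#' inside them, emulating single-copy shotgun coverage of roughly 17-20x with
#' optional tandem duplications. An optional negative-binomial switch
#' (`dispersion = size`) adds overdispersion.
#'
#' @param ref a `reference_bundle`, or an integer genome length.
#' @param duplications list of `c(start, end)` 1-based inclusive intervals;
#'   must lie within the genome and not overlap.
#' @param mean_depth single-copy mean coverage (> 0).
#' @param seed integer seed.
#' @param dispersion `NULL` for Poisson, else the negative-binomial `size`.
#' @param chrom label when `ref` is a bare length.
#' @return A `depth_track`: list(chrom, depths) with `depths[i]` the depth at
#'   position `i`.
#' @export
simulate_depth <- function(ref, duplications = list(), mean_depth = 20,
                           seed = 1L, dispersion = NULL, chrom = "chr1") {
  n <- if (inherits(ref, "reference_bundle")) nchar(ref$genome)
       else as.integer(ref)
  if (inherits(ref, "reference_bundle")) chrom <- ref$chrom
  if (!is.finite(mean_depth) || mean_depth <= 0)
    abort2("mean_depth must be > 0 (got %s)", format(mean_depth))
  if (length(duplications)) {
    iv <- do.call(rbind, lapply(duplications, as.integer))
    if (any(iv[, 1L] < 1L) || any(iv[, 2L] > n) || any(iv[, 1L] > iv[, 2L]))
      abort2("duplication intervals must lie within 1..%d", n)
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (nrow(iv) > 1L && any(iv[-1L, 1L] <= iv[-nrow(iv), 2L]))
      abort2("duplication intervals overlap")
  }
  set.seed(substream_seed(seed, "depth"))
  lambda <- rep(mean_depth, n)
  for (d in duplications) lambda[d[1L]:d[2L]] <- 2 * mean_depth
  depths <- if (is.null(dispersion)) rpois(n, lambda)
            else rnbinom(n, size = dispersion, mu = lambda)
  depth_track(chrom, depths)
}

#' Construct a depth track
#' @param chrom chromosome label.
#' @param depths non-negative integer vector, position 1..length.
#' @return A `depth_track` object.
#' @export
depth_track <- function(chrom, depths) {
  depths <- as.integer(depths)
  if (any(depths < 0L, na.rm = TRUE)) abort2("depths must be >= 0")
  structure(list(chrom = chrom, depths = depths), class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("<depth_track> %s: %d positions, mean %.2f\n", x$chrom,
              length(x$depths), mean(x$depths)))
  invisible(x)
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Mutate a protein sequence site-wise
#'
#' Each site is substituted with probability `sub_rate` (to one of the other
#' 19 residues, uniformly) and hit by an indel event with probability
#' `indel_rate` (deletion of the site or insertion of one random residue
#' after it, equiprobable). Used to fabricate diverged homologue pairs with
#' a known divergence for the homology profiler.
#'
#' @param protein non-empty residue string over the 20-letter alphabet.
#' @param sub_rate,indel_rate per-site probabilities in `[0, 1]`.
#' @param seed integer seed.
#' @return Mutated residue string.
#' @export
mutate_protein <- function(protein, sub_rate, indel_rate = 0, seed = 1L) {
  if (!is.character(protein) || length(protein) != 1L || !nzchar(protein))
    abort2("protein must be a non-empty residue string")
  if (sub_rate < 0 || sub_rate > 1 || indel_rate < 0 || indel_rate > 1)
    abort2("rates must lie in [0, 1]")
  set.seed(substream_seed(seed, "protein"))
  res <- strsplit(protein, "")[[1]]
  n <- length(res)
  sub_hit <- runif(n) < sub_rate
  res[sub_hit] <- vapply(res[sub_hit],
                         function(a) sample(setdiff(AA20, a), 1L), "")
  if (indel_rate > 0) {
    ind_hit <- runif(n) < indel_rate
    is_del <- runif(n) < 0.5
    out <- vector("list", n)
    for (i in seq_len(n)) {
      out[[i]] <- if (!ind_hit[i]) res[i]
        else if (is_del[i]) character(0)
        else c(res[i], sample(AA20, 1L))
    }
    res <- unlist(out)
  }
  paste(res, collapse = "")
}

#' Specification for a synthetic cell image
#'
#' @param image_size square image side in pixels.
#' @param cx,cy,rx,ry ellipse centre and semi-axes (pixels); the cell must
#'   fit inside the image.
#' @param cytosol_mean,cytosol_sd interior intensity Normal parameters
#'   (truncated at 0, then rounded to integer grey levels).
#' @param membrane_mean intensity of the 1-px membrane ring.
#' @param patch_fraction fraction of the perimeter covered by one contiguous
#'   bright patch, in `[0, 1]`.
#' @param patch_gain intensity added inside the patch (>= 0).
#' @param background mean intensity outside the cell.
#' @param seed integer seed.
#' @return A `synthetic_image_spec` list.
#' @export
synthetic_image_spec <- function(image_size = 192L, cx = 96, cy = 96,
                                 rx = 60, ry = 45, cytosol_mean = 100,
                                 cytosol_sd = 10, membrane_mean = 100,
                                 patch_fraction = 0, patch_gain = 100,
                                 background = 5, seed = 1L) {
  if (patch_fraction < 0 || patch_fraction > 1)
    abort2("patch_fraction must lie in [0, 1]")
  if (patch_gain < 0) abort2("patch_gain must be >= 0")
  if (min(cytosol_mean, membrane_mean, background) < 0)
    abort2("intensities must be >= 0")
  if (cx - rx < 2 || cx + rx > image_size - 1 ||
      cy - ry < 2 || cy + ry > image_size - 1)
    abort2("cell ellipse does not fit within the %dx%d image",
           image_size, image_size)
  structure(as.list(environment()), class = "synthetic_image_spec")
}

#' Render a synthetic cell image with a planted membrane patch
#'
#' Produces a 2-D integer intensity grid: cytosol pixels ~ round(truncated
#' Normal(cytosol_mean, cytosol_sd)), a 1-px elliptical membrane ring at
#' `membrane_mean`, and one contiguous perimeter arc covering
#' `patch_fraction` of the ring raised by `patch_gain`. The outline polygon
#' is the ordered ring pixel trace (counter-clockwise by the shoelace sign on
#' raw x/y coordinates; with the image y-axis pointing down this renders
#' visually clockwise).
#'
#' @param spec a [synthetic_image_spec()].
#' @return list(image = integer matrix `[y, x]`, outline = n x 2 matrix of
#'   (x, y) pixel coordinates, truth = list(patch_fraction, patch_index)).
#' @export
render_cells <- function(spec) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  set.seed(substream_seed(spec$seed, "cells"))
  n <- spec$image_size
  img <- matrix(pmax(0, round(rnorm(n * n, spec$background, 1))), n, n)

  # ordered 1-px ring trace of the ellipse
  tt <- seq(0, 2 * pi, length.out = ceiling(8 * pi * max(spec$rx, spec$ry)))
  px <- round(spec$cx + spec$rx * cos(tt))
  py <- round(spec$cy + spec$ry * sin(tt))
  keep <- c(TRUE, diff(px) != 0 | diff(py) != 0)
  px <- px[keep]; py <- py[keep]
  if (px[1L] == px[length(px)] && py[1L] == py[length(py)]) {
    px <- px[-length(px)]; py <- py[-length(py)]
  }
  # enforce positive shoelace area (declared counter-clockwise orientation)
  area2 <- sum(px * c(py[-1L], py[1L]) - c(px[-1L], px[1L]) * py)
  if (area2 < 0) { px <- rev(px); py <- rev(py) }

  xg <- matrix(rep(seq_len(n), each = n), n, n)   # [y, x]: col index = x
  yg <- matrix(rep(seq_len(n), times = n), n, n)
  inside <- ((xg - spec$cx) / spec$rx)^2 + ((yg - spec$cy) / spec$ry)^2 < 1
  n_in <- sum(inside)
  img[inside] <- pmax(0, round(rnorm(n_in, spec$cytosol_mean,
                                     spec$cytosol_sd)))
  ring_idx <- cbind(py, px)   # matrix[y, x]
  img[ring_idx] <- round(spec$membrane_mean)

  n_ring <- length(px)
  n_patch <- round(spec$patch_fraction * n_ring)
  patch_start <- if (n_patch > 0L) sample.int(n_ring, 1L) else NA_integer_
  if (n_patch > 0L) {
    sel <- ((patch_start - 1L + seq_len(n_patch) - 1L) %% n_ring) + 1L
    img[ring_idx[sel, , drop = FALSE]] <-
      round(spec$membrane_mean + spec$patch_gain)
  }
  list(image = img, outline = cbind(x = px, y = py),
       truth = list(patch_fraction = spec$patch_fraction,
                    patch_index = patch_start))
}
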