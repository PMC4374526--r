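#' Per-strain variant call set
#'
#' A light container for one strain's called variants. Records are kept
#' sorted by (chrom, pos) and must be unique on (chrom, pos, ref, alt).
#' Multi-allelic records (comma-separated `alt`) are split into one record
#' per alternate allele on construction.
#'
#' @param strain_id strain label.
#' @param records data.frame/data.table with columns `chrom`, `pos`, `ref`,
#'   `alt`, `qual`, `depth`, `mq`, `gt` (genotype class, `"hom"`/`"het"`);
#'   `id` optional.
#' @return A `callset` object.
#' @export
callset <- function(strain_id, records) {
  d <- data.table::as.data.table(records)
  need <- c("chrom", "pos", "ref", "alt", "qual", "depth", "mq", "gt")
  miss <- setdiff(need, names(d))
  if (length(miss)) abort2("callset records lack columns: %s",
                           paste(miss, collapse = ", "))
  if (!"id" %in% names(d)) d$id <- "."
  if (nrow(d) && any(grepl(",", d$alt, fixed = TRUE))) {
    d <- data.table::rbindlist(lapply(seq_len(nrow(d)), function(i) {
      alts <- strsplit(d$alt[i], ",", fixed = TRUE)[[1L]]
      r <- d[rep(i, length(alts))]
      r$alt <- alts
      r
    }))
  }
  d <- d[order(chrom, pos, ref, alt)]
  if (anyDuplicated(d[, c("chrom", "pos", "ref", "alt")]))
    abort2("duplicate (chrom, pos, ref, alt) records in strain %s", strain_id)
  structure(list(strain_id = strain_id, records = d), class = "callset")
}

#' @export
print.callset <- function(x, ...) {
  cat(sprintf("<callset> %s: %d records\n", x$strain_id, nrow(x$records)))
  invisible(x)
}

variant_key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")

#' Triage quality thresholds
#'
#' Defaults reproduce the screen's pre-filter: depth strictly greater than 3,
#' mapping quality strictly greater than 20, call (SNP) quality strictly
#' greater than 20, and heterozygous calls excluded (read, in a haploid
#' organism, as mixed-allele alignment artefacts).
#'
#' @param min_depth_exclusive,min_mq_exclusive,min_qual_exclusive strict
#'   lower bounds.
#' @param drop_heterozygous drop any record whose genotype class is not a
#'   single homozygous ALT.
#' @return A `triage_thresholds` list.
#' @export
triage_thresholds <- function(min_depth_exclusive = 3L,
                              min_mq_exclusive = 20,
                              min_qual_exclusive = 20,
                              drop_heterozygous = TRUE) {
  if (min(min_depth_exclusive, min_mq_exclusive, min_qual_exclusive) < 0)
    abort2("thresholds must be >= 0")
  structure(list(min_depth_exclusive = min_depth_exclusive,
                 min_mq_exclusive = min_mq_exclusive,
                 min_qual_exclusive = min_qual_exclusive,
                 drop_heterozygous = drop_heterozygous),
            class = "triage_thresholds")
}

#' Pre-filter a call set on quality thresholds
#'
#' A record is retained iff `depth > min_depth` AND `mq > min_mq` AND
#' `qual > min_qual` AND (homozygous, when `drop_heterozygous`). All
#' inequalities are strict. Records with missing quality fields are counted,
#' reported in one warning with their row context, and dropped; the run
#' continues. Idempotent; never modifies a record.
#'
#' @param calls a [callset()].
#' @param thresholds a [triage_thresholds()].
#' @return The filtered `callset` (order preserved).
#' @export
filter_calls <- function(calls, thresholds = triage_thresholds()) {
  stopifnot(inherits(calls, "callset"))
  d <- calls$records
  bad <- !stats::complete.cases(d[, c("depth", "mq", "qual", "gt")])
  if (any(bad)) {
    warning(sprintf("%d malformed record(s) dropped in strain %s (rows %s)",
                    sum(bad), calls$strain_id,
                    paste(utils::head(which(bad), 5L), collapse = ", ")),
            call. = FALSE)
    d <- d[!bad]
  }
  keep <- d$depth > thresholds$min_depth_exclusive &
    d$mq > thresholds$min_mq_exclusive &
    d$qual > thresholds$min_qual_exclusive
  if (thresholds$drop_heterozygous) keep <- keep & d$gt == "hom"
  out <- calls
  out$records <- d[keep]
  out
}

#' Subtract variants common to all strains
#'
#' A variant, keyed by exact (chrom, pos, ref, alt), is removed from every
#' call set iff it is present in at least `require_n` of them (default: all,
#' the parental-background rule). All other records pass through unchanged.
#' Unmatched indel representations at identical positions are reported via
#' the `"position_collisions"` attribute so near-duplicate indels can be
#' reviewed by hand (no normalisation is attempted).
#'
#' @param callsets list of >= 2 filtered [callset()] objects.
#' @param require_n minimum number of strains sharing a key for removal.
#' @return List of subtracted `callset` objects (same order).
#' @export
subtract_shared <- function(callsets, require_n = length(callsets)) {
  if (!is.list(callsets) || length(callsets) < 2L)
    abort2("subtraction requires at least 2 call sets")
  stopifnot(all(vapply(callsets, inherits, TRUE, "callset")))
  keys <- lapply(callsets, function(cs) unique(variant_key(cs$records)))
  tab <- table(unlist(keys))
  common <- names(tab)[tab >= require_n]
  out <- lapply(callsets, function(cs) {
    cs$records <- cs$records[!variant_key(cs$records) %in% common]
    cs
  })
  # indels at identical positions with different representations
  poskey <- lapply(out, function(cs) {
    d <- cs$records[nchar(cs$records$ref) != nchar(cs$records$alt)]
    unique(paste(d$chrom, d$pos))
  })
  ptab <- table(unlist(poskey))
  attr(out, "position_collisions") <- names(ptab)[ptab >= 2L]
  out
}

#' Flag records that alter coding sequence
#'
#' A record is flagged coding iff the genomic interval it alters overlaps
#' the CDS interval: one base for a substitution, `[pos, pos + nchar(ref) -
#' 1]` for anchored indel/MNV representations. Records on other chromosomes
#' are flagged non-coding with one warning.
#'
#' @param calls a [callset()].
#' @param cds_chrom,cds_start,cds_end the CDS genomic interval, or pass a
#'   `reference_bundle` as `cds_chrom`.
#' @return The `callset` with an added logical `coding` column.
#' @export
flag_coding <- function(calls, cds_chrom, cds_start = NULL, cds_end = NULL) {
  stopifnot(inherits(calls, "callset"))
  if (inherits(cds_chrom, "reference_bundle")) {
    ref <- cds_chrom
    cds_start <- ref$cds_start
    cds_end <- ref$cds_start + ref$cds_length - 1L
    cds_chrom <- ref$chrom
  }
  d <- calls$records
  vstart <- d$pos
  vend <- d$pos + pmax(nchar(d$ref), 1L) - 1L
  on_chrom <- d$chrom == cds_chrom
  if (nrow(d) && !all(on_chrom))
    warning(sprintf("%d record(s) on chromosomes absent from the CDS model; flagged non-coding",
                    sum(!on_chrom)), call. = FALSE)
  d$coding <- on_chrom & vstart <= cds_end & vend >= cds_start
  calls$records <- d
  calls
}

#' Run the full triage on a set of strains
#'
#' filter -> subtract-common -> flag-coding, with a per-strain report.
#'
#' @param callsets list of [callset()] objects (>= 2).
#' @param thresholds a [triage_thresholds()].
#' @param cds_region optional `reference_bundle` or
#'   `list(chrom, start, end)` for coding flags.
#' @param require_n see [subtract_shared()].
#' @return list(callsets = triaged callsets, report = data.table with
#'   columns strain, n_input, n_post_filter, n_post_subtraction, n_coding).
#' @export
triage_strains <- function(callsets, thresholds = triage_thresholds(),
                           cds_region = NULL, require_n = length(callsets)) {
  n_input <- vapply(callsets, function(cs) nrow(cs$records), 0L)
  filtered <- lapply(callsets, filter_calls, thresholds = thresholds)
  n_filt <- vapply(filtered, function(cs) nrow(cs$records), 0L)
  sub <- subtract_shared(filtered, require_n = require_n)
  n_sub <- vapply(sub, function(cs) nrow(cs$records), 0L)
  n_coding <- rep(NA_integer_, length(sub))
  if (!is.null(cds_region)) {
    sub <- lapply(sub, function(cs) {
      if (inherits(cds_region, "reference_bundle"))
        flag_coding(cs, cds_region)
      else flag_coding(cs, cds_region$chrom, cds_region$start, cds_region$end)
    })
    n_coding <- vapply(sub, function(cs) sum(cs$records$coding), 0L)
  }
  report <- data.table::data.table(
    strain = vapply(callsets, function(cs) cs$strain_id, ""),
    n_input = n_input, n_post_filter = n_filt,
    n_post_subtraction = n_sub, n_coding = n_coding)
  list(callsets = sub, report = report)
}
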