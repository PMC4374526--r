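#' Read / write FASTA
#'
#' Thin wrappers over Biostrings that move between plain named character
#' vectors (the package's working representation) and FASTA files.
#'
#' @param path file path.
#' @param type `"dna"` or `"protein"` (read only).
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  x <- if (type == "dna") Biostrings::readDNAStringSet(path)
       else Biostrings::readAAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

VCF_HEADER <- c(
  "##fileformat=VCFv4.2",
  "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
  "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")

#' Write a call set as a minimal VCF v4.2
#'
#' Emits the fixed-field subset the pipeline consumes: CHROM POS ID REF ALT
#' QUAL FILTER INFO(DP, MQ) FORMAT(GT) plus one sample column named after
#' the strain. Genotype class `"hom"` is written `1/1`, `"het"` `0/1`.
#'
#' @param cs a [callset()].
#' @param path output path.
#' @export
write_vcf <- function(cs, path) {
  stopifnot(inherits(cs, "callset"))
  d <- cs$records
  lines <- c(VCF_HEADER,
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           cs$strain_id))
  if (nrow(d))
    lines <- c(lines, sprintf("%s\t%d\t%s\t%s\t%s\t%s\tPASS\tDP=%d;MQ=%s\tGT\t%s",
      d$chrom, d$pos, d$id, d$ref, d$alt, format(d$qual, trim = TRUE),
      d$depth, format(d$mq, trim = TRUE),
      ifelse(d$gt == "hom", "1/1", "0/1")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a minimal VCF v4.2 into a call set
#'
#' Parses the subset of fields the triage uses (DP and MQ from INFO, GT from
#' the first sample column). Any genotype other than a single homozygous ALT
#' (`1/1` or `1`) is classed heterozygous. Multi-allelic lines are split by
#' [callset()].
#'
#' @param path VCF path.
#' @param strain_id strain label; default: the sample column name, or the
#'   file name.
#' @return A [callset()].
#' @export
read_vcf <- function(path, strain_id = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) abort2("no #CHROM header line in %s", path)
  cols <- strsplit(lines[hdr[1L]], "\t")[[1]]
  if (is.null(strain_id))
    strain_id <- if (length(cols) >= 10L) cols[10L] else
      sub("\\.vcf$", "", basename(path))
  body <- lines[-seq_len(hdr[1L])]
  body <- body[nzchar(body)]
  if (!length(body))
    return(callset(strain_id, data.table::data.table(
      chrom = character(), pos = integer(), id = character(),
      ref = character(), alt = character(), qual = numeric(),
      depth = integer(), mq = numeric(), gt = character())))
  f <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  info_get <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
    vapply(m, function(g) if (length(g) == 2L) g[2] else NA_character_, "")
  }
  gt_raw <- if (length(f) >= 10L)
    vapply(strsplit(f[[10L]], ":", fixed = TRUE), `[`, "", 1L) else "1/1"
  callset(strain_id, data.table::data.table(
    chrom = f[[1L]], pos = as.integer(f[[2L]]), id = f[[3L]],
    ref = f[[4L]], alt = f[[5L]],
    qual = suppressWarnings(as.numeric(f[[6L]])),
    depth = as.integer(info_get(f[[8L]], "DP")),
    mq = as.numeric(info_get(f[[8L]], "MQ")),
    gt = ifelse(gt_raw %in% c("1/1", "1|1", "1"), "hom", "het")))
}

#' Read / write 3-column depth tracks
#'
#' Tab-separated `chrom  pos  depth` with one contiguous 1-based position
#' run per chromosome.
#'
#' @param track a [depth_track()].
#' @param path file path.
#' @export
write_depth_tsv <- function(track, path) {
  data.table::fwrite(data.table::data.table(
    chrom = track$chrom, pos = seq_along(track$depths),
    depth = track$depths), path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_tsv
#' @param chrom read only this chromosome (default: the first present).
#' @export
read_depth_tsv <- function(path, chrom = NULL) {
  d <- data.table::fread(path, sep = "\t",
                         col.names = c("chrom", "pos", "depth"))
  if (is.null(chrom)) chrom <- d$chrom[1L]
  d <- d[d$chrom == chrom]
  d <- d[order(d$pos)]
  if (nrow(d) && !identical(d$pos, seq_len(nrow(d))))
    abort2("depth track for %s is not contiguous from position 1", chrom)
  depth_track(chrom, d$depth)
}

#' Read / write images as plain-text intensity grids
#'
#' Portable text stand-in for 16-bit grayscale rasters: one tab-separated
#' row of integers per pixel row, `[y, x]` orientation, origin top-left.
#'
#' @param image integer matrix.
#' @param path file path.
#' @export
write_image_tsv <- function(image, path) {
  data.table::fwrite(data.table::as.data.table(image), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_image_tsv
#' @export
read_image_tsv <- function(path) {
  as.matrix(data.table::fread(path, sep = "\t", header = FALSE))
}

#' Read / write cell outlines as JSON vertex lists
#'
#' JSON array of `[x, y]` pixel-coordinate pairs, origin top-left, x
#' rightward, y downward.
#'
#' @param outline n x 2 matrix of (x, y) vertices.
#' @param path file path.
#' @export
write_outline_json <- function(outline, path) {
  outline <- as.matrix(outline)
  jsonlite::write_json(lapply(seq_len(nrow(outline)), function(i)
    unname(outline[i, ])), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_outline_json
#' @export
read_outline_json <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- if (is.list(v)) do.call(rbind, v) else as.matrix(v)
  colnames(m) <- c("x", "y")
  m
}

write_tsv <- function(d, path) {
  data.table::fwrite(d, path, sep = "\t", quote = FALSE)
  invisible(path)
}
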