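#' Coding-sequence gene model
#'
#' A bare CDS with optional upstream sequence supplying the coordinate frame
#' for HGVS c. descriptions: CDS base 1 is the A of the start codon, negative
#' positions lie 5' of it.
#'
#' @param cds_seq DNA string; must start `ATG`, have length a multiple of 3,
#'   end in a stop codon and contain no internal stop codon.
#' @param upstream_seq DNA string 5' of the start codon (may be empty).
#' @param id label for the model.
#' @return An object of class `cds_model`.
#' @export
cds_model <- function(cds_seq, upstream_seq = "", id = "cds") {
  cds_seq <- toupper(cds_seq); upstream_seq <- toupper(upstream_seq)
  n <- nchar(cds_seq)
  if (n %% 3L != 0L) abort2("CDS length %d is not a multiple of 3", n)
  if (substr(cds_seq, 1L, 3L) != "ATG") abort2("CDS does not start with ATG")
  aa <- translate_dna(cds_seq)
  if (substr(aa, nchar(aa), nchar(aa)) != "*")
    abort2("CDS does not end with a stop codon")
  if (grepl("\\*", substr(aa, 1L, nchar(aa) - 1L)))
    abort2("CDS contains an internal stop codon")
  structure(list(cds_seq = cds_seq, upstream_seq = upstream_seq, id = id),
            class = "cds_model")
}

#' @export
print.cds_model <- function(x, ...) {
  cat(sprintf("<cds_model> %s: CDS %d nt (%d codons), upstream %d nt\n",
              x$id, nchar(x$cds_seq), nchar(x$cds_seq) / 3L,
              nchar(x$upstream_seq)))
  invisible(x)
}

translate_dna <- function(seq) {
  n <- 3L * (nchar(seq) %/% 3L)
  if (n == 0L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(gsub("[^ACGTN]", "N", seq), 1L, n)),
    if.fuzzy.codon = "solve"))
}

revcomp_dna <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Apply an HGVS c. variant to a gene model
#'
#' Edits are interpreted on the coding strand of `paste0(upstream, cds)`.
#' Substitutions replace one base (after checking the stated reference base
#' against the model, which guards against coordinate bugs), deletions remove
#' the span, insertions insert between the two flanking positions, delins
#' replaces the span with the insert (external-reference inserts of declared
#' length are filled with `N`), and inversions replace the span with its
#' reverse complement.
#'
#' @param cds a [cds_model()].
#' @param v an `hgvs_variant` (or HGVS string, parsed on the fly).
#' @return The full mutated sequence (upstream + CDS) as a character string,
#'   with attribute `cds_offset` = number of retained bases 5' of the
#'   original CDS start (so `substr(out, cds_offset + 1, ...)` is the mutant
#'   CDS region when the start itself is untouched).
#' @export
apply_variant <- function(cds, v) {
  if (is.character(v)) v <- parse_hgvs_c(v)
  stopifnot(inherits(cds, "cds_model"), inherits(v, "hgvs_variant"))
  up <- nchar(cds$upstream_seq)
  full <- paste0(cds$upstream_seq, cds$cds_seq)
  i <- c_to_index(v$start, up); j <- c_to_index(v$end, up)
  if (i < 1L || j > nchar(full))
    abort2("variant span c.%d_%d outside the modelled sequence (upstream %d nt, CDS %d nt)",
           v$start, v$end, up, nchar(cds$cds_seq))
  seg <- substr(full, i, j)
  if (v$kind == "substitution" && !is.na(v$ref_base) && seg != v$ref_base)
    abort2("reference mismatch at c.%d: model has %s, variant states %s",
           v$start, seg, v$ref_base)
  if (v$kind == "deletion" && !is.na(v$ref_base) && seg != v$ref_base)
    abort2("reference mismatch at c.%d_%d: model has %s, variant states %s",
           v$start, v$end, seg, v$ref_base)
  left <- substr(full, 1L, i - 1L); right <- substr(full, j + 1L, nchar(full))
  out <- switch(v$kind,
    substitution = paste0(left, v$alt, right),
    deletion     = paste0(left, right),
    insertion    = paste0(substr(full, 1L, i), v$alt,
                          substr(full, i + 1L, nchar(full))),
    delins       = paste0(left,
                          if (!is.na(v$insert_ext))
                            strrep("N", v$insert_len) else v$alt,
                          right),
    inversion    = paste0(left, revcomp_dna(seg), right))
  attr(out, "cds_offset") <- min(up, i - 1L)
  out
}

#' Codon span of a variant
#'
#' The codon containing CDS base `p` is `ceiling(p / 3)`. Spans reaching into
#' upstream (negative) coordinates are restricted to their CDS part and
#' flagged `truncated`.
#'
#' @param v an `hgvs_variant` or HGVS string.
#' @return list(first_codon, last_codon, count, truncated).
#' @export
#' @examples
#' codons_spanned("c.6393_6413inv")$count  # 8 codons
codons_spanned <- function(v) {
  if (is.character(v)) v <- parse_hgvs_c(v)
  if (v$end < 0L) abort2("span c.%d_%d lies entirely upstream of the CDS",
                         v$start, v$end)
  truncated <- v$start < 0L
  first <- ceiling(max(v$start, 1L) / 3)
  last <- ceiling(v$end / 3)
  list(first_codon = as.integer(first), last_codon = as.integer(last),
       count = as.integer(last - first + 1), truncated = truncated)
}

net_length_change <- function(v) {
  del <- switch(v$kind,
    substitution = 1L, inversion = 0L,
    insertion = 0L,
    deletion = hgvs_span_length(v$start, v$end),
    delins = hgvs_span_length(v$start, v$end))
  ins <- switch(v$kind,
    substitution = 1L, inversion = 0L,
    insertion = v$insert_len,
    deletion = 0L,
    delins = v$insert_len)
  if (v$kind %in% c("substitution", "inversion")) 0L else ins - del
}

#' Classify the coding consequence of a variant
#'
#' The variant is applied to the model and the mutant sequence translated in
#' frame from the original ATG. Classification precedence:
#' \enumerate{
#'   \item entirely upstream of the ATG: `upstream_noncoding`;
#'   \item start codon disrupted (span overlaps CDS bases 1..3 with a
#'     sequence change, or upstream deletion removing the ATG): `start_lost`;
#'   \item net inserted-minus-deleted length within the CDS not a multiple of
#'     3: `frameshift` (a supplementary field reports the downstream stop);
#'   \item an in-frame premature stop appears: `nonsense`;
#'   \item otherwise `missense`/`silent` for substitutions,
#'     `inframe_deletion` for deletions, `inframe_substitution` for in-frame
#'     inversions and delins (and `silent` when the peptide is unchanged).
#' }
#'
#' @param cds a [cds_model()].
#' @param v an `hgvs_variant` or HGVS string.
#' @return An `effect_call`: list with `effect_class`, `first_affected_codon`,
#'   `ref_residues`, `alt_residues`, `hgvs`, and for frameshifts
#'   `downstream_stop_codon` (codon index of the first stop in the shifted
#'   frame, `NA` if none before the sequence end).
#' @export
classify_effect <- function(cds, v) {
  if (is.character(v)) v <- parse_hgvs_c(v)
  stopifnot(inherits(cds, "cds_model"))
  up <- nchar(cds$upstream_seq)
  ref_pep_full <- translate_dna(cds$cds_seq)
  ref_pep <- sub("\\*$", "", ref_pep_full)

  if (v$end < 0L)
    return(effect_call("upstream_noncoding", NA_integer_, v = v))

  mut_full <- apply_variant(cds, v)
  off <- attr(mut_full, "cds_offset")
  mut_cds_region <- substr(mut_full, off + 1L, nchar(mut_full))

  # start codon integrity: the first three bases at the (possibly shifted)
  # CDS anchor must still read ATG
  if (v$start <= 3L && substr(mut_cds_region, 1L, 3L) != "ATG")
    return(effect_call("start_lost", 1L, v = v))

  net <- net_length_change(v)
  first_codon <- codons_spanned(v)$first_codon

  mut_pep_full <- translate_dna(mut_cds_region)
  stop_at <- regexpr("*", mut_pep_full, fixed = TRUE)
  mut_pep <- if (stop_at > 0L) substr(mut_pep_full, 1L, stop_at - 1L) else
    mut_pep_full

  if (net %% 3L != 0L) {
    return(effect_call("frameshift", first_codon, v = v,
      downstream_stop = if (stop_at > 0L) as.integer(stop_at) else NA_integer_))
  }

  if (v$kind == "substitution") {
    k <- first_codon
    ref_aa <- substr(ref_pep_full, k, k)
    alt_aa <- substr(mut_pep_full, k, k)
    cls <- if (alt_aa == ref_aa) "silent"
      else if (alt_aa == "*") "nonsense" else "missense"
    return(effect_call(cls, k, ref_aa, alt_aa, v = v))
  }

  # in-frame indel / inversion / delins: a stop arriving before the expected
  # mutant length (ref length + net/3) is premature and wins, else diff
  if (stop_at > 0L && (stop_at - 1L) < nchar(ref_pep) + net %/% 3L) {
    changed <- peptide_diff(ref_pep_full, mut_pep_full)
    return(effect_call("nonsense", changed$first, changed$ref, changed$alt,
                       v = v, downstream_stop = as.integer(stop_at)))
  }
  changed <- peptide_diff(ref_pep_full, mut_pep_full)
  if (is.na(changed$first))
    return(effect_call("silent", first_codon, "", "", v = v))
  cls <- switch(v$kind,
    deletion = "inframe_deletion",
    insertion = "inframe_substitution",
    delins = "inframe_substitution",
    inversion = "inframe_substitution")
  effect_call(cls, changed$first, changed$ref, changed$alt, v = v)
}

# changed stretch between two peptides: trim common prefix, then common
# suffix of the remainders (mirrors the nucleotide-level edit normalisation)
peptide_diff <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  p <- 0L
  while (p < min(length(av), length(bv)) && av[p + 1L] == bv[p + 1L])
    p <- p + 1L
  if (p == length(av) && p == length(bv))
    return(list(first = NA_integer_, ref = "", alt = ""))
  s <- 0L
  while (s < min(length(av), length(bv)) - p &&
         av[length(av) - s] == bv[length(bv) - s]) s <- s + 1L
  list(first = p + 1L,
       ref = paste(av[seq_len(length(av) - s)][-seq_len(p)], collapse = ""),
       alt = paste(bv[seq_len(length(bv) - s)][-seq_len(p)], collapse = ""))
}

effect_call <- function(class, first_codon, ref_res = NA_character_,
                        alt_res = NA_character_, v = NULL,
                        downstream_stop = NA_integer_) {
  structure(list(effect_class = class,
                 first_affected_codon = first_codon,
                 ref_residues = ref_res, alt_residues = alt_res,
                 hgvs = if (!is.null(v)) format_hgvs(v) else NA_character_,
                 downstream_stop_codon = downstream_stop),
            class = "effect_call")
}

#' @export
print.effect_call <- function(x, ...) {
  cat(sprintf("<effect_call> %s: %s at codon %s%s\n", x$hgvs, x$effect_class,
              x$first_affected_codon,
              if (!is.na(x$ref_residues) && nzchar(x$ref_residues))
                sprintf(" (%s > %s)", x$ref_residues, x$alt_residues) else ""))
  invisible(x)
}

#' Name the single contiguous edit between a reference CDS and a mutant
#'
#' The inverse of [apply_variant()] for edits confined to the CDS. The edit
#' is normalised per the HGVS 3' rule: the common prefix of the two sequences
#' is maximised before trimming the common suffix, so deletions and
#' insertions inside repeats take their most 3' representation. An
#' equal-length changed segment that is the reverse complement of its
#' reference is reported as an inversion.
#'
#' @param ref_cds a [cds_model()] (its CDS is the reference).
#' @param mut_seq mutant CDS-region sequence (character).
#' @return An `hgvs_variant`, or `NULL` when the sequences are identical.
#'   Two or more disjoint edits are rejected with both loci reported.
#' @export
#' @examples
#' m <- cds_model("ATGAAACCCTAA")
#' format_hgvs(name_variant(m, "ATGACCCTAA"))  # "c.5_6del"
name_variant <- function(ref_cds, mut_seq) {
  stopifnot(inherits(ref_cds, "cds_model"), is.character(mut_seq))
  a <- ref_cds$cds_seq; b <- toupper(mut_seq)
  if (a == b) return(NULL)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  p <- 0L
  while (p < min(length(av), length(bv)) && av[p + 1L] == bv[p + 1L])
    p <- p + 1L
  s <- 0L
  while (s < min(length(av), length(bv)) - p &&
         av[length(av) - s] == bv[length(bv) - s]) s <- s + 1L
  ra <- substr(a, p + 1L, nchar(a) - s)   # deleted reference segment
  rb <- substr(b, p + 1L, nchar(b) - s)   # inserted segment
  # two clearly separate edits: equal-length changed region whose interior
  # contains a long (>= 8 nt) unchanged run between mismatches; short
  # interior matches arise routinely inside genuine delins/inversion edits
  if (nchar(ra) == nchar(rb) && nchar(ra) > 1L && rb != revcomp_dna(ra)) {
    same <- strsplit(ra, "")[[1]] == strsplit(rb, "")[[1]]
    runs <- rle(same)
    inner <- runs$values & seq_along(runs$values) != 1L &
      seq_along(runs$values) != length(runs$values)
    if (any(runs$lengths[inner] >= 8L)) {
      dif <- which(!same)
      abort2("multiple disjoint edits (loci near c.%d and c.%d); one contiguous edit required",
             p + dif[1L], p + dif[length(dif)])
    }
  }
  if (nchar(ra) == 1L && nchar(rb) == 1L)
    return(new_hgvs("substitution", p + 1L, p + 1L, ref_base = ra, alt = rb))
  if (nchar(rb) == 0L)
    return(new_hgvs("deletion", p + 1L, p + nchar(ra), ref_base = ra))
  if (nchar(ra) == 0L)
    return(new_hgvs("insertion", p, p + 1L, alt = rb,
                    insert_len = nchar(rb)))
  if (nchar(ra) == nchar(rb) && nchar(ra) >= 2L && rb == revcomp_dna(ra))
    return(new_hgvs("inversion", p + 1L, p + nchar(ra)))
  new_hgvs("delins", p + 1L, p + nchar(ra), alt = rb, insert_len = nchar(rb))
}
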