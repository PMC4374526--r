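#' HGVS c.-notation variants
#'
#' Parse a coding-sequence (c.) variant description into a structured
#' `hgvs_variant`. Positions are 1-based on the CDS; negative positions count
#' upstream from the base immediately 5' of the start codon (position 0 does
#' not exist). Whitespace inside the string (as often typeset in tables,
#' e.g. `"c.1015A > T"`) is stripped before parsing.
#'
#' Supported kinds: substitution (`c.1015A>T`), deletion (`c.7137_7143del`,
#' `c.3508del`), insertion (`c.12_13insTTA`), deletion-insertion
#' (`c.1_6delinsAT`, with external-reference insert tokens such as
#' `CM000150.2:1390060_1390808` carried opaquely with a declared length), and
#' inversion (`c.6393_6413inv`).
#'
#' @param text HGVS string beginning `"c."`.
#' @return An object of class `hgvs_variant`: a list with `kind`, `start`,
#'   `end`, `ref_base`, `alt` (alt base or insert sequence), `insert_ext`
#'   (external token or `NA`), `insert_len`.
#' @export
#' @examples
#' v <- parse_hgvs_c("c.7137_7143del")
#' hgvs_span_length(v$start, v$end)  # 7
parse_hgvs_c <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[[:space:]]", "", text)
  if (!startsWith(s, "c.")) abort2("not a c. variant: '%s'", text)
  body <- substr(s, 3L, nchar(s))
  num <- "(-?[0-9]+)"
  m <- function(pat) regmatches(body, regexec(paste0("^", pat, "$"), body))[[1]]

  if (length(g <- m(paste0(num, "_", num, "inv")))) {
    v <- new_hgvs("inversion", as.integer(g[2]), as.integer(g[3]))
  } else if (length(g <- m(paste0(num, "(_", num, ")?delins(.+)")))) {
    end <- if (nzchar(g[3])) as.integer(g[4]) else as.integer(g[2])
    ins <- g[5]
    if (grepl("^[ACGT]+$", ins)) {
      v <- new_hgvs("delins", as.integer(g[2]), end, alt = ins,
                    insert_len = nchar(ins))
    } else if (length(e <- regmatches(ins,
                 regexec("^([^:]+):([0-9]+)_([0-9]+)$", ins)))[[1]] &&
               length(e[[1]]) == 4L) {
      e <- e[[1]]
      v <- new_hgvs("delins", as.integer(g[2]), end, insert_ext = ins,
                    insert_len = as.integer(e[4]) - as.integer(e[3]) + 1L)
    } else abort2("unparseable delins insert token: '%s'", ins)
  } else if (length(g <- m(paste0(num, "(_", num, ")?del([ACGT]*)")))) {
    end <- if (nzchar(g[3])) as.integer(g[4]) else as.integer(g[2])
    v <- new_hgvs("deletion", as.integer(g[2]), end,
                  ref_base = if (nzchar(g[5])) g[5] else NA_character_)
  } else if (length(g <- m(paste0(num, "_", num, "ins([ACGT]+)")))) {
    a <- as.integer(g[2]); b <- as.integer(g[3])
    if (hgvs_span_length(a, b) != 2L)
      abort2("insertion positions must be adjacent: '%s'", text)
    v <- new_hgvs("insertion", a, b, alt = g[4], insert_len = nchar(g[4]))
  } else if (length(g <- m(paste0(num, "([ACGT])>([ACGT])")))) {
    if (g[3] == g[4]) abort2("substitution with identical alleles: '%s'", text)
    v <- new_hgvs("substitution", as.integer(g[2]), as.integer(g[2]),
                  ref_base = g[3], alt = g[4])
  } else abort2("unparseable HGVS c. description: '%s'", text)
  v
}

new_hgvs <- function(kind, start, end = start, ref_base = NA_character_,
                     alt = NA_character_, insert_ext = NA_character_,
                     insert_len = NA_integer_) {
  if (start == 0L || end == 0L) abort2("c. position 0 does not exist")
  if (c_lt(end, start)) abort2("start > end in span %d_%d", start, end)
  structure(list(kind = kind, start = as.integer(start), end = as.integer(end),
                 ref_base = ref_base, alt = alt, insert_ext = insert_ext,
                 insert_len = as.integer(insert_len)),
            class = "hgvs_variant")
}

# c.-coordinate ordering: ... -2 < -1 < 1 < 2 ...
c_lt <- function(a, b) a < b

#' Length of a c.-coordinate span
#'
#' `end - start + 1` when both coordinates share a sign; when the span
#' crosses the (non-existent) position 0 the `+1` is absorbed by the missing
#' zero, giving `end - start`.
#'
#' @param start,end integer c. coordinates (no zero).
#' @return Integer span length in nucleotides.
#' @export
hgvs_span_length <- function(start, end) {
  stopifnot(start != 0L, end != 0L, !c_lt(end, start))
  as.integer(end - start + (if (sign(start) == sign(end)) 1L else 0L))
}

#' Format an `hgvs_variant` back to its string form
#' @param v an `hgvs_variant`.
#' @return The normalised HGVS string, e.g. `"c.7137_7143del"`.
#' @export
format_hgvs <- function(v) {
  stopifnot(inherits(v, "hgvs_variant"))
  span <- if (v$end == v$start) as.character(v$start) else
    sprintf("%d_%d", v$start, v$end)
  switch(v$kind,
    substitution = sprintf("c.%d%s>%s", v$start, v$ref_base, v$alt),
    deletion     = sprintf("c.%sdel", span),
    insertion    = sprintf("c.%d_%dins%s", v$start, v$end, v$alt),
    delins       = sprintf("c.%sdelins%s", span,
                           if (!is.na(v$insert_ext)) v$insert_ext else v$alt),
    inversion    = sprintf("c.%sinv", span))
}

#' @export
print.hgvs_variant <- function(x, ...) {
  cat("<hgvs_variant> ", format_hgvs(x), "  kind=", x$kind, "\n", sep = "")
  invisible(x)
}

# map a c. coordinate onto an index into paste0(upstream, cds)
c_to_index <- function(pos, upstream_len) {
  if (pos > 0L) upstream_len + pos else upstream_len + pos + 1L
}
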