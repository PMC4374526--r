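#' Alignment scoring scheme
#'
#' Substitution matrix plus affine gap penalties. The default is BLOSUM62
#' with gap open 10 and gap extend 0.5 — the defaults of the classic EMBOSS
#' `water`/`needle` tools. A gap of length L costs `open + extend * (L - 1)`.
#' Ambiguity residues (B, Z, X) are scored 0 against everything.
#'
#' @param matrix a symmetric residue-pair score matrix with residue
#'   rownames/colnames, or `"BLOSUM62"` (taken from Biostrings' data set).
#' @param gap_open,gap_extend non-negative penalties.
#' @return A `scoring_scheme` list with `matrix`, `gap_open`, `gap_extend`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 10,
                           gap_extend = 0.5) {
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(matrix, envir = e)
  }
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            identical(rownames(matrix), colnames(matrix)))
  if (gap_open < 0 || gap_extend < 0) abort2("gap penalties must be >= 0")
  amb <- intersect(c("B", "Z", "X"), rownames(matrix))
  matrix[amb, ] <- 0
  matrix[, amb] <- 0
  if (!isTRUE(all.equal(matrix, t(matrix))))
    abort2("substitution matrix must be symmetric")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend), class = "scoring_scheme")
}

seq_to_idx <- function(seq, scheme) {
  ch <- strsplit(toupper(seq), "")[[1]]
  idx <- match(ch, rownames(scheme$matrix))
  if (anyNA(idx))
    abort2("residue(s) not in the scoring alphabet: %s",
           paste(unique(ch[is.na(idx)]), collapse = ", "))
  idx - 1L
}

render_alignment <- function(a, b, a_pos, b_pos) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  c(paste(ifelse(is.na(a_pos), "-", av[a_pos]), collapse = ""),
    paste(ifelse(is.na(b_pos), "-", bv[b_pos]), collapse = ""))
}

#' Local (Smith-Waterman) alignment with affine gaps
#'
#' @param a,b residue strings.
#' @param scheme a [scoring_scheme()].
#' @param score_only skip the traceback (fast path for window profiling).
#' @return list(score, alignment = c(gapped a, gapped b), a_start, a_end,
#'   b_start, b_end). An empty input yields score 0 with an empty alignment
#'   (the local-alignment floor).
#' @export
local_align <- function(a, b, scheme = scoring_scheme(), score_only = FALSE) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  if (!nzchar(a) || !nzchar(b))
    return(list(score = 0, alignment = c("", ""),
                a_start = NA_integer_, a_end = NA_integer_,
                b_start = NA_integer_, b_end = NA_integer_))
  ai <- seq_to_idx(a, scheme); bi <- seq_to_idx(b, scheme)
  if (score_only)
    return(list(score = .sw_score(ai, bi, scheme$matrix, scheme$gap_open,
                                  scheme$gap_extend)))
  r <- .align_affine(ai, bi, scheme$matrix, scheme$gap_open,
                     scheme$gap_extend, TRUE)
  ap <- r$a_pos; bp <- r$b_pos
  list(score = r$score, alignment = render_alignment(a, b, ap, bp),
       a_start = if (length(ap)) min(ap, na.rm = TRUE) else NA_integer_,
       a_end = if (length(ap)) max(ap, na.rm = TRUE) else NA_integer_,
       b_start = if (length(bp)) min(bp, na.rm = TRUE) else NA_integer_,
       b_end = if (length(bp)) max(bp, na.rm = TRUE) else NA_integer_)
}

#' Global (Needleman-Wunsch) alignment and homology percentages
#'
#' Percent identity is the fraction of alignment columns with identical
#' residues; percent similarity the fraction with a strictly positive
#' substitution score. Gap columns count in the denominator, so indels
#' reduce both percentages.
#'
#' @param a,b non-empty residue strings.
#' @param scheme a [scoring_scheme()].
#' @return A `global_homology`: list(score, alignment = c(gapped a,
#'   gapped b), pct_identity, pct_similarity).
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  if (!nzchar(a) || !nzchar(b)) abort2("global alignment of an empty sequence")
  ai <- seq_to_idx(a, scheme); bi <- seq_to_idx(b, scheme)
  r <- .align_affine(ai, bi, scheme$matrix, scheme$gap_open,
                     scheme$gap_extend, FALSE)
  aln <- render_alignment(a, b, r$a_pos, r$b_pos)
  ac <- strsplit(aln[1], "")[[1]]; bc <- strsplit(aln[2], "")[[1]]
  len <- length(ac)
  nongap <- !is.na(r$a_pos) & !is.na(r$b_pos)
  ident <- nongap & ac == bc
  simil <- nongap
  simil[nongap] <- scheme$matrix[cbind(ac[nongap], bc[nongap])] > 0
  structure(list(score = r$score, alignment = aln,
                 pct_identity = 100 * sum(ident) / len,
                 pct_similarity = 100 * sum(simil) / len),
            class = "global_homology")
}

#' @export
print.global_homology <- function(x, ...) {
  cat(sprintf("<global_homology> length %d: identity %.1f%%, similarity %.1f%%\n",
              nchar(x$alignment[1]), x$pct_identity, x$pct_similarity))
  invisible(x)
}

#' Sliding-window homology profile normalised to self
#'
#' The query is cut into windows of `window` residues starting at 1,
#' 1 + step, ... (inclusive ranges; the final window is shortened to the
#' tail, never discarded; a query shorter than `window` yields one window =
#' the whole sequence). Each window is locally aligned against every target
#' and against the full query itself, and the per-window score is divided by
#' that self score — so profiling the query against itself gives exactly 1
#' everywhere, and no window can exceed 1 (its perfect match is a substring
#' of the query).
#'
#' @param query residue string.
#' @param targets named character vector (or list) of target sequences.
#' @param window window width in residues.
#' @param step window start interval; `step = window` reproduces the
#'   non-overlapping "split into segments" reading, the default 100 gives
#'   half-overlapping windows.
#' @param scheme a [scoring_scheme()].
#' @param query_id label for the query.
#' @return A `window_profile`: list(query_id, window, step, starts, scores)
#'   where `scores` is a windows x targets matrix of normalised scores in
#'   `[0, 1]`.
#' @export
window_profile <- function(query, targets, window = 200L, step = 100L,
                           scheme = scoring_scheme(), query_id = "query") {
  if (!nzchar(query)) abort2("empty query")
  window <- as.integer(window); step <- as.integer(step)
  if (window < 1L || step < 1L) abort2("window and step must be >= 1")
  targets <- unlist(targets)
  if (is.null(names(targets)) || any(!nzchar(names(targets))))
    names(targets) <- paste0("target", seq_along(targets))
  n <- nchar(query)
  starts <- seq.int(1L, n, by = step)
  scores <- matrix(NA_real_, length(starts), length(targets),
                   dimnames = list(NULL, names(targets)))
  selfs <- numeric(length(starts))
  for (i in seq_along(starts)) {
    win <- substr(query, starts[i], min(starts[i] + window - 1L, n))
    selfs[i] <- local_align(win, query, scheme, score_only = TRUE)$score
    if (selfs[i] <= 0)
      abort2("window at %d has non-positive self score", starts[i])
    for (j in seq_along(targets))
      scores[i, j] <- local_align(win, targets[[j]], scheme,
                                  score_only = TRUE)$score / selfs[i]
  }
  structure(list(query_id = query_id, window = as.integer(window),
                 step = as.integer(step), starts = starts,
                 self_scores = selfs, scores = scores),
            class = "window_profile")
}

#' @export
print.window_profile <- function(x, ...) {
  cat(sprintf("<window_profile> %s: %d windows (w=%d, step=%d) x %d targets\n",
              x$query_id, length(x$starts), x$window, x$step,
              ncol(x$scores)))
  invisible(x)
}

#' Map a query residue position through a pairwise alignment
#'
#' Returns the target residue index aligned to `query_pos`. When the query
#' position sits opposite a gap, the nearest aligned target position 5'-ward
#' (leftward) is returned and flagged `exact = FALSE`; 0 is returned when no
#' aligned target position exists to the left.
#'
#' @param alignment character vector of two equal-length gapped strings
#'   (query, target), e.g. `x$alignment` from [global_align()].
#' @param query_pos 1-based index into the ungapped query.
#' @return list(target_pos, exact).
#' @export
map_aligned_position <- function(alignment, query_pos) {
  stopifnot(length(alignment) == 2L,
            nchar(alignment[1]) == nchar(alignment[2]))
  qa <- strsplit(alignment[1], "")[[1]]; ta <- strsplit(alignment[2], "")[[1]]
  qidx <- cumsum(qa != "-")
  if (query_pos < 1L || query_pos > max(qidx))
    abort2("query_pos %d outside ungapped query length %d",
           query_pos, max(qidx))
  col <- which(qidx == query_pos & qa != "-")[1L]
  tidx <- cumsum(ta != "-")
  if (ta[col] != "-") return(list(target_pos = tidx[col], exact = TRUE))
  list(target_pos = tidx[col], exact = FALSE)  # tidx[col] = last aligned 5'
}
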