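#' Rolling median of a depth track
#'
#' Per-position median over a centred window of odd width `window`; at the
#' chromosome ends the window is truncated to the available positions
#' (median of fewer values) so output length equals input length. With
#' `edge = "drop"` the `(window - 1) / 2` positions at each end are set to
#' `NA` instead. The interior uses the C running-median in [stats::runmed()];
#' the truncated ends are recomputed explicitly.
#'
#' @param track a [depth_track()].
#' @param window odd integer >= 1, <= track length.
#' @param edge `"truncate"` (default) or `"drop"`.
#' @return A `depth_track` of medians (numeric, same length).
#' @export
rolling_median <- function(track, window = 999L, edge = c("truncate", "drop")) {
  stopifnot(inherits(track, "depth_track"))
  edge <- match.arg(edge)
  window <- as.integer(window)
  x <- track$depths
  n <- length(x)
  if (window %% 2L == 0L) abort2("window must be odd (got %d)", window)
  if (window < 1L || window > n)
    abort2("window must lie in [1, %d] (got %d)", n, window)
  if (window == 1L) return(track)
  h <- (window - 1L) %/% 2L
  y <- as.numeric(stats::runmed(x, window, endrule = "keep"))
  if (edge == "truncate") {
    for (i in seq_len(h)) {
      y[i] <- median(x[1:(i + h)])
      y[n - i + 1L] <- median(x[(n - i + 1L - h):n])
    }
  } else {
    y[seq_len(h)] <- NA_real_
    y[(n - h + 1L):n] <- NA_real_
  }
  out <- track
  out$depths <- y
  class(out) <- class(track)
  out
}

#' Subsample a track on a regular grid
#'
#' Values are taken at positions `step, 2*step, ...` up to the track length;
#' a track shorter than `step` yields an empty profile.
#'
#' @param track a [depth_track()] (usually rolling-median smoothed).
#' @param step sampling interval in bp (>= 1).
#' @param window the smoothing window used upstream (metadata only).
#' @return A `sampled_profile`: list(chrom, positions, values, window, step).
#' @export
subsample <- function(track, step = 1000L, window = NA_integer_) {
  stopifnot(inherits(track, "depth_track"))
  step <- as.integer(step)
  if (step < 1L) abort2("step must be >= 1 (got %d)", step)
  idx <- if (step > length(track$depths)) integer(0)
    else seq.int(step, length(track$depths), by = step)
  structure(list(chrom = track$chrom, positions = idx,
                 values = as.numeric(track$depths[idx]),
                 window = window, step = step),
            class = "sampled_profile")
}

#' @export
print.sampled_profile <- function(x, ...) {
  cat(sprintf("<sampled_profile> %s: %d points every %d bp\n", x$chrom,
              length(x$positions), x$step))
  invisible(x)
}

#' Call duplicated segments from a sampled depth profile
#'
#' Background coverage is the chromosome-wide median of the profile values.
#' A maximal run of at least `min_run` consecutive points whose
#' value/background ratio lies in `[ratio_lo, ratio_hi]` ("approximately
#' double") is reported as one segment with `copy_ratio` = median of the
#' segment values divided by the background. Segments are disjoint and
#' sorted; the output depends on depth ratios only, so it is invariant under
#' uniform scaling of all depths.
#'
#' @param profile a [subsample()] output.
#' @param ratio_lo,ratio_hi copy-ratio band for "approximately double".
#' @param min_run minimum run length in sampled points (50 points = 50 kb at
#'   the default 1-kb step, matching duplications spanning hundreds of kb).
#' @return data.table: chrom, start_pos, end_pos, n_points, copy_ratio.
#' @export
detect_duplications <- function(profile, ratio_lo = 1.75, ratio_hi = 2.25,
                                min_run = 50L) {
  stopifnot(inherits(profile, "sampled_profile"))
  v <- profile$values
  if (length(v) == 0L) abort2("empty profile")
  bg <- median(v, na.rm = TRUE)
  if (!is.finite(bg) || bg <= 0) abort2("background median is 0: no coverage")
  ratio <- v / bg
  inband <- !is.na(ratio) & ratio >= ratio_lo & ratio <= ratio_hi
  r <- rle(inband)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- which(r$values & r$lengths >= min_run)
  data.table::data.table(
    chrom = profile$chrom,
    start_pos = profile$positions[starts[seg]],
    end_pos = profile$positions[ends[seg]],
    n_points = r$lengths[seg],
    copy_ratio = vapply(seg, function(k)
      median(v[starts[k]:ends[k]]) / bg, 0))
}

#' One-call duplication scan
#'
#' rolling-median smoothing, grid subsampling, and segment calling with the
#' module defaults (window 999, step 1000).
#'
#' @param track a [depth_track()].
#' @param window,step,edge see [rolling_median()] / [subsample()].
#' @param ... passed to [detect_duplications()].
#' @return list(profile = `sampled_profile`, segments = data.table).
#' @export
cnv_scan <- function(track, window = 999L, step = 1000L,
                     edge = "truncate", ...) {
  sm <- rolling_median(track, window = window, edge = edge)
  prof <- subsample(sm, step = step, window = window)
  list(profile = prof, segments = detect_duplications(prof, ...))
}
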