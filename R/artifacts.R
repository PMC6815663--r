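# ---------------------------------------------------------------------------
# Artifact intervals: detection on the continuous recording and blanking of
# the expanded design. Intervals are half-open [start, stop) in 0-based
# sample indices, kept merged / sorted / disjoint.
# ---------------------------------------------------------------------------

#' Build a normalized interval set
#'
#' @param starts,stops 0-based sample indices of half-open intervals
#'   `[start, stop)`.
#' @return an `erp_intervals` object: a two-column matrix of merged, sorted,
#'   pairwise-disjoint intervals.
#' @export
interval_set <- function(starts = integer(), stops = integer()) {
  stopifnot(length(starts) == length(stops))
  if (length(starts) == 0)
    return(structure(cbind(start = integer(), stop = integer()),
                     class = "erp_intervals"))
  if (any(stops <= starts)) stop("intervals must satisfy stop > start")
  o <- order(starts)
  starts <- as.integer(starts[o]); stops <- as.integer(stops[o])
  ms <- starts[1]; me <- stops[1]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) me <- max(me, stops[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me)
           ms <- starts[i]; me <- stops[i] }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  structure(cbind(start = out_s, stop = out_e), class = "erp_intervals")
}

#' @export
print.erp_intervals <- function(x, ...) {
  cat(sprintf("<intervals> %d interval(s), %d sample(s) covered\n",
              nrow(x), interval_samples_count(x)))
  invisible(x)
}

interval_samples_count <- function(intervals)
  if (nrow(intervals) == 0) 0L else sum(intervals[, 2] - intervals[, 1])

# 0-based sample indices covered by the interval set
interval_samples <- function(intervals) {
  if (nrow(intervals) == 0) return(integer())
  unlist(lapply(seq_len(nrow(intervals)), function(i)
    seq.int(intervals[i, 1], intervals[i, 2] - 1L)))
}

#' Detect artifacts by a moving-window peak-to-peak threshold
#'
#' Slides a window of `winlen` seconds across the recording in steps of
#' `step` seconds; whenever the peak-to-peak amplitude (max minus min)
#' within the window exceeds `threshold` on any channel, the full window is
#' flagged. Flagged windows are merged. A window longer than the recording
#' degrades to a single whole-recording check.
#'
#' @param data channels x samples numeric matrix.
#' @param threshold peak-to-peak amplitude threshold (same units as the
#'   data, e.g. microvolts), > 0.
#' @param winlen window length in seconds, > 0.
#' @param step window step in seconds; default `winlen / 2`.
#' @param srate sampling rate in Hz.
#' @return an `erp_intervals` set of flagged sample intervals.
#' @export
detect_peak2peak <- function(data, threshold, winlen, step = winlen / 2,
                             srate) {
  stopifnot(is.matrix(data), threshold > 0, winlen > 0, step > 0, srate > 0)
  n <- ncol(data)
  wl <- max(2L, as.integer(round(winlen * srate)))
  st <- max(1L, as.integer(round(step * srate)))
  if (wl >= n) {
    p2p <- apply(data, 1, function(ch) diff(range(ch)))
    if (any(p2p > threshold)) return(interval_set(0L, n))
    return(interval_set())
  }
  starts <- seq.int(0L, n - wl, by = st)
  if (utils::tail(starts, 1) + wl < n)
    starts <- c(starts, n - wl)           # final window flush with the end
  flagged <- vapply(starts, function(s) {
    seg <- data[, (s + 1L):(s + wl), drop = FALSE]
    any(apply(seg, 1, function(ch) diff(range(ch))) > threshold)
  }, TRUE)
  if (!any(flagged)) return(interval_set())
  interval_set(starts[flagged], starts[flagged] + wl)
}

#' Blank design-matrix rows inside artifact intervals
#'
#' Sets every entry of the expanded design to zero in rows covered by the
#' intervals. Zeroed rows have zero leverage, so contaminated samples do not
#' affect the coefficient estimates; the column structure is unchanged. The
#' blanked row set is recorded on the result so the solver can also zero the
#' response on those rows and exclude them from the residual-scale estimate.
#'
#' @param X an `erp_expanded`.
#' @param intervals an `erp_intervals` (sample indices within
#'   `[0, n_samples)`).
#' @return the blanked `erp_expanded`, with attributes `blanked_rows`
#'   (0-based indices) and `n_blanked` stored in its `blanked` element.
#' @export
blank_rows <- function(X, intervals) {
  stopifnot(inherits(X, "erp_expanded"), inherits(intervals, "erp_intervals"))
  rows <- interval_samples(intervals)
  if (length(rows)) {
    if (min(rows) < 0 || max(rows) >= X$n_samples)
      stop("intervals outside [0, n_samples)")
    X$X[rows + 1L, ] <- 0
    X$X <- Matrix::drop0(X$X)
  }
  X$blanked <- sort(unique(c(X$blanked, rows)))
  X
}

#' Read / write artifact intervals as two-column delimited text
#'
#' @param path file path (tab-separated, columns `start` and `stop`).
#' @param intervals an `erp_intervals`.
#' @param seconds if `TRUE`, values are interpreted/written as seconds and
#'   converted with `srate`.
#' @param srate sampling rate, required when `seconds = TRUE`.
#' @return `read_intervals`: an `erp_intervals`.
#' @export
write_intervals <- function(intervals, path, seconds = FALSE, srate = NULL) {
  m <- unclass(intervals)
  if (seconds) {
    stopifnot(!is.null(srate))
    m <- m / srate
  }
  utils::write.table(as.data.frame(m), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path, seconds = FALSE, srate = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  if (seconds) {
    stopifnot(!is.null(srate))
    d <- round(d * srate)
  }
  interval_set(d[[1]], d[[2]])
}
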