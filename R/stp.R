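# Switch-time-peak (STP) layer: bin filtered switch events into fixed-width
# bins on the experimental time axis and call peaks in the distribution.

#' Bin switch times into a histogram
#'
#' Half-open bins `[edge_k, edge_{k+1})` of constant width starting at
#' `origin`. Events before `origin` (or beyond `t_max` when given) are
#' collected in an overflow bucket, never silently dropped.
#'
#' @param events Switch-event `data.frame` (see [detect_switches()]).
#' @param bin_width Bin width in hours (> 0); 3 h matches the sampling
#'   interval of the emulated design.
#' @param origin Left edge of the first bin (hours).
#' @param t_max Optional right edge of the last bin; defaults to the
#'   smallest grid point covering all event times.
#' @return A `switch_histogram`: list with `edges`, `counts`, `members`
#'   (event row indices per bin) and `overflow` (indices outside the
#'   histogram range).
#' @export
bin_switch_times <- function(events, bin_width = 3, origin = 0,
                             t_max = NULL) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  t <- events$switch_time
  if (is.null(t_max)) {
    hi <- if (length(t)) max(t[t >= origin], origin) else origin
    n_bins <- max(1L, ceiling((hi - origin) / bin_width + 1e-9))
    # a time exactly on the last edge opens one more bin (half-open rule)
    if (length(t) && any(t >= origin + n_bins * bin_width)) {
      n_bins <- n_bins + 1L
    }
  } else {
    n_bins <- max(1L, ceiling((t_max - origin) / bin_width - 1e-9))
  }
  edges <- origin + bin_width * (0:n_bins)
  counts <- integer(n_bins)
  members <- rep(list(integer(0)), n_bins)
  overflow <- integer(0)
  for (i in seq_along(t)) {
    k <- floor((t[i] - origin) / bin_width) + 1
    if (k < 1 || k > n_bins) {
      overflow <- c(overflow, i)
    } else {
      counts[k] <- counts[k] + 1L
      members[[k]] <- c(members[[k]], i)
    }
  }
  structure(list(edges = edges, counts = counts, members = members,
                 overflow = overflow),
            class = "switch_histogram")
}

#' @export
print.switch_histogram <- function(x, ...) {
  cat("switch_histogram:", length(x$counts), "bins of width",
      diff(x$edges)[1], "h,", sum(x$counts), "events",
      if (length(x$overflow)) paste0("(+", length(x$overflow), " overflow)")
      else "", "\n")
  invisible(x)
}

#' Call switch time peaks (STPs)
#'
#' An STP is a peak in the distribution of switch events per bin. A bin (or
#' plateau of adjacent equal bins, resolved to its earliest bin) is called
#' iff its count is strictly greater than both neighbouring counts
#' (boundary bins compare to their single neighbour) and reaches
#' `mean(counts) + alpha * sd(counts)`. A flat histogram has no peak. Calls
#' are ranked STP1, STP2, ... in ascending time order.
#'
#' @param hist A `switch_histogram` (>= 3 bins).
#' @param alpha Prominence multiplier on the count standard deviation.
#' @return A `data.frame` with columns `rank`, `bin_start`, `bin_end`,
#'   `count` and list-column `members` (event row indices).
#' @export
detect_stps <- function(hist, alpha = 1.0) {
  stopifnot(inherits(hist, "switch_histogram"))
  counts <- hist$counts
  n <- length(counts)
  if (n < 3) stop("need at least 3 bins to call peaks")
  threshold <- mean(counts) + alpha * stats::sd(counts)
  # runs of equal counts; a run is a local maximum iff strictly above the
  # counts flanking the run (missing flank at a boundary imposes nothing,
  # but a run spanning the whole histogram is flat, not a peak)
  r <- rle(counts)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  peaks <- integer(0)
  for (k in seq_along(r$values)) {
    left_ok <- k == 1L || r$values[k] > r$values[k - 1L]
    right_ok <- k == length(r$values) || r$values[k] > r$values[k + 1L]
    whole <- r$lengths[k] == n
    if (!whole && left_ok && right_ok && r$values[k] >= threshold) {
      peaks <- c(peaks, starts[k])
    }
  }
  data.frame(
    rank = seq_along(peaks),
    bin_start = hist$edges[peaks],
    bin_end = hist$edges[peaks + 1L],
    count = counts[peaks],
    members = I(hist$members[peaks])
  )
}

#' Assign switch events to STPs
#'
#' An event belongs to an STP iff its switch time lies in the STP's
#' half-open bin `[bin_start, bin_end)`.
#'
#' @param events Switch-event `data.frame`.
#' @param stps STP table from [detect_stps()].
#' @return Integer vector, one entry per event: the STP rank or `NA`.
#' @export
assign_events_to_stp <- function(events, stps) {
  out <- rep(NA_integer_, nrow(events))
  if (!nrow(stps)) return(out)
  for (k in seq_len(nrow(stps))) {
    inside <- events$switch_time >= stps$bin_start[k] &
      events$switch_time < stps$bin_end[k]
    out[inside] <- stps$rank[k]
  }
  out
}

#' Write a switch histogram / STP table as TSV
#'
#' @param hist A `switch_histogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(hist, path) {
  n <- length(hist$counts)
  utils::write.table(
    data.frame(bin_start_h = hist$edges[seq_len(n)],
               bin_end_h = hist$edges[seq_len(n) + 1L],
               count = hist$counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param stps STP table from [detect_stps()].
#' @rdname write_histogram
#' @export
write_stps <- function(stps, path) {
  utils::write.table(
    stps[, c("rank", "bin_start", "bin_end", "count")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
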