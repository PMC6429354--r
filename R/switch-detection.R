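# Core switch-detection layer: crossing localisation between isoform pairs
# and the five per-switch metrics (probability, magnitude S2, paired-t
# p-value, interval sizes, isoform correlation) plus the conjunctive filter.

# run expr under a fixed RNG seed without disturbing the caller's stream
with_rng_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Add uniform measurement noise to a time-course matrix
#'
#' Each value is perturbed by an independent uniform draw on
#' `(-amount, +amount)` and clamped at zero, emulating jitter applied to
#' single-sample time courses to mimic biological variation. The same seed
#' always yields the same output.
#'
#' @param x A [time_course_matrix()] or plain numeric matrix.
#' @param amount Noise half-range in TPM (>= 0); 2 TPM reproduces the study
#'   conditions.
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG
#'   stream.
#' @return Object of the same type as `x`.
#' @export
add_noise <- function(x, amount, seed = NULL) {
  if (!is.numeric(amount) || amount < 0) stop("amount must be >= 0")
  vals <- if (inherits(x, "time_course_matrix")) x$values else x
  draw <- function() {
    matrix(stats::runif(length(vals), -amount, amount), nrow = nrow(vals))
  }
  noise <- if (is.null(seed)) draw() else with_rng_seed(seed, draw())
  out <- pmax(vals + noise, 0)
  dimnames(out) <- dimnames(vals)
  if (inherits(x, "time_course_matrix")) {
    x$values <- out
    x
  } else {
    out
  }
}

#' Smooth an expression series with a B-spline fit
#'
#' Least-squares fit of a degree-`degree` B-spline basis evaluated at the
#' sampling times. The default basis dimension `df = degree + 1` places
#' one interior knot, which keeps the fit flexible near the window edges
#' (a knot-free basis is a bare polynomial whose edge bias displaces
#' crossings near the first and last samples). Degree 4 concentrates the
#' fit on slow, roughly 24-hour periodic trends over a 30-hour window;
#' polynomials up to the requested degree are always reproduced exactly.
#'
#' @param values Numeric series.
#' @param times Sampling times (hours), same length.
#' @param degree Spline degree; must be < `length(times)`.
#' @param df Basis dimension (>= `degree`; `degree` itself means no
#'   interior knots).
#' @return Fitted values at `times`.
#' @export
smooth_series <- function(values, times, degree = 4, df = degree + 1) {
  if (length(values) != length(times)) stop("length mismatch")
  if (degree >= length(times) || df >= length(times)) {
    stop("degree (", degree, ") and df must be < number of time points (",
         length(times), ")")
  }
  basis <- splines::bs(times, degree = degree, df = df)
  fit <- stats::lm.fit(cbind(1, basis), values)
  as.numeric(cbind(1, basis) %*% fit$coefficients)
}

#' Locate expression crossings between two isoform series
#'
#' A crossing lies between samples where the difference
#' `d = series_i - series_j` changes sign (a touch of zero with the same
#' sign on both sides is not a crossing). The switch time is the
#' linear-interpolation root of `d`. Consecutive crossings partition the
#' samples into flanking intervals: `before` holds all samples after the
#' previous crossing (or the series start) and strictly before the switch
#' time, `after` all samples strictly after it up to the next crossing (or
#' the series end).
#'
#' @param series_i,series_j Numeric series of equal length.
#' @param times Sampling times (hours).
#' @return A `data.frame` with columns `time` and list-columns `before`,
#'   `after` (integer sample indices); zero rows if the series never cross.
#' @export
find_crossings <- function(series_i, series_j, times) {
  n <- length(series_i)
  if (length(series_j) != n || length(times) != n) stop("length mismatch")
  if (n < 2) stop("need at least 2 samples")
  d <- series_i - series_j
  nz <- which(d != 0)
  roots <- numeric(0)
  if (length(nz) >= 2) {
    for (m in seq_len(length(nz) - 1L)) {
      a <- nz[m]; b <- nz[m + 1L]
      if (sign(d[a]) != sign(d[b])) {
        # root of the chord through (t_a, d_a), (t_b, d_b); intermediate
        # samples (if any) have d == 0 and the root passes through them
        roots <- c(roots,
                   times[a] - d[a] * (times[b] - times[a]) / (d[b] - d[a]))
      }
    }
  }
  if (!length(roots)) {
    return(data.frame(time = numeric(0),
                      before = I(list()), after = I(list())))
  }
  bounds <- c(-Inf, roots, Inf)
  before <- vector("list", length(roots))
  after <- vector("list", length(roots))
  for (m in seq_along(roots)) {
    before[[m]] <- which(times > bounds[m] & times < roots[m])
    after[[m]] <- which(times > roots[m] & times < bounds[m + 2L])
  }
  data.frame(time = roots, before = I(before), after = I(after))
}

#' Mean absolute abundance difference within an interval
#'
#' `d(iso_i, iso_j | I_k) = (1/|I_k|) * sum over samples m in I_k of
#' |exp_i(m) - exp_j(m)|` — the average separation of the two isoforms in
#' the interval, in TPM.
#'
#' @param series_i,series_j Numeric series.
#' @param idx Sample indices of the interval (non-empty).
#' @return Non-negative scalar, TPM.
#' @export
interval_mean_difference <- function(series_i, series_j, idx) {
  if (!length(idx)) stop("empty interval")
  mean(abs(series_i[idx] - series_j[idx]))
}

#' Switch magnitude S2
#'
#' The sum of the mean absolute abundance differences of the two isoforms
#' in the intervals before and after the switch:
#' `S2 = d(I1) + d(I2)`. Larger values indicate larger expression changes
#' around the switch.
#'
#' @inheritParams interval_mean_difference
#' @param before,after Sample-index sets flanking the switch (non-empty).
#' @return Non-negative scalar, TPM.
#' @export
switch_magnitude <- function(series_i, series_j, before, after) {
  interval_mean_difference(series_i, series_j, before) +
    interval_mean_difference(series_i, series_j, after)
}

#' Switch probability
#'
#' The frequency of samples consistent with the putative switch: isoform i
#' above isoform j before the switch and below it after. Ties count as
#' inconsistent.
#'
#' @inheritParams switch_magnitude
#' @return Scalar in `[0, 1]`.
#' @export
switch_probability <- function(series_i, series_j, before, after) {
  if (!length(before) || !length(after)) stop("empty interval")
  consistent <- sum(series_i[before] > series_j[before]) +
    sum(series_j[after] > series_i[after])
  consistent / (length(before) + length(after))
}

#' Switch p-value
#'
#' Within each flanking interval, a one-sample two-sided t-test of the
#' paired differences `exp_i(m) - exp_j(m)` against zero; the reported
#' p-value is the maximum of the two interval p-values (both intervals must
#' show a significant separation). Zero-variance differences give p = 0
#' when the mean is non-zero and p = 1 when it is zero.
#'
#' @inheritParams switch_magnitude
#' @return Scalar in `[0, 1]`.
#' @export
switch_pvalue <- function(series_i, series_j, before, after) {
  interval_p <- function(idx) {
    if (length(idx) < 2) stop("interval with < 2 samples: p-value undefined")
    d <- series_i[idx] - series_j[idx]
    s <- stats::sd(d)
    if (s == 0) return(if (mean(d) == 0) 1 else 0)
    tstat <- mean(d) / (s / sqrt(length(d)))
    2 * stats::pt(-abs(tstat), df = length(d) - 1L)
  }
  max(interval_p(before), interval_p(after))
}

#' Correlation of two isoform series
#'
#' Pearson correlation across all time points; defined as 0 when either
#' series is constant.
#'
#' @param series_i,series_j Numeric series of equal length (>= 3).
#' @return Scalar in `[-1, 1]`.
#' @export
series_correlation <- function(series_i, series_j) {
  if (length(series_i) != length(series_j)) stop("length mismatch")
  if (length(series_i) < 3) stop("need at least 3 samples")
  if (stats::sd(series_i) == 0 || stats::sd(series_j) == 0) return(0)
  stats::cor(series_i, series_j)
}

empty_events <- function() {
  data.frame(
    gene_id = character(0), iso_before = character(0),
    iso_after = character(0), switch_time = numeric(0),
    prob = numeric(0), diff = numeric(0), pval = numeric(0),
    cor = numeric(0), min_points = integer(0),
    n_before = integer(0), n_after = integer(0),
    idx_before = I(list()), idx_after = I(list())
  )
}

#' Score all isoform pairs of one gene for expression switches
#'
#' For every unordered pair of the gene's isoforms, crossings are located
#' (on spline-smoothed series when `use_smoothing = TRUE`; smoothing serves
#' crossing localisation only) and each crossing is scored with the five
#' switch metrics computed on the observed per-timepoint values in the
#' flanking intervals. `iso_before` is the isoform dominant before the
#' switch. Single-isoform genes yield zero events. An interval with fewer
#' than two samples leaves `pval` as `NA` (such events are removed by the
#' minimum-points filter).
#'
#' @param x A [time_course_matrix()].
#' @param gene_id Gene to score; must be present in the matrix.
#' @param use_smoothing Detect crossings on smoothed series.
#' @param degree Spline degree for smoothing.
#' @return A switch-event `data.frame` (possibly empty) with columns
#'   `gene_id`, `iso_before`, `iso_after`, `switch_time`, `prob`, `diff`,
#'   `pval`, `cor`, `min_points`, `n_before`, `n_after` and list-columns
#'   `idx_before`, `idx_after`.
#' @export
score_gene <- function(x, gene_id, use_smoothing = TRUE, degree = 4) {
  stopifnot(inherits(x, "time_course_matrix"))
  txs <- names(x$tx2gene)[x$tx2gene == gene_id]
  if (!length(txs)) stop("unknown gene_id: ", gene_id)
  if (length(txs) < 2) return(empty_events())
  times <- x$times
  rows <- list()
  for (a in seq_len(length(txs) - 1L)) {
    for (b in seq(a + 1L, length(txs))) {
      si <- x$values[txs[a], ]; sj <- x$values[txs[b], ]
      di <- si; dj <- sj
      if (use_smoothing) {
        di <- smooth_series(si, times, degree)
        dj <- smooth_series(sj, times, degree)
      }
      cr <- find_crossings(di, dj, times)
      if (!nrow(cr)) next
      for (m in seq_len(nrow(cr))) {
        i1 <- cr$before[[m]]; i2 <- cr$after[[m]]
        if (!length(i1) || !length(i2)) next
        # orient so iso_before dominates in I1 (observed values decide)
        md <- mean(si[i1] - sj[i1])
        if (md == 0) md <- di[max(i1)] - dj[max(i1)]
        if (md >= 0) {
          iso_b <- txs[a]; iso_a <- txs[b]; fi <- si; fj <- sj
        } else {
          iso_b <- txs[b]; iso_a <- txs[a]; fi <- sj; fj <- si
        }
        pv <- if (length(i1) >= 2 && length(i2) >= 2) {
          switch_pvalue(fi, fj, i1, i2)
        } else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gene_id, iso_before = iso_b, iso_after = iso_a,
          switch_time = cr$time[m],
          prob = switch_probability(fi, fj, i1, i2),
          diff = switch_magnitude(fi, fj, i1, i2),
          pval = pv,
          cor = series_correlation(fi, fj),
          min_points = min(length(i1), length(i2)),
          n_before = length(i1), n_after = length(i2),
          idx_before = I(list(i1)), idx_after = I(list(i2))
        )
      }
    }
  }
  if (!length(rows)) return(empty_events())
  do.call(rbind, rows)
}

#' Detect switches across all genes of a time-course matrix
#'
#' Applies [score_gene()] to every gene with at least two isoforms.
#'
#' @inheritParams score_gene
#' @param genes Optional character vector restricting the gene set.
#' @return Combined switch-event `data.frame`.
#' @export
detect_switches <- function(x, genes = NULL, use_smoothing = TRUE,
                            degree = 4) {
  stopifnot(inherits(x, "time_course_matrix"))
  if (is.null(genes)) genes <- unique(x$tx2gene)
  counts <- table(x$tx2gene)
  genes <- genes[genes %in% names(counts)[counts >= 2]]
  out <- lapply(genes, function(g) {
    score_gene(x, g, use_smoothing = use_smoothing, degree = degree)
  })
  if (!length(out)) return(empty_events())
  do.call(rbind, out)
}

#' Switch-filter thresholds
#'
#' Defaults reproduce the study's filtering: probability >= 0.5, magnitude
#' S2 >= 1 TPM, p-value <= 0.001, at least 2 time points in each flanking
#' interval, correlation cutoff 0 (which disables the correlation filter;
#' see [filter_switches()]) and a switch-time window of 0-30 h of
#' experimental time.
#'
#' @param prob_min,diff_min,pval_max,min_points_min,cor_min Metric bounds.
#' @param time_lower,time_upper Switch-time window (hours, `time_lower <
#'   time_upper`).
#' @return A `switch_thresholds` list.
#' @export
switch_thresholds <- function(prob_min = 0.5, diff_min = 1,
                              pval_max = 0.001, min_points_min = 2,
                              cor_min = 0, time_lower = 0,
                              time_upper = 30) {
  vals <- c(prob_min, diff_min, pval_max, min_points_min, cor_min,
            time_lower, time_upper)
  if (any(!is.finite(vals))) stop("all thresholds must be finite")
  if (time_lower >= time_upper) stop("time_lower must be < time_upper")
  structure(
    list(prob_min = prob_min, diff_min = diff_min, pval_max = pval_max,
         min_points_min = min_points_min, cor_min = cor_min,
         time_lower = time_lower, time_upper = time_upper),
    class = "switch_thresholds"
  )
}

#' Filter switch events
#'
#' Conjunctive filter: an event is kept iff `prob >= prob_min`, `diff >=
#' diff_min`, `pval <= pval_max` (an undefined p-value fails), `min_points
#' >= min_points_min`, `|cor| >= cor_min` and `time_lower <= switch_time <=
#' time_upper`. The correlation bound is applied to the magnitude of the
#' correlation because genuinely switching isoform pairs are
#' anti-correlated (an antiphase pair has cor close to -1); a cutoff of 0
#' therefore disables the correlation filter rather than discarding every
#' true switch. Input order is preserved.
#'
#' @param events Switch-event `data.frame` from [detect_switches()].
#' @param thresholds A [switch_thresholds()] object.
#' @return The retained subset of `events`.
#' @export
filter_switches <- function(events, thresholds = switch_thresholds()) {
  if (!nrow(events)) return(events)
  th <- thresholds
  keep <- events$prob >= th$prob_min &
    events$diff >= th$diff_min &
    (!is.na(events$pval) & events$pval <= th$pval_max) &
    events$min_points >= th$min_points_min &
    abs(events$cor) >= th$cor_min &
    events$switch_time >= th$time_lower &
    events$switch_time <= th$time_upper
  events[keep, , drop = FALSE]
}

#' Write / read a switch-event table as TSV
#'
#' Columns: `gene_id`, `iso_before`, `iso_after`, `switch_time_h`, `prob`,
#' `diff_tpm`, `pval`, `cor`, `n_before`, `n_after`. Interval index sets
#' are not serialised.
#'
#' @param events Switch-event `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_switch_events <- function(events, path) {
  out <- data.frame(
    gene_id = events$gene_id, iso_before = events$iso_before,
    iso_after = events$iso_after,
    switch_time_h = sprintf("%.17g", events$switch_time),
    prob = sprintf("%.17g", events$prob),
    diff_tpm = sprintf("%.17g", events$diff),
    pval = sprintf("%.17g", events$pval),
    cor = sprintf("%.17g", events$cor),
    n_before = events$n_before, n_after = events$n_after
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_switch_events
#' @export
read_switch_events <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  data.frame(
    gene_id = tab$gene_id, iso_before = tab$iso_before,
    iso_after = tab$iso_after, switch_time = as.numeric(tab$switch_time_h),
    prob = as.numeric(tab$prob), diff = as.numeric(tab$diff_tpm),
    pval = as.numeric(tab$pval), cor = as.numeric(tab$cor),
    min_points = pmin(tab$n_before, tab$n_after),
    n_before = tab$n_before, n_after = tab$n_after
  )
}
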