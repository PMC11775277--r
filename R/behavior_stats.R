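# Population-level behavior statistics: ethograms, cumulative action
# probabilities, transition matrices, chi-square comparisons with
# Benjamini-Hochberg correction, and velocity-distribution comparisons.

#' Build an ethogram
#'
#' Discretizes refined action intervals onto a uniform time grid: each bin
#' takes the label of the interval covering its midpoint; bins with no
#' covering interval (tracking gaps) are marked \code{"untracked"}.  One row
#' per larva per bin.
#'
#' @param intervals refined action intervals.
#' @param trackset the \code{track_set} the intervals came from (defines the
#'   larva list and recording span).
#' @param bin_s bin width, s.
#' @return data frame (larva_id, t, label) of class \code{ethogram}; the
#'   bin width in \code{attr(, "bin_s")}.
#' @export
build_ethogram <- function(intervals, trackset, bin_s = 0.5) {
  check_intervals(intervals)
  spans <- lapply(trackset$tracks, function(tr) range(tr$t))
  lo <- min(vapply(spans, `[`, 0, 1)); hi <- max(vapply(spans, `[`, 0, 2))
  mids <- seq(lo + bin_s / 2, hi, by = bin_s)
  out <- do.call(rbind, lapply(names(trackset$tracks), function(id) {
    iv <- intervals[intervals$larva_id == id, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    lab <- rep("untracked", length(mids))
    if (nrow(iv)) {
      idx <- findInterval(mids, iv$start)
      ok <- idx > 0
      ok[ok] <- mids[ok] < iv$end[idx[ok]]
      lab[ok] <- iv$refined_label[idx[ok]]
    }
    data.frame(larva_id = id, t = mids, label = lab,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "bin_s") <- bin_s
  class(out) <- c("ethogram", "data.frame")
  out
}

#' Cumulative probability of an action in a window
#'
#' Probability that a larva performs at least one interval of \code{action}
#' overlapping the window, among larvae tracked at the window start (the
#' beginning of the stimulus): larvae not tracked at that moment enter
#' neither numerator nor denominator.
#'
#' @param intervals refined action intervals.
#' @param trackset the \code{track_set}.
#' @param action refined label.
#' @param window length-2 numeric, (t0, t1), half-open.
#' @return list(p, n, performers).
#' @export
cumulative_probability <- function(intervals, trackset, action, window) {
  ids <- tracked_at(trackset, window[1])
  if (!length(ids)) stop("no larvae tracked at window start")
  hit <- intervals$refined_label == action &
    intervals$start < window[2] & intervals$end > window[1] &
    intervals$larva_id %in% ids
  performers <- unique(intervals$larva_id[hit])
  list(p = length(performers) / length(ids), n = length(ids),
       performers = performers)
}

#' Transition matrix between consecutive actions
#'
#' Counts transitions between consecutive distinct actions whose transition
#' time (the start of the destination interval) falls within the window;
#' adjacent same-label intervals are merged first, so self-transitions are
#' impossible by construction.  Probabilities are row-normalized; cells
#' below \code{threshold} are flagged hidden for display but retained in the
#' data.
#'
#' @param intervals refined action intervals.
#' @param window length-2 numeric (s); transitions with destination start in
#'   \code{[window[1], window[2])} are counted.
#' @param threshold display threshold on probabilities (default 0.03: only
#'   transition probabilities of 3\% or more are shown).
#' @return list of class \code{transition_matrix}: \code{counts},
#'   \code{prob}, logical \code{hidden}, \code{window}, \code{threshold}.
#' @export
transition_matrix <- function(intervals, window = c(-Inf, Inf),
                              threshold = 0.03) {
  labs <- refined_labels()
  counts <- matrix(0L, length(labs), length(labs),
                   dimnames = list(from = labs, to = labs))
  for (id in unique(intervals$larva_id)) {
    iv <- intervals[intervals$larva_id == id, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    # merge adjacent same-label runs
    r <- rle(iv$refined_label)
    ends <- cumsum(r$lengths)
    starts <- c(1L, ends[-length(ends)] + 1L)
    lab <- r$values
    st <- iv$start[starts]
    if (length(lab) < 2) next
    for (k in seq_len(length(lab) - 1L)) {
      tt <- st[k + 1L]
      if (tt >= window[1] && tt < window[2])
        counts[lab[k], lab[k + 1L]] <- counts[lab[k], lab[k + 1L]] + 1L
    }
  }
  rs <- rowSums(counts)
  prob <- counts / ifelse(rs > 0, rs, NA)
  hidden <- !is.na(prob) & prob < threshold
  structure(list(counts = counts, prob = prob, hidden = hidden,
                 window = window, threshold = threshold),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  shown <- x$prob
  shown[x$hidden] <- NA
  keep <- rowSums(x$counts) > 0 | colSums(x$counts) > 0
  cat(sprintf("Transition probabilities (window [%g, %g), cells < %g%% hidden)\n",
              x$window[1], x$window[2], 100 * x$threshold))
  print(round(shown[keep, keep, drop = FALSE], 3))
  invisible(x)
}

#' Chi-square comparison of behavioral count tables
#'
#' Pearson chi-square test (two-sided, no continuity correction by default)
#' of an r x c table of condition by performed/not-performed counts.
#'
#' @param table integer matrix of counts with positive margins.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return list(chi2, df, p).
#' @export
chi2_compare <- function(table, correct = FALSE) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m))) stop("counts must be nonnegative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin in count table")
  ht <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control across a family of p-values, with a
#' pass-through mode for planned comparisons (where raw p-values are
#' reported unadjusted).
#'
#' @param pvalues numeric vector in [0, 1].
#' @param alpha FDR level for the rejection flags.
#' @param planned if TRUE, no adjustment is applied (a few planned
#'   comparisons are reported with raw p-values).
#' @return list(adjusted, reject).
#' @export
bh_adjust <- function(pvalues, alpha = 0.05, planned = FALSE) {
  if (any(pvalues < 0 | pvalues > 1 | is.na(pvalues)))
    stop("p-values must lie in [0, 1]")
  adj <- if (planned) pvalues else stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adj, reject = adj <= alpha)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' \eqn{D_{n,m} = \sup_x |F_n(x) - G_m(x)|} between the empirical
#' distribution functions of the two samples, with the asymptotic two-sided
#' p-value (exact small-sample p available via \code{exact = TRUE}).
#'
#' @param x,y numeric samples, both nonempty.
#' @param exact use the exact p-value computation.
#' @return list(D, p).
#' @export
ks_two_sample <- function(x, y, exact = FALSE) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  ht <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  list(D = unname(ht$statistic), p = unname(ht$p.value))
}

#' Gaussian kernel density estimate
#'
#' Scott's-rule bandwidth by default (\eqn{h = \hat\sigma n^{-1/5}}); falls
#' back to a fixed minimal bandwidth, with a warning, for zero-variance
#' samples.
#'
#' @param sample numeric, nonempty.
#' @param bandwidth numeric bandwidth, or \code{"scott"}.
#' @param n grid size.
#' @return data frame (x, density).
#' @export
kde_density <- function(sample, bandwidth = "scott", n = 512) {
  if (!length(sample)) stop("empty sample")
  if (identical(bandwidth, "scott")) {
    s <- stats::sd(sample)
    bandwidth <- if (is.na(s) || s == 0) {
      warning("zero-variance sample; using fixed minimal bandwidth")
      1e-3
    } else s * length(sample)^(-1 / 5)
  }
  stopifnot(bandwidth > 0)
  d <- stats::density(sample, bw = bandwidth, kernel = "gaussian", n = n,
                      cut = 4)
  data.frame(x = d$x, density = d$y)
}

#' Compare crawl speeds before and during stimulation
#'
#' Per-larva mean normalized centre-of-mass speed over Crawl intervals in
#' each window, compared with a two-sample Kolmogorov-Smirnov test.  Used to
#' detect stimulus-evoked Fast Crawls (crawling faster upon activation than
#' in the control window).
#'
#' @param trackset the \code{track_set}.
#' @param intervals refined action intervals.
#' @param series the matching \code{feature_series} (computed if NULL).
#' @param window_before,window_during length-2 windows, s.
#' @return list(before, during) of per-larva mean speeds, \code{ks} test
#'   result, and the two KDEs.
#' @export
crawl_speed_comparison <- function(trackset, intervals, series = NULL,
                                   window_before, window_during) {
  if (is.null(series)) series <- compute_features(trackset)
  speeds_in <- function(win) {
    crawl <- intervals[intervals$refined_label == "Crawl" &
                         intervals$start < win[2] &
                         intervals$end > win[1], , drop = FALSE]
    if (!nrow(crawl)) return(NULL)
    sapply(split(crawl, crawl$larva_id), function(iv) {
      s <- series[series$larva_id == iv$larva_id[1], , drop = FALSE]
      sel <- rep(FALSE, nrow(s))
      for (k in seq_len(nrow(iv))) {
        sel <- sel | (s$t >= max(iv$start[k], win[1]) &
                        s$t < min(iv$end[k], win[2]))
      }
      mean(s$v_motion[sel], na.rm = TRUE)
    })
  }
  before <- speeds_in(window_before)
  during <- speeds_in(window_during)
  if (is.null(before)) stop("no Crawl intervals in window_before")
  if (is.null(during)) stop("no Crawl intervals in window_during")
  before <- before[is.finite(before)]; during <- during[is.finite(during)]
  list(before = before, during = during,
       ks = ks_two_sample(before, during),
       kde_before = kde_density(before), kde_during = kde_density(during))
}
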