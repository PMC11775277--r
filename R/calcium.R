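# dF/F0 processing of calcium imaging traces.

split_traces <- function(traces) {
  key <- paste0(traces$larva_id, "_rep", traces$repetition)
  split(traces, factor(key, levels = unique(key)))
}

#' Compute dF/F0
#'
#' For each trace (larva x repetition), F0 is the mean fluorescence during
#' the baseline window (the pre-stimulus segment by default) and
#' \eqn{\Delta F/F_0 = (F(t) - F_0)/F_0} at each time step.
#'
#' @param traces data frame: larva_id, repetition, t, F, stim_onset,
#'   stim_duration.
#' @param baseline_window optional length-2 window (s); default: all
#'   \code{t < stim_onset}.
#' @return the traces with \code{dff} and \code{F0} columns.
#' @export
dff <- function(traces, baseline_window = NULL) {
  out <- do.call(rbind, lapply(split_traces(traces), function(tr) {
    base <- if (is.null(baseline_window)) tr$t < tr$stim_onset[1]
            else tr$t >= baseline_window[1] & tr$t < baseline_window[2]
    if (!any(base)) stop("empty baseline window for trace ",
                         tr$larva_id[1], " rep ", tr$repetition[1])
    f0 <- mean(tr$F[base])
    if (f0 <= 0) stop("nonpositive baseline F0 for trace ",
                      tr$larva_id[1], " rep ", tr$repetition[1])
    tr$F0 <- f0
    tr$dff <- (tr$F - f0) / f0
    tr
  }))
  rownames(out) <- NULL
  out[order(out$larva_id, out$repetition, out$t), , drop = FALSE]
}

#' Average repetitions per larva, then across larvae
#'
#' Means are calculated using the same number of repetitions per larva:
#' larvae with more repetitions than the minimum are subsampled (seeded) to
#' that minimum.  Returns the time-aligned grand mean with the standard
#' error across larvae, and the per-larva means with the standard error
#' across repetitions.
#'
#' @param traces dF/F0-annotated traces (\code{\link{dff}} output).
#' @param seed seed for the repetition subsample.
#' @return list: \code{t}, \code{mean}, \code{sem} (across larvae),
#'   \code{per_larva} matrix, \code{sem_reps} (across repetitions, pooled),
#'   \code{n_reps_used}.
#' @export
average_repetitions <- function(traces, seed = 1) {
  set.seed(seed)
  tt <- sort(unique(traces$t))
  bylarva <- split(traces, traces$larva_id)
  reps_per <- vapply(bylarva, function(d) length(unique(d$repetition)), 0L)
  r <- min(reps_per)
  per_larva <- sapply(bylarva, function(d) {
    reps <- sort(unique(d$repetition))
    use <- if (length(reps) > r) sort(sample(reps, r)) else reps
    m <- sapply(use, function(rep1) {
      dr <- d[d$repetition == rep1, , drop = FALSE]
      if (!isTRUE(all.equal(sort(dr$t), tt)))
        stop("misaligned time grids across traces")
      dr$dff[order(dr$t)]
    })
    rowMeans(m)
  })
  sem_reps <- sapply(bylarva, function(d) {
    m <- sapply(sort(unique(d$repetition)), function(rep1)
      d$dff[d$repetition == rep1][order(d$t[d$repetition == rep1])])
    apply(m, 1, stats::sd) / sqrt(ncol(m))
  })
  nl <- ncol(per_larva)
  list(t = tt, mean = rowMeans(per_larva),
       sem = apply(per_larva, 1, stats::sd) / sqrt(nl),
       per_larva = per_larva, sem_reps = rowMeans(sem_reps),
       n_reps_used = r)
}

#' Exclude traces with pre-stimulus activity
#'
#' Experiments showing activity before stimulation are removed: any trace
#' whose baseline |dF/F0| exceeds \code{threshold} at any pre-stimulus time
#' step is dropped; the exclusion log records which.
#'
#' @param traces dF/F0-annotated traces.
#' @param threshold baseline |dF/F0| bound (default 0.3).
#' @return filtered traces; excluded trace ids in
#'   \code{attr(, "excluded")}.
#' @export
exclude_prestim_active <- function(traces, threshold = 0.3) {
  parts <- split_traces(traces)
  bad <- vapply(parts, function(tr) {
    base <- tr$t < tr$stim_onset[1]
    any(abs(tr$dff[base]) > threshold)
  }, TRUE)
  out <- do.call(rbind, parts[!bad])
  if (is.null(out)) out <- traces[0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- names(parts)[bad]
  out
}
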