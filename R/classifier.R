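# Hierarchical action classification: a threshold-rule coarse base layer
# (stand-in for the upstream tracker's classifier, pluggable with external
# coarse labels) and a two-layer random-forest refinement of Bends and
# Hunches into the refined vocabulary.

new_action_intervals <- function(larva_id, start, end, coarse_label,
                                 refined_label = NA_character_,
                                 subtype = "none") {
  data.frame(larva_id = larva_id, start = start, end = end,
             coarse_label = coarse_label, refined_label = refined_label,
             subtype = subtype, stringsAsFactors = FALSE)
}

check_intervals <- function(intervals) {
  stopifnot(all(c("larva_id", "start", "end") %in% names(intervals)))
  if (any(intervals$end <= intervals$start)) stop("intervals must have end > start")
  for (id in unique(intervals$larva_id)) {
    iv <- intervals[intervals$larva_id == id, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)] - 1e-9))
      stop("overlapping intervals for larva ", id,
           " (actions must be mutually exclusive)")
  }
  invisible(intervals)
}

#' Coarse base classification of a feature series
#'
#' Tiles each larva's tracked span with coarse labels using documented
#' threshold rules on frame features (a stand-in base layer: Roll by
#' alternating bend side, Stop by all speeds near zero, Hunch by rapid
#' shortening of a straight body, Back by rearward centre-of-mass motion,
#' Bend by bend angle, Crawl otherwise).  Alternatively, externally supplied
#' coarse intervals are passed through unchanged.
#'
#' @param series a \code{feature_series} (one or more larvae).
#' @param config named list of rule thresholds; see defaults in the source.
#' @param coarse_intervals optional externally supplied coarse intervals
#'   (pass-through mode): returned as given after validation.
#' @return action-interval data frame (larva_id, start, end, coarse_label,
#'   refined_label, subtype).
#' @export
base_classify <- function(series, config = list(), coarse_intervals = NULL) {
  if (!is.null(coarse_intervals)) {
    check_intervals(coarse_intervals)
    return(coarse_intervals)
  }
  cfg <- utils::modifyList(list(
    stop_speed = 0.01, bend_angle = 30, sweep_head_speed = 0.3,
    hunch_dlen = -0.1, hunch_S = 0.85, quiet_com = 0.02,
    back_speed = 0.01, roll_flips_per_s = 3, roll_bend = 20), config)
  out <- lapply(split(seq_len(nrow(series)), series$larva_id), function(idx) {
    s <- series[idx, , drop = FALSE]
    n <- nrow(s)
    dt <- stats::median(diff(s$t))
    lab <- rep(NA_character_, n)
    bend <- abs(s$bend_angle)
    # bend-side flip rate and mean bend over a 1 s window (Roll signature)
    side <- sign(s$bend_angle)
    flip <- c(0, as.numeric(side[-1] * side[-n] < 0))
    w <- max(3L, round(1 / dt))
    flips <- roll_mean(flip, w) / dt
    mbend <- roll_mean(bend, w)
    ok <- s$valid & is.finite(s$v_motion)
    lab[ok] <- "Crawl"
    lab[ok & bend >= cfg$bend_angle] <- "Bend"
    lab[ok & s$v_head >= cfg$sweep_head_speed &
          s$v_head > 5 * s$v_motion & bend > 5] <- "Bend"  # head sweep
    lab[ok & s$v_com_forward < -cfg$back_speed &
          s$v_motion > cfg$stop_speed] <- "Back"
    lab[ok & s$dlen < cfg$hunch_dlen & s$S > cfg$hunch_S &
          s$v_motion < cfg$quiet_com] <- "Hunch"
    lab[ok & s$v_head < cfg$stop_speed & s$v_motion < cfg$stop_speed &
          s$v_tail < cfg$stop_speed & bend < cfg$bend_angle] <- "Stop"
    lab[ok & flips >= cfg$roll_flips_per_s & mbend >= cfg$roll_bend] <- "Roll"
    # run-length encode into intervals; NA frames break runs
    r <- rle(ifelse(is.na(lab), "<gap>", lab))
    ends <- cumsum(r$lengths)
    starts <- c(1L, ends[-length(ends)] + 1L)
    keep <- r$values != "<gap>"
    if (!any(keep)) return(NULL)
    new_action_intervals(s$larva_id[1], s$t[starts[keep]],
                         s$t[ends[keep]] + dt, r$values[keep])
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Aggregate features for every action interval
#'
#' @param intervals action-interval data frame.
#' @param series matching \code{feature_series}.
#' @param context context frames per side (default 5).
#' @return data frame, one row of aggregated features per interval, in the
#'   same order.
#' @export
interval_features <- function(intervals, series, context = 5L) {
  bylarva <- split(series, series$larva_id)
  rows <- lapply(seq_len(nrow(intervals)), function(i) {
    s <- bylarva[[intervals$larva_id[i]]]
    if (is.null(s)) stop("no feature series for larva ", intervals$larva_id[i])
    aggregate_action_features(s, intervals[i, ], context = context)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Auto-tag training intervals
#'
#' Implements the automatic annotation rules used to build refinement
#' training data: Head Casts are sampled randomly from Bends occurring
#' before the stimulus; Static Bends are Bends during stimulation whose
#' length-normalized motion speed stays below \code{speed_threshold}
#' (0.02 s^-1) for at least half of the action's frames -- a deliberately
#' low threshold so erroneous annotations do not steer the ensembles.
#' Hunch, Head-and-Tail and C-shape tags are taken from \code{truth}
#' (synthetic ground truth standing in for manual annotation): an interval
#' inherits the truth label covering its midpoint when that label is one of
#' the three.
#'
#' @param intervals coarse action intervals.
#' @param series matching \code{feature_series}.
#' @param protocol a \code{\link{stimulus_protocol}}.
#' @param seed integer seed for the random Head Cast sample.
#' @param truth optional ground-truth intervals (larva_id, start, end,
#'   label).
#' @param speed_threshold normalized motion-speed threshold, s^-1.
#' @param min_slow_fraction fraction of frames that must be below threshold.
#' @param n_headcast number of pre-stimulus Bends to sample as Head Casts
#'   (default: all of them).
#' @return subset of \code{intervals} with a \code{tag} column.
#' @export
auto_tag_training <- function(intervals, series, protocol, seed = 1,
                              truth = NULL, speed_threshold = 0.02,
                              min_slow_fraction = 0.5, n_headcast = NULL) {
  set.seed(seed)
  onset <- protocol$onset[1]
  stim_end <- onset + protocol$duration[1]
  bylarva <- split(series, series$larva_id)
  slow_frac <- vapply(seq_len(nrow(intervals)), function(i) {
    s <- bylarva[[intervals$larva_id[i]]]
    v <- s$v_motion[s$t >= intervals$start[i] & s$t < intervals$end[i]]
    v <- v[is.finite(v)]
    if (!length(v)) return(NA_real_)
    mean(v < speed_threshold)
  }, 0)

  tag <- rep(NA_character_, nrow(intervals))
  # manually-tagged classes first (ground truth stands in for the manual
  # annotation): an interval carrying one of these labels is never
  # auto-tagged
  if (!is.null(truth)) {
    mid <- (intervals$start + intervals$end) / 2
    for (i in which(intervals$coarse_label %in% c("Bend", "Hunch"))) {
      tv <- truth[truth$larva_id == intervals$larva_id[i] &
                    truth$start <= mid[i] & truth$end > mid[i], ]
      if (nrow(tv) == 1 && tv$label %in% c("Hunch", "HeadAndTail", "CShape"))
        tag[i] <- tv$label
    }
  }

  is_bend <- intervals$coarse_label == "Bend" & is.na(tag)
  pre <- is_bend & intervals$end <= onset
  during <- is_bend & intervals$start >= onset & intervals$start < stim_end

  tag[during & !is.na(slow_frac) & slow_frac >= min_slow_fraction] <-
    "StaticBend"

  hc_pool <- which(pre)
  if (!length(hc_pool)) {
    warning("no pre-stimulus Bends available for Head Cast tagging")
  } else {
    k <- if (is.null(n_headcast)) length(hc_pool)
         else min(n_headcast, length(hc_pool))
    tag[sample(hc_pool, k)] <- "HeadCast"
  }
  out <- intervals[!is.na(tag), , drop = FALSE]
  out$tag <- tag[!is.na(tag)]
  rownames(out) <- NULL
  out
}

#' Fit the two-layer refinement model
#'
#' Random-forest refinement of coarse Bend/Hunch actions.  The first layer
#' separates Bends and Hunches into new Hunches, Static Bends and Head
#' Casts; the second layer categorizes the new Hunches into Hunch,
#' Head-and-Tail and C-shape.  With \code{layer1_classes = 4}, C-shape is
#' instead a first-layer class.
#'
#' @param training data frame: aggregated interval features plus a
#'   \code{tag} column with the provisional refined label.
#' @param hyperparams list: \code{ntree} (default 300), \code{mtry}
#'   (default sqrt of feature count), \code{layer1_classes} 3 or 4,
#'   \code{min_per_class} minimum training examples per class (default 20).
#' @param seed integer seed.
#' @return an object of class \code{refinement_model}.
#' @export
train_refinement <- function(training, hyperparams = list(), seed = 1) {
  hp <- utils::modifyList(list(ntree = 300, mtry = NULL, layer1_classes = 3,
                               min_per_class = 20), hyperparams)
  stopifnot("tag" %in% names(training))
  l1_direct <- c("HeadCast", "StaticBend",
                 if (hp$layer1_classes == 4) "CShape")
  l2_classes <- setdiff(c("Hunch", "HeadAndTail", "CShape"), l1_direct)
  y1 <- ifelse(training$tag %in% l1_direct, training$tag, "newHunch")
  need1 <- c(l1_direct, "newHunch")
  cnt1 <- table(factor(y1, levels = need1))
  cnt2 <- table(factor(training$tag[y1 == "newHunch"], levels = l2_classes))
  short <- c(names(cnt1)[cnt1 < hp$min_per_class],
             names(cnt2)[cnt2 < hp$min_per_class])
  if (length(short))
    stop("insufficient training examples (< ", hp$min_per_class,
         ") for class(es): ", paste(unique(short), collapse = ", "))

  fcols <- names(training)[vapply(training, is.numeric, TRUE)]
  fcols <- setdiff(fcols, c("start", "end"))
  X <- as.matrix(training[, fcols, drop = FALSE])
  med <- apply(X, 2, function(v) {
    m <- stats::median(v[is.finite(v)])
    if (is.finite(m)) m else 0
  })
  for (j in seq_along(fcols)) X[!is.finite(X[, j]), j] <- med[j]
  mtry <- hp$mtry %||% max(1L, floor(sqrt(ncol(X))))

  set.seed(seed)
  layer1 <- randomForest::randomForest(
    x = X, y = factor(y1, levels = sort(need1)), ntree = hp$ntree,
    mtry = mtry)
  i2 <- y1 == "newHunch"
  layer2 <- randomForest::randomForest(
    x = X[i2, , drop = FALSE],
    y = factor(training$tag[i2], levels = sort(l2_classes)),
    ntree = hp$ntree, mtry = mtry)

  structure(list(layer1 = layer1, layer2 = layer2, feature_cols = fcols,
                 impute = med, layer1_classes = hp$layer1_classes,
                 hyperparams = hp, seed = seed,
                 n_training = nrow(training)),
            class = "refinement_model")
}

rf_oob_acc <- function(rf) {
  cm <- rf$confusion[, rownames(rf$confusion), drop = FALSE]
  diag(cm) / rowSums(cm)
}

#' @export
print.refinement_model <- function(x, ...) {
  cat("Two-layer action refinement model (random forests)\n")
  cat(sprintf("  layer 1: %s  (ntree = %d)\n",
              paste(colnames(x$layer1$confusion)[
                seq_len(nrow(x$layer1$confusion))], collapse = " / "),
              x$layer1$ntree))
  cat(sprintf("  layer 2: %s\n",
              paste(colnames(x$layer2$confusion)[
                seq_len(nrow(x$layer2$confusion))], collapse = " / ")))
  cat(sprintf("  trained on %d intervals, seed %d\n", x$n_training, x$seed))
  invisible(x)
}

#' @export
summary.refinement_model <- function(object, ...) {
  cat("Out-of-bag class accuracy\n  layer 1:\n")
  print(round(rf_oob_acc(object$layer1), 3))
  cat("  layer 2:\n")
  print(round(rf_oob_acc(object$layer2), 3))
  invisible(list(layer1 = rf_oob_acc(object$layer1),
                 layer2 = rf_oob_acc(object$layer2)))
}

#' Predict refined labels from aggregated interval features
#'
#' @param object a \code{refinement_model}.
#' @param newdata data frame of aggregated interval features
#'   (\code{\link{interval_features}} output).
#' @param ... unused.
#' @return character vector of refined labels.
#' @export
predict.refinement_model <- function(object, newdata, ...) {
  miss <- setdiff(object$feature_cols, names(newdata))
  if (length(miss))
    stop("feature schema mismatch; missing column(s): ",
         paste(miss, collapse = ", "))
  X <- as.matrix(newdata[, object$feature_cols, drop = FALSE])
  for (j in seq_along(object$feature_cols))
    X[!is.finite(X[, j]), j] <- object$impute[j]
  p1 <- as.character(predict(object$layer1, X))
  out <- p1
  i2 <- p1 == "newHunch"
  if (any(i2))
    out[i2] <- as.character(predict(object$layer2, X[i2, , drop = FALSE]))
  out
}

#' Refine coarse intervals with a trained model
#'
#' Every Bend/Hunch interval is assigned a refined label by layer 1 and, if
#' layer 1 says new Hunch, layer 2.  Other coarse labels map one-to-one
#' (Crawl to Crawl, Back to BackUp, Stop to Stop, Roll to Roll).  Refined
#' Head Casts get a slow/fast subtype from the ratio of mean tail speed to
#' mean centre-of-mass speed.
#'
#' @param intervals coarse action intervals.
#' @param series matching \code{feature_series}.
#' @param model a \code{\link{train_refinement}} fit.
#' @param fast_tail_speed normalized tail-speed threshold (s^-1) above
#'   which a Head Cast is subtyped "fast".
#' @return the intervals with \code{refined_label} and \code{subtype}
#'   filled in.
#' @export
refine <- function(intervals, series, model, fast_tail_speed = 0.08) {
  check_intervals(intervals)
  out <- intervals
  if (is.null(out$refined_label)) out$refined_label <- NA_character_
  if (is.null(out$subtype)) out$subtype <- "none"
  map <- c(Crawl = "Crawl", Back = "BackUp", Stop = "Stop", Roll = "Roll")
  direct <- out$coarse_label %in% names(map)
  out$refined_label[direct] <- map[out$coarse_label[direct]]
  todo <- which(out$coarse_label %in% c("Bend", "Hunch"))
  if (length(todo)) {
    fx <- interval_features(out[todo, , drop = FALSE], series)
    out$refined_label[todo] <- predict(model, fx)
    hc <- todo[out$refined_label[todo] == "HeadCast"]
    if (length(hc)) {
      vt <- fx$v_tail_mean[match(hc, todo)]
      out$subtype[hc] <- ifelse(vt > fast_tail_speed, "fast", "slow")
    }
  }
  out
}

#' Evaluate refined intervals against ground truth
#'
#' Frame-weighted confusion matrix over the refined vocabulary: both
#' labelings are sampled on a uniform grid and agreement is scored per grid
#' point, so long actions weigh proportionally to their duration.
#'
#' @param predicted refined action intervals (\code{refined_label} set).
#' @param truth ground-truth intervals (\code{label} column).
#' @param bin grid step, s.
#' @return list of class \code{classification_eval}: \code{confusion},
#'   per-class \code{precision}, \code{recall}, \code{f1}, and
#'   \code{macro_f1}.
#' @export
evaluate_classification <- function(predicted, truth, bin = 0.1) {
  ids <- union(unique(predicted$larva_id), unique(truth$larva_id))
  labs <- refined_labels()
  cm <- matrix(0L, length(labs), length(labs), dimnames = list(
    truth = labs, predicted = labs))
  label_at <- function(iv, labcol, tt) {
    idx <- findInterval(tt, iv$start)
    lab <- rep(NA_character_, length(tt))
    ok <- idx > 0
    ok[ok] <- tt[ok] < iv$end[idx[ok]]
    lab[ok] <- iv[[labcol]][idx[ok]]
    lab
  }
  for (id in ids) {
    pv <- predicted[predicted$larva_id == id, , drop = FALSE]
    tv <- truth[truth$larva_id == id, , drop = FALSE]
    if (!nrow(pv) || !nrow(tv)) next
    pv <- pv[order(pv$start), , drop = FALSE]
    tv <- tv[order(tv$start), , drop = FALSE]
    lo <- max(min(pv$start), min(tv$start))
    hi <- min(max(pv$end), max(tv$end))
    if (hi <= lo) next
    tt <- seq(lo + bin / 2, hi, by = bin)
    pl <- label_at(pv, "refined_label", tt)
    tl <- label_at(tv, "label", tt)
    keep <- !is.na(pl) & !is.na(tl)
    if (any(keep))
      cm <- cm + table(factor(tl[keep], labs), factor(pl[keep], labs))
  }
  prec <- diag(cm) / pmax(colSums(cm), 1e-12)
  rec <- diag(cm) / pmax(rowSums(cm), 1e-12)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  present <- rowSums(cm) > 0
  structure(list(confusion = cm, precision = prec, recall = rec, f1 = f1,
                 macro_f1 = mean(f1[present])),
            class = "classification_eval")
}

#' @export
print.classification_eval <- function(x, ...) {
  present <- rowSums(x$confusion) > 0 | colSums(x$confusion) > 0
  cat("Frame-weighted confusion (truth rows x predicted columns)\n")
  print(x$confusion[present, present, drop = FALSE])
  cat(sprintf("macro-F1 over present classes: %.3f\n", x$macro_f1))
  invisible(x)
}
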