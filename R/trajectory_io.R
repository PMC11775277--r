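# -- Track data model ---------------------------------------------------------

#' Construct a single-larva track
#'
#' A track holds the time series of midline ("spine") points produced by a
#' tracker for one larva: K ordered points from head to tail per frame, an
#' optional body-outline contour, and a per-frame validity flag.  Frames where
#' the tracker lost the animal are kept (time axis intact) but flagged
#' \code{valid = FALSE}.
#'
#' @param larva_id character scalar identifier.
#' @param t numeric vector of frame times in seconds, strictly increasing.
#' @param x,y numeric matrices (frames x K) of spine point coordinates in mm,
#'   column 1 the head, column K the tail.
#' @param valid logical vector, one per frame; defaults to frames with all
#'   spine coordinates finite.
#' @param contour optional list (one element per frame) of two-column matrices
#'   giving the closed outline polygon, or \code{NULL}.
#' @param frame_rate nominal acquisition rate in Hz.
#' @return an object of class \code{larva_track}.
#' @export
larva_track <- function(larva_id, t, x, y, valid = NULL, contour = NULL,
                        frame_rate = 10) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(is.character(larva_id), length(larva_id) == 1L,
            nrow(x) == length(t), nrow(y) == length(t),
            ncol(x) == ncol(y), ncol(x) >= 3L)
  if (any(diff(t) <= 0))
    stop("frame times must be strictly increasing for larva ", larva_id)
  if (is.null(valid)) {
    valid <- rowSums(!is.finite(x)) == 0 & rowSums(!is.finite(y)) == 0
  }
  stopifnot(length(valid) == length(t))
  if (any(valid & (rowSums(!is.finite(x)) > 0 | rowSums(!is.finite(y)) > 0)))
    stop("valid frames must have finite spine coordinates (larva ",
         larva_id, ")")
  structure(list(larva_id = larva_id, t = as.numeric(t), x = x, y = y,
                 valid = as.logical(valid), contour = contour,
                 frame_rate = frame_rate),
            class = "larva_track")
}

#' @export
print.larva_track <- function(x, ...) {
  cat(sprintf("<larva_track> id=%s  frames=%d (%.1f%% valid)  K=%d  %.1f Hz\n",
              x$larva_id, length(x$t), 100 * mean(x$valid), ncol(x$x),
              x$frame_rate))
  invisible(x)
}

#' Per-frame body length of a track
#'
#' Sum of consecutive spine point distances; \code{NA} on invalid frames.
#'
#' @param track a \code{larva_track}.
#' @return numeric vector, mm per frame.
#' @export
track_length <- function(track) {
  K <- ncol(track$x)
  dx <- track$x[, -1, drop = FALSE] - track$x[, -K, drop = FALSE]
  dy <- track$y[, -1, drop = FALSE] - track$y[, -K, drop = FALSE]
  len <- rowSums(sqrt(dx^2 + dy^2))
  len[!track$valid] <- NA_real_
  len
}

#' Stimulus protocol
#'
#' Epochs of stimulation: modality (\code{"air_puff"} or \code{"light"}),
#' onset and duration in seconds, intensity in modality units (m/s for air
#' puff, mW/cm2 for light).  A typical assay delivers the air puff at the
#' 60th second for 30 seconds.
#'
#' @param modality character vector.
#' @param onset,duration numeric vectors, seconds.
#' @param intensity numeric vector.
#' @return a \code{stimulus_protocol} data frame.
#' @export
stimulus_protocol <- function(modality = "air_puff", onset = 60,
                              duration = 30, intensity = 4) {
  stopifnot(all(onset >= 0), all(duration > 0))
  p <- data.frame(modality = modality, onset = onset, duration = duration,
                  intensity = intensity, stringsAsFactors = FALSE)
  for (m in unique(p$modality)) {
    e <- p[p$modality == m, , drop = FALSE]
    e <- e[order(e$onset), , drop = FALSE]
    if (nrow(e) > 1 && any(e$onset[-1] < (e$onset + e$duration)[-nrow(e)]))
      stop("overlapping epochs for modality ", m)
  }
  class(p) <- c("stimulus_protocol", "data.frame")
  p
}

#' Read / write a stimulus protocol config (YAML or JSON)
#' @param path file path; format chosen by extension (.yaml/.yml or .json).
#' @return a \code{stimulus_protocol}.
#' @export
read_protocol <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  ep <- raw$epochs
  if (is.data.frame(ep)) {
    stimulus_protocol(ep$modality, ep$onset, ep$duration, ep$intensity)
  } else {
    stimulus_protocol(vapply(ep, `[[`, "", "modality"),
                      vapply(ep, `[[`, 0, "onset"),
                      vapply(ep, `[[`, 0, "duration"),
                      vapply(ep, `[[`, 0, "intensity"))
  }
}

#' @rdname read_protocol
#' @param protocol a \code{stimulus_protocol} to serialize.
#' @export
write_protocol <- function(protocol, path) {
  obj <- list(epochs = lapply(seq_len(nrow(protocol)), function(i)
    as.list(protocol[i, , drop = FALSE])))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(obj, path)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Bundle tracks with their stimulus protocol
#'
#' @param tracks list of \code{larva_track} objects with unique ids.
#' @param protocol a \code{stimulus_protocol} (or \code{NULL}).
#' @param condition_label free-text genotype/stimulus condition label.
#' @return a \code{track_set}.
#' @export
track_set <- function(tracks, protocol = NULL, condition_label = "") {
  ids <- vapply(tracks, `[[`, "", "larva_id")
  if (anyDuplicated(ids)) stop("duplicate larva_ids in track set")
  names(tracks) <- ids
  structure(list(tracks = tracks, protocol = protocol,
                 condition_label = condition_label),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracks%s\n", length(x$tracks),
              if (nzchar(x$condition_label))
                paste0("  [", x$condition_label, "]") else ""))
  invisible(x)
}

# -- TSV dialect --------------------------------------------------------------
# One row per (larva, frame).  Columns: larva_id, t, x1,y1 ... xK,yK, contour
# (semicolon-joined "x,y" pairs, may be empty).  Invalid frames have blank
# spine columns.  Modeled on flat Multi-Worm-Tracker/Choreography exports.

fmt_num <- function(v) ifelse(is.na(v), "", sprintf("%.12g", v))

#' Write a track set to the tab-separated spine/contour dialect
#'
#' @param trackset a \code{track_set}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_track_table <- function(trackset, path) {
  K <- if (length(trackset$tracks))
    ncol(trackset$tracks[[1]]$x) else 11L
  hdr <- c("larva_id", "t",
           as.vector(rbind(paste0("x", 1:K), paste0("y", 1:K))), "contour")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = "\t"), con)
  for (tr in trackset$tracks) {
    n <- length(tr$t)
    xy <- matrix("", n, 2L * K)
    xm <- tr$x; ym <- tr$y
    xm[!tr$valid, ] <- NA; ym[!tr$valid, ] <- NA
    xy[, seq(1, 2 * K, 2)] <- fmt_num(xm)
    xy[, seq(2, 2 * K, 2)] <- fmt_num(ym)
    ctr <- rep("", n)
    if (!is.null(tr$contour)) {
      ctr <- vapply(seq_len(n), function(i) {
        cm <- tr$contour[[i]]
        if (is.null(cm)) "" else
          paste(sprintf("%.12g,%.12g", cm[, 1], cm[, 2]), collapse = ";")
      }, "")
    }
    rows <- cbind(tr$larva_id, fmt_num(tr$t), xy, ctr)
    writeLines(apply(rows, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read the tab-separated spine/contour dialect
#'
#' One \code{larva_track} is built per distinct \code{larva_id}; frames are
#' sorted by time on read and frames with blank spine columns are kept but
#' flagged invalid (a tracking dropout, not a data loss).
#'
#' @param path input file.
#' @param frame_rate nominal rate (Hz) recorded on each track.
#' @return a \code{track_set} (protocol unset).
#' @export
read_track_table <- function(path, frame_rate = 10) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  K <- sum(grepl("^x[0-9]+$", hdr))
  if (K < 3) stop("malformed header: fewer than 3 spine points")
  ncol_exp <- length(hdr)
  body <- lines[-1]
  if (!length(body))
    return(track_set(list(), condition_label = ""))
  parts <- strsplit(body, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    np <- length(parts[[i]])
    if (np == ncol_exp - 1L) parts[[i]] <- c(parts[[i]], "")  # empty contour
    else if (np != ncol_exp)
      stop("malformed row at line ", i + 1L, ": expected ", ncol_exp,
           " fields, got ", np)
  }
  m <- do.call(rbind, parts)
  ids <- m[, 1L]
  tracks <- lapply(unique(ids), function(id) {
    rows <- m[ids == id, , drop = FALSE]
    tt <- as.numeric(rows[, 2L])
    if (anyNA(tt)) stop("malformed time at line ",
                        which(ids == id)[which(is.na(tt))[1]] + 1L)
    o <- order(tt)
    rows <- rows[o, , drop = FALSE]; tt <- tt[o]
    spine <- suppressWarnings(
      matrix(as.numeric(rows[, 2L + seq_len(2L * K)]), nrow = nrow(rows)))
    x <- spine[, seq(1, 2 * K, 2), drop = FALSE]
    y <- spine[, seq(2, 2 * K, 2), drop = FALSE]
    blank <- rows[, 2L + seq_len(2L * K), drop = FALSE] == ""
    valid <- rowSums(blank) == 0
    if (any(valid & (rowSums(is.na(x)) > 0 | rowSums(is.na(y)) > 0)))
      stop("malformed spine coordinates for larva ", id)
    partial <- rowSums(blank) > 0 & rowSums(blank) < 2L * K
    if (any(partial))
      stop("inconsistent spine point count within larva ", id)
    ctr <- lapply(rows[, ncol_exp], function(s) {
      if (!nzchar(s)) return(NULL)
      pairs <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ",", fixed = TRUE)
      matrix(as.numeric(unlist(pairs)), ncol = 2L, byrow = TRUE)
    })
    if (all(vapply(ctr, is.null, TRUE))) ctr <- NULL
    larva_track(id, tt, x, y, valid = valid, contour = ctr,
                frame_rate = frame_rate)
  })
  track_set(tracks)
}

#' Larvae tracked at a given time
#'
#' Returns the ids of larvae with a valid frame at time \code{t} (the nearest
#' frame, within half a frame period).  Used as the denominator for cumulative
#' action probabilities, which count only larvae tracked at the beginning of
#' the stimulus.
#'
#' @param trackset a \code{track_set}.
#' @param t time in seconds.
#' @return character vector of larva ids.
#' @export
tracked_at <- function(trackset, t) {
  hit <- vapply(trackset$tracks, function(tr) {
    if (!length(tr$t)) return(FALSE)
    i <- which.min(abs(tr$t - t))
    abs(tr$t[i] - t) <= 0.5 / tr$frame_rate + 1e-9 && tr$valid[i]
  }, TRUE)
  names(trackset$tracks)[hit]
}
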