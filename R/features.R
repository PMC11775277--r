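# Kinematic posture features.  All speed-like features are normalized by the
# larva's instantaneous body length so they are scale-free (units s^-1).

#' Spine order parameter
#'
#' Nematic order of the spine segments with respect to the body axis:
#' \deqn{S = \tfrac{1}{2}(3 \langle \cos^2\theta \rangle - 1)}
#' where \eqn{\theta} is the angle between each normalized spine segment and
#' the normalized body-axis direction.  \eqn{S = 1} for a straight larva,
#' \eqn{S = -0.5} when every segment is orthogonal to the axis.
#'
#' @param spine_points numeric K x 2 matrix of midline points, head first.
#' @param body_axis length-2 vector giving the body-axis direction
#'   (default: tail-to-head vector).
#' @return scalar in [-0.5, 1].
#' @export
spine_order_parameter <- function(spine_points,
                                  body_axis = spine_points[1, ] -
                                    spine_points[nrow(spine_points), ]) {
  p <- as.matrix(spine_points)
  if (nrow(p) < 2) stop("need at least 2 spine points")
  an <- sqrt(sum(body_axis^2))
  if (an == 0) stop("zero body axis")
  seg <- p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
  sl <- sqrt(rowSums(seg^2))
  keep <- sl > 0
  if (!any(keep)) stop("all spine segments have zero length")
  cth <- (seg[keep, , drop = FALSE] %*% (body_axis / an)) / sl[keep]
  0.5 * (3 * mean(cth^2) - 1)
}

#' Movement shape factor
#'
#' Eigenvalue anisotropy \eqn{\lambda = (\lambda_1-\lambda_2)/(\lambda_1+
#' \lambda_2)} of the 2x2 covariance matrix of centre-of-mass movement:
#' 0 for isotropic motion, 1 for purely linear motion.
#'
#' @param movement_covariance symmetric positive semidefinite 2x2 matrix.
#' @return scalar in [0, 1]; 0 for a degenerate (all-zero) covariance.
#' @export
shape_factor <- function(movement_covariance) {
  m <- as.matrix(movement_covariance)
  stopifnot(all(dim(m) == 2L))
  if (abs(m[1, 2] - m[2, 1]) > 1e-8 * (1 + max(abs(m))))
    stop("covariance matrix must be symmetric")
  tr <- m[1, 1] + m[2, 2]
  if (tr <= 0) return(0)
  sqrt((m[1, 1] - m[2, 2])^2 + 4 * m[1, 2]^2) / tr
}

#' Head/tail length ratio
#'
#' \eqn{\lVert HG\rVert / \lVert TG\rVert} with H the head (first spine
#' point), T the tail (last) and G the centre of mass (mean of spine points).
#'
#' @param spine_points numeric K x 2 matrix.
#' @return positive scalar.
#' @export
length_ratio <- function(spine_points) {
  p <- as.matrix(spine_points)
  g <- colMeans(p)
  dt <- sqrt(sum((p[nrow(p), ] - g)^2))
  if (dt == 0) stop("degenerate posture: tail coincides with centre of mass")
  sqrt(sum((p[1, ] - g)^2)) / dt
}

#' Projection of an end-point velocity onto the spine
#'
#' The velocity endpoint (point + velocity vector) is projected onto the
#' spine polyline by the closest-point rule; the returned value is the signed
#' component of the velocity along the closest segment's direction (positive
#' toward the tail), normalized by the larva's length.  The residual
#' point-to-polyline distance is available as attribute \code{"residual"}.
#'
#' @param velocity length-2 velocity vector (mm/s).
#' @param spine_points K x 2 matrix, head first.
#' @param point the end whose velocity this is (default the head, row 1).
#' @param length larva length for normalization (default: polyline length).
#' @return signed scalar, s^-1.
#' @export
velocity_spine_projection <- function(velocity, spine_points,
                                      point = spine_points[1, ],
                                      length = NULL) {
  p <- as.matrix(spine_points)
  K <- nrow(p)
  seg <- p[-1, , drop = FALSE] - p[-K, , drop = FALSE]
  sl2 <- rowSums(seg^2)
  if (all(sl2 == 0)) stop("zero spine")
  if (is.null(length)) length <- sum(sqrt(sl2))
  tip <- point + velocity
  rel <- matrix(tip, K - 1L, 2L, byrow = TRUE) - p[-K, , drop = FALSE]
  u <- pmin(pmax(rowSums(rel * seg) / pmax(sl2, .Machine$double.eps), 0), 1)
  dd <- rowSums((rel - seg * u)^2)
  dd[sl2 == 0] <- Inf
  j <- which.min(dd)
  proj <- sum(velocity * seg[j, ]) / sqrt(sl2[j]) / length
  structure(proj, residual = sqrt(dd[j]) / length)
}

#' Cosine between a velocity vector and a spine segment
#'
#' For the head the first spine segment is used, for the tail the last:
#' \eqn{\cos\theta = (r_{s} \cdot v) / (\lVert r_s\rVert \lVert v \rVert)}.
#'
#' @param velocity length-2 velocity vector.
#' @param segment length-2 spine segment vector.
#' @return scalar in [-1, 1]; \code{NA} if either vector is zero.
#' @export
velocity_segment_cosine <- function(velocity, segment) {
  nv <- sqrt(sum(velocity^2)); ns <- sqrt(sum(segment^2))
  if (nv == 0 || ns == 0) return(NA_real_)
  max(-1, min(1, sum(velocity * segment) / (nv * ns)))
}

# rolling mean over a centered window, NA at ends filled with shrunk window
roll_mean <- function(v, w) {
  n <- length(v)
  half <- w %/% 2L
  cs <- cumsum(c(0, ifelse(is.na(v), 0, v)))
  cn <- cumsum(c(0, !is.na(v)))
  lo <- pmax(seq_len(n) - half, 1L); hi <- pmin(seq_len(n) + half, n)
  num <- cs[hi + 1L] - cs[lo]
  den <- cn[hi + 1L] - cn[lo]
  ifelse(den > 0, num / den, NA_real_)
}

#' Per-frame kinematic feature series for one track
#'
#' Computes length-normalized head/centre-of-mass/tail speeds, the spine
#' order parameter, the movement shape factor (over a sliding window of
#' centre-of-mass displacements), the head/tail length ratio, spine
#' projections and segment cosines of the end-point velocities, the signed
#' forward speed of the centre of mass, the bend angle between the
#' centre-to-head and centre-to-tail directions, and the relative length
#' change rate.  Velocities use central differences over \code{stencil}
#' frames (one-sided at track ends); all entries are \code{NA} on or next to
#' invalid frames.
#'
#' @param track a \code{larva_track}.
#' @param window sliding-window width (frames) for the shape factor.
#' @param stencil half-width (frames) of the central-difference velocity
#'   estimator.
#' @return a data frame (one row per frame) of class \code{feature_series}.
#' @export
compute_frame_features <- function(track, window = 5L, stencil = 1L) {
  n <- length(track$t)
  if (n <= 2L * stencil) stop("track shorter than velocity stencil")
  K <- ncol(track$x)
  len <- track_length(track)
  gx <- rowMeans(track$x); gy <- rowMeans(track$y)
  hx <- track$x[, 1]; hy <- track$y[, 1]
  tx <- track$x[, K]; ty <- track$y[, K]
  gx[!track$valid] <- NA; gy[!track$valid] <- NA
  hx[!track$valid] <- NA; hy[!track$valid] <- NA
  tx[!track$valid] <- NA; ty[!track$valid] <- NA

  cdiff <- function(v) {
    s <- stencil
    lo <- pmax(seq_len(n) - s, 1L); hi <- pmin(seq_len(n) + s, n)
    (v[hi] - v[lo]) / (track$t[hi] - track$t[lo])
  }
  vhx <- cdiff(hx); vhy <- cdiff(hy)
  vgx <- cdiff(gx); vgy <- cdiff(gy)
  vtx <- cdiff(tx); vty <- cdiff(ty)
  dlen <- cdiff(len) / len

  v_head <- sqrt(vhx^2 + vhy^2) / len
  v_motion <- sqrt(vgx^2 + vgy^2) / len
  v_tail <- sqrt(vtx^2 + vty^2) / len

  # body axis: tail -> head
  ax <- hx - tx; ay <- hy - ty
  an <- sqrt(ax^2 + ay^2)
  v_com_forward <- (vgx * ax + vgy * ay) / an / len

  # spine order parameter, vectorized over frames
  sx <- track$x[, -1, drop = FALSE] - track$x[, -K, drop = FALSE]
  sy <- track$y[, -1, drop = FALSE] - track$y[, -K, drop = FALSE]
  sl <- sqrt(sx^2 + sy^2)
  cth2 <- ((sx * ax + sy * ay) / (sl * an))^2
  S <- 0.5 * (3 * rowMeans(cth2) - 1)
  S[!track$valid | an == 0] <- NA

  # shape factor from sliding-window covariance of CoM displacements
  dxs <- c(NA, diff(gx)); dys <- c(NA, diff(gy))
  mx <- roll_mean(dxs, window); my <- roll_mean(dys, window)
  cxx <- roll_mean(dxs^2, window) - mx^2
  cyy <- roll_mean(dys^2, window) - my^2
  cxy <- roll_mean(dxs * dys, window) - mx * my
  trc <- cxx + cyy
  lambda <- ifelse(is.na(trc) | trc <= 0, 0,
                   sqrt((cxx - cyy)^2 + 4 * cxy^2) / trc)
  lambda <- pmin(pmax(lambda, 0), 1)
  lambda[!track$valid] <- NA

  # head/tail length ratio
  dh <- sqrt((hx - gx)^2 + (hy - gy)^2)
  dt <- sqrt((tx - gx)^2 + (ty - gy)^2)
  len_ratio <- ifelse(dt > 0, dh / dt, NA)

  # closest-segment projection of end velocities, vectorized over segments
  proj_end <- function(px, py, vx, vy) {
    tipx <- px + vx; tipy <- py + vy
    relx <- tipx - track$x[, -K, drop = FALSE]
    rely <- tipy - track$y[, -K, drop = FALSE]
    sl2 <- sx^2 + sy^2
    u <- (relx * sx + rely * sy) / pmax(sl2, .Machine$double.eps)
    u <- pmin(pmax(u, 0), 1)
    dd <- (relx - sx * u)^2 + (rely - sy * u)^2
    dd[sl2 == 0] <- Inf
    j <- max.col(-dd, ties.method = "first")
    i <- cbind(seq_len(n), j)
    (vx * sx[i] + vy * sy[i]) / sqrt(sl2[i]) / len
  }
  proj_head <- proj_end(hx, hy, vhx, vhy)
  proj_tail <- proj_end(tx, ty, vtx, vty)

  # cosines with first / last spine segment
  cosv <- function(vx, vy, rx, ry) {
    nv <- sqrt(vx^2 + vy^2); nr <- sqrt(rx^2 + ry^2)
    out <- (vx * rx + vy * ry) / (nv * nr)
    out[nv == 0 | nr == 0] <- NA
    pmin(pmax(out, -1), 1)
  }
  cos_head <- cosv(vhx, vhy, sx[, 1], sy[, 1])
  cos_tail <- cosv(vtx, vty, sx[, K - 1L], sy[, K - 1L])

  # bend angle: signed angle between the head-end and tail-end spine
  # segment directions (degrees); 0 for a straight larva
  ux <- sx[, 1] / sl[, 1]; uy <- sy[, 1] / sl[, 1]
  wx <- sx[, K - 1L] / sl[, K - 1L]; wy <- sy[, K - 1L] / sl[, K - 1L]
  dotv <- pmin(pmax(ux * wx + uy * wy, -1), 1)
  crossv <- wx * uy - wy * ux
  bend <- sign(crossv) * acos(dotv) * 180 / pi

  out <- data.frame(
    larva_id = track$larva_id, t = track$t, valid = track$valid,
    v_head = v_head, v_motion = v_motion, v_tail = v_tail,
    S = S, lambda = lambda, len_ratio = len_ratio,
    proj_head = proj_head, proj_tail = proj_tail,
    cos_head = cos_head, cos_tail = cos_tail,
    v_com_forward = v_com_forward, bend_angle = bend, dlen = dlen,
    length = len, rel_length = len / mean(len[track$valid]),
    stringsAsFactors = FALSE)
  class(out) <- c("feature_series", "data.frame")
  out
}

#' Feature series for every track in a set
#'
#' @param trackset a \code{track_set}.
#' @param ... passed to \code{\link{compute_frame_features}}.
#' @return one \code{feature_series} data frame, rows from all larvae.
#' @export
compute_features <- function(trackset, ...) {
  out <- do.call(rbind, lapply(trackset$tracks, compute_frame_features, ...))
  rownames(out) <- NULL
  class(out) <- c("feature_series", "data.frame")
  out
}

# columns that enter per-action aggregates (scale-free set + rel_length)
action_feature_cols <- function() {
  c("v_head", "v_motion", "v_tail", "S", "lambda", "len_ratio",
    "proj_head", "proj_tail", "cos_head", "cos_tail",
    "v_com_forward", "bend_angle", "dlen", "rel_length")
}

#' Aggregate frame features over one action interval
#'
#' Mean, max and min per feature over the frames of the half-open interval
#' \code{[start, end)}, plus context means over the \code{context} frames
#' before and after the action (truncated and flagged at track edges), and
#' the action duration.
#'
#' @param series a \code{feature_series} for a single larva.
#' @param interval list or one-row data frame with \code{start}, \code{end}
#'   (seconds).
#' @param context number of context frames on each side (default 5).
#' @return one-row data frame of aggregated features.
#' @export
aggregate_action_features <- function(series, interval, context = 5L) {
  idx <- which(series$t >= interval$start & series$t < interval$end)
  if (!length(idx)) stop("empty interval: no frames in [start, end)")
  cols <- intersect(action_feature_cols(), names(series))
  agg <- function(f, v) if (all(is.na(v))) NA_real_ else f(v, na.rm = TRUE)
  out <- list(duration = interval$end - interval$start)
  for (cn in cols) {
    v <- series[[cn]][idx]
    out[[paste0(cn, "_mean")]] <- agg(mean, v)
    out[[paste0(cn, "_max")]] <- agg(max, v)
    out[[paste0(cn, "_min")]] <- agg(min, v)
  }
  pre <- seq(max(1L, min(idx) - context), min(idx) - 1L)
  post <- seq(max(idx) + 1L, min(nrow(series), max(idx) + context))
  if (min(idx) == 1L) pre <- integer(0)
  if (max(idx) == nrow(series)) post <- integer(0)
  for (cn in cols) {
    out[[paste0(cn, "_pre")]] <- if (length(pre))
      agg(mean, series[[cn]][pre]) else NA_real_
    out[[paste0(cn, "_post")]] <- if (length(post))
      agg(mean, series[[cn]][post]) else NA_real_
  }
  out$pre_truncated <- length(pre) < context
  out$post_truncated <- length(post) < context
  as.data.frame(out, stringsAsFactors = FALSE)
}
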