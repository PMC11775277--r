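# Fixture builders used across the suite.  All synthetic, built in code.

# straight horizontal larva: head at x = len/2, tail at -len/2, K points
straight_spine <- function(K = 11, len = 4, origin = c(0, 0), angle = 0) {
  s <- seq(len / 2, -len / 2, length.out = K)
  p <- cbind(s * cos(angle), s * sin(angle))
  sweep(p, 2, origin, "+")
}

# track of a rigid larva translating at constant velocity (mm/s)
rigid_track <- function(id = "rigid", n = 20, vel = c(0, 0), K = 11,
                        len = 4, frame_rate = 10) {
  tt <- (seq_len(n) - 1) / frame_rate
  base <- straight_spine(K, len)
  x <- outer(tt * vel[1], rep(1, K)) + matrix(base[, 1], n, K, byrow = TRUE)
  y <- outer(tt * vel[2], rep(1, K)) + matrix(base[, 2], n, K, byrow = TRUE)
  larva_track(id, tt, x, y, frame_rate = frame_rate)
}

# random wiggly (non-degenerate) posture for oracle comparisons
random_spine <- function(K = 11, len = 4) {
  ang <- cumsum(c(stats::runif(1, 0, 2 * pi),
                  stats::rnorm(K - 2, 0, 0.4)))
  h <- len / (K - 1)
  p <- apply(rbind(c(0, 0), cbind(h * cos(ang), h * sin(ang))), 2, cumsum)
  p[seq(K, 1), , drop = FALSE]  # head first
}

# brute-force oracles -------------------------------------------------------

oracle_S <- function(p, axis = p[1, ] - p[nrow(p), ]) {
  axis <- axis / sqrt(sum(axis^2))
  tot <- 0; m <- 0
  for (i in seq_len(nrow(p) - 1)) {
    seg <- p[i + 1, ] - p[i, ]
    ns <- sqrt(sum(seg^2))
    if (ns == 0) next
    tot <- tot + (sum(seg * axis) / ns)^2
    m <- m + 1
  }
  0.5 * (3 * tot / m - 1)
}

oracle_len_ratio <- function(p) {
  g <- c(mean(p[, 1]), mean(p[, 2]))
  sqrt(sum((p[1, ] - g)^2)) / sqrt(sum((p[nrow(p), ] - g)^2))
}

oracle_projection <- function(v, p, point = p[1, ]) {
  L <- sum(sqrt(rowSums((p[-1, , drop = FALSE] -
                           p[-nrow(p), , drop = FALSE])^2)))
  tip <- point + v
  best <- Inf; proj <- NA
  for (i in seq_len(nrow(p) - 1)) {
    a <- p[i, ]; b <- p[i + 1, ]
    d <- b - a
    if (sum(d^2) == 0) next
    u <- max(0, min(1, sum((tip - a) * d) / sum(d^2)))
    dist <- sum(((tip - a) - u * d)^2)
    if (dist < best) {
      best <- dist
      proj <- sum(v * d) / sqrt(sum(d^2)) / L
    }
  }
  proj
}

oracle_ks_D <- function(x, y) {
  pts <- c(x, y)
  mx <- 0
  for (p in pts) {
    d <- abs(mean(x <= p) - mean(y <= p))
    if (d > mx) mx <- d
  }
  mx
}

# exhaustive step-up BH: largest k with p_(k) <= k/m * alpha rejected
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i / m * alpha) k <- i
  rej <- rep(FALSE, m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

oracle_chi2_2x2 <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
  n <- a + b + cc + d
  n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
}

oracle_bfs_dist <- function(edges, from, to) {
  # edges: data.frame pre,post (already filtered); unit hop BFS
  adj <- split(edges$post, edges$pre)
  dist <- stats::setNames(Inf, from)
  frontier <- from; d <- 0
  seen <- character(0)
  while (length(frontier)) {
    if (to %in% frontier) return(d)
    seen <- c(seen, frontier)
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
    d <- d + 1
  }
  Inf
}

# minimal feature series for rule tests (only columns the rules read)
fake_series <- function(id, t, v_motion) {
  data.frame(larva_id = id, t = t, valid = TRUE, v_motion = v_motion,
             stringsAsFactors = FALSE)
}
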