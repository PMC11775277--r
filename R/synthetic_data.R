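# Synthetic larval trajectories, connectomes and fluorescence traces with
# known ground truth.  Motif kinematics are package conventions chosen to
# realize each action's defining dynamics (see the methods vignette); they
# are not measurements.

#' Refined and coarse behavior vocabularies
#'
#' The refined dictionary distinguishes Head Cast (dynamic lateral head
#' sweep), Static Bend (sustained low-speed bend), Hunch (fast head
#' retraction), Head-and-Tail (simultaneous retraction of both ends) and
#' C-shape (strong bend with both ends still) in addition to Crawl, Roll,
#' Back-up and Stop.  The coarse vocabulary is the pre-refinement one.
#'
#' @return character vector of labels.
#' @export
refined_labels <- function() {
  c("Crawl", "HeadCast", "StaticBend", "Hunch", "HeadAndTail", "CShape",
    "Roll", "BackUp", "Stop")
}

#' @rdname refined_labels
#' @export
coarse_labels <- function() c("Crawl", "Bend", "Hunch", "Back", "Stop", "Roll")

#' Map refined labels to the coarse vocabulary
#'
#' Head Cast, Static Bend and C-shape are subcategories of the coarse Bend;
#' Hunch and Head-and-Tail fall under the coarse Hunch (head-retraction)
#' category; the rest map one-to-one.
#'
#' @param labels character vector of refined labels.
#' @return character vector of coarse labels.
#' @export
coarse_from_refined <- function(labels) {
  map <- c(Crawl = "Crawl", HeadCast = "Bend", StaticBend = "Bend",
           CShape = "Bend", Hunch = "Hunch", HeadAndTail = "Hunch",
           Roll = "Roll", BackUp = "Back", Stop = "Stop")
  bad <- setdiff(unique(labels), names(map))
  if (length(bad)) stop("unknown refined label(s): ", paste(bad, collapse = ", "))
  unname(map[labels])
}

#' Behavior script
#'
#' A time-ordered sequence of motifs for one larva.
#'
#' @param label character vector of refined labels.
#' @param duration numeric vector of motif durations (s), all positive.
#' @param params optional list (one element per motif) of amplitude
#'   parameter lists, e.g. \code{list(speed_mult = 1.5)} for a fast Crawl or
#'   \code{list(fast = TRUE)} for a fast Head Cast.
#' @return a \code{behavior_script} data frame.
#' @export
behavior_script <- function(label, duration, params = NULL) {
  stopifnot(length(label) == length(duration), all(duration > 0))
  bad <- setdiff(label, refined_labels())
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  if (is.null(params)) params <- rep(list(list()), length(label))
  s <- data.frame(label = label, duration = duration,
                  stringsAsFactors = FALSE)
  s$params <- params
  class(s) <- c("behavior_script", "data.frame")
  s
}

# Hinge posture in the body frame: two straight sections joined mid-spine,
# the anterior rotated by `beta` degrees.  `ca`/`cp` compress the anterior/
# posterior segment spacing (head or tail retraction).  Returns K x 2 points
# head first, centred on their centroid.
hinge_posture <- function(K, L, beta = 0, ca = 1, cp = 1) {
  h <- L / (K - 1)
  m <- (K + 1) %/% 2                       # hinge index
  b <- beta * pi / 180
  adir <- c(cos(b), sin(b))
  p <- matrix(0, K, 2)
  ia <- seq_len(m - 1)                     # anterior points (head side)
  p[ia, 1] <- (m - ia) * h * ca * adir[1]
  p[ia, 2] <- (m - ia) * h * ca * adir[2]
  ip <- seq(m + 1, K)                      # posterior points (tail side)
  p[ip, 1] <- -(ip - m) * h * cp
  sweep(p, 2, colMeans(p))
}

ramp01 <- function(tau, rise) pmin(tau / rise, 1)

# Per-motif kinematic state at phase tau (s since motif start): body length
# scale factors, bend angle, CoM velocity in the heading frame
# (forward, lateral) in body lengths per second.
motif_state <- function(label, tau, params) {
  p <- function(nm, def) if (!is.null(params[[nm]])) params[[nm]] else def
  switch(label,
    Crawl = list(beta = 0, ca = 1 + 0.08 * sin(2 * pi * tau), cp = NA,
                 v = c(0.06 * p("speed_mult", 1), 0)),
    HeadCast = {
      A <- p("amplitude", 50); Tp <- p("period", 2)
      # tail stays planted (anchored); the anterior sweep translates the
      # centroid; the fast variant adds a tail-propelled lateral lunge
      lat <- if (isTRUE(p("fast", FALSE)))
        0.12 * sign(sin(2 * pi * tau / Tp)) else 0
      list(beta = A * sin(2 * pi * tau / Tp), ca = 1, cp = 1,
           v = c(0.005, lat), anchor = "tail")
    },
    StaticBend = list(beta = p("amplitude", 50), ca = 1, cp = 1, v = c(0, 0)),
    Hunch = list(beta = 0, ca = 1 - 0.45 * ramp01(tau, 0.5), cp = 1,
                 v = c(0, 0)),
    HeadAndTail = {
      c0 <- 1 - 0.35 * ramp01(tau, 0.5)
      list(beta = 0, ca = c0, cp = c0, v = c(0, 0))
    },
    CShape = list(beta = p("amplitude", 110), ca = 1, cp = 1, v = c(0, 0)),
    Roll = list(beta = 60 * sin(4 * pi * tau), ca = 1, cp = 1,
                v = c(0, 0.10)),
    BackUp = list(beta = 0, ca = 1 + 0.04 * sin(2 * pi * tau), cp = NA,
                  v = c(-0.05, 0)),
    Stop = list(beta = 0, ca = 1, cp = 1, v = c(0, 0)),
    stop("unknown motif label: ", label))
}

#' Simulate one larva from a behavior script
#'
#' Generates a spine time series realizing each motif's defining kinematics
#' (Crawl: peristaltic length oscillation with forward centre-of-mass
#' motion; Head Cast: lateral head sweep with the head much faster than the
#' centre of mass; Static Bend: sustained bend with near-zero speeds; Hunch:
#' head-to-centroid contraction with a straight body; Head-and-Tail:
#' contraction of both ends with a larger total length drop than Hunch;
#' C-shape: strong bend, both ends still; Roll: alternating bend side with
#' lateral translation; Back-up: rearward motion; Stop: immobility), plus
#' additive point jitter and heading drift noise.
#'
#' @param script a \code{\link{behavior_script}}.
#' @param noise list with \code{point_sd} (mm) and \code{heading_drift}
#'   (rad/sqrt(s)).
#' @param seed integer RNG seed (required: outputs are reproducible).
#' @param larva_id id for the generated track.
#' @param frame_rate Hz.
#' @param K spine points per frame.
#' @param L nominal body length, mm.
#' @param t0 time of the first frame, s.
#' @return list with \code{track} (a \code{larva_track}) and \code{truth}
#'   (data frame larva_id, start, end, label exactly tiling the script).
#' @export
simulate_larva <- function(script, noise = list(point_sd = 0,
                                                heading_drift = 0),
                           seed = 1, larva_id = "larva1", frame_rate = 10,
                           K = 11, L = 4, t0 = 0) {
  stopifnot(inherits(script, "behavior_script"))
  set.seed(seed)
  dt <- 1 / frame_rate
  ends <- cumsum(script$duration)
  starts <- c(0, ends[-length(ends)])
  total <- ends[length(ends)]
  tt <- seq(0, total - dt / 2, by = dt)
  n <- length(tt)
  G <- c(0, 0); phi <- stats::runif(1, 0, 2 * pi)
  x <- matrix(NA_real_, n, K); y <- matrix(NA_real_, n, K)
  ps <- noise$point_sd %||% 0
  hd <- noise$heading_drift %||% 0
  prev_mi <- 0L
  anchor <- NULL
  for (i in seq_len(n)) {
    mi <- findInterval(tt[i], starts)
    st <- motif_state(script$label[mi], tt[i] - starts[mi],
                      script$params[[mi]])
    cp <- if (is.na(st$cp)) st$ca else st$cp
    p <- hinge_posture(K, L, st$beta, st$ca, cp)
    cs <- cos(phi); sn <- sin(phi)
    rx <- p[, 1] * cs - p[, 2] * sn
    ry <- p[, 1] * sn + p[, 2] * cs
    if (!is.null(st$anchor)) {
      # tail-anchored motif: pin the tail where it was when the motif
      # began; the centroid position follows from the posture
      if (mi != prev_mi) {
        anchor <- if (i > 1) c(x[i - 1, K], y[i - 1, K])
                  else G + c(rx[K], ry[K])
      }
      G <- anchor - c(rx[K], ry[K])
    } else if (mi != prev_mi) {
      anchor <- NULL
    }
    prev_mi <- mi
    x[i, ] <- G[1] + rx
    y[i, ] <- G[2] + ry
    if (ps > 0) {
      x[i, ] <- x[i, ] + stats::rnorm(K, 0, ps)
      y[i, ] <- y[i, ] + stats::rnorm(K, 0, ps)
    }
    # advance state for next frame (anchored motifs advance the anchor)
    vf <- st$v[1] * L; vl <- st$v[2] * L
    step <- dt * c(vf * cs - vl * sn, vf * sn + vl * cs)
    if (!is.null(st$anchor)) anchor <- anchor + step else G <- G + step
    if (hd > 0) phi <- phi + stats::rnorm(1, 0, hd * sqrt(dt))
  }
  tr <- larva_track(larva_id, t0 + tt, x, y, frame_rate = frame_rate)
  truth <- data.frame(larva_id = larva_id, start = t0 + starts,
                      end = t0 + ends, label = script$label,
                      stringsAsFactors = FALSE)
  list(track = tr, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Population configuration for the synthetic generator
#'
#' Defaults emulate the assay structure: a 90 s recording at 10 Hz with an
#' air puff delivered at the 60th second for 30 seconds; baseline behavior
#' dominated by crawling with exploratory head casts and stops; the stimulus
#' evoking an avoidance repertoire (Hunch, Head-and-Tail, C-shape, Static
#' Bend, Head Cast, Back-up); a fraction of larvae not tracked before
#' stimulus onset.
#'
#' @param n_larvae number of larvae.
#' @param duration recording length, s.
#' @param baseline_initial,baseline_kernel initial distribution and
#'   transition kernel (rows sum to 1) over labels before stimulus onset.
#' @param stim_initial,stim_kernel same, from stimulus onset.
#' @param mean_durations named mean motif durations, s.
#' @param noise list(point_sd, heading_drift).
#' @param dropout probability a larva is untracked before stimulus onset.
#' @param crawl_speed_mult speed multiplier applied to post-onset Crawls
#'   (1 = none; 1.5 emulates stimulus-evoked Fast Crawls).
#' @param frame_rate,K,L acquisition rate (Hz), spine points, body length
#'   (mm).
#' @param seed integer seed.
#' @return a \code{population_config} list.
#' @export
population_config <- function(n_larvae = 50, duration = 90,
                              baseline_initial = NULL, baseline_kernel = NULL,
                              stim_initial = NULL, stim_kernel = NULL,
                              mean_durations = NULL,
                              noise = list(point_sd = 0, heading_drift = 0),
                              dropout = 0.1, crawl_speed_mult = 1,
                              frame_rate = 10, K = 11, L = 4, seed = 1) {
  labs <- refined_labels()
  unit <- function(v) v / sum(v)
  if (is.null(baseline_initial)) {
    baseline_initial <- unit(stats::setNames(
      c(0.6, 0.2, 0, 0, 0, 0, 0, 0, 0.2), labs))
  }
  if (is.null(baseline_kernel)) {
    baseline_kernel <- matrix(0, length(labs), length(labs),
                              dimnames = list(labs, labs))
    baseline_kernel["Crawl", ] <- unit(stats::setNames(
      c(0, 0.5, 0, 0, 0, 0, 0, 0.1, 0.4), labs))
    baseline_kernel["HeadCast", ] <- unit(stats::setNames(
      c(0.8, 0, 0, 0, 0, 0, 0, 0, 0.2), labs))
    baseline_kernel["Stop", ] <- unit(stats::setNames(
      c(0.7, 0.3, 0, 0, 0, 0, 0, 0, 0), labs))
    baseline_kernel["BackUp", ] <- unit(stats::setNames(
      c(0.7, 0.2, 0, 0, 0, 0, 0, 0, 0.1), labs))
  }
  if (is.null(stim_initial)) {
    stim_initial <- unit(stats::setNames(
      c(0.05, 0.15, 0.1, 0.3, 0.15, 0.1, 0, 0.1, 0.05), labs))
  }
  if (is.null(stim_kernel)) {
    stim_kernel <- matrix(0, length(labs), length(labs),
                          dimnames = list(labs, labs))
    stim_kernel["Crawl", ] <- unit(stats::setNames(
      c(0, 0.4, 0.1, 0.1, 0.05, 0.05, 0, 0.15, 0.15), labs))
    stim_kernel["HeadCast", ] <- unit(stats::setNames(
      c(0.4, 0, 0.2, 0.1, 0.05, 0.1, 0, 0.05, 0.1), labs))
    stim_kernel["StaticBend", ] <- unit(stats::setNames(
      c(0.3, 0.3, 0, 0.1, 0.05, 0.1, 0, 0.05, 0.1), labs))
    stim_kernel["Hunch", ] <- unit(stats::setNames(
      c(0.25, 0.25, 0.1, 0, 0.1, 0.1, 0, 0.1, 0.1), labs))
    stim_kernel["HeadAndTail", ] <- unit(stats::setNames(
      c(0.2, 0.2, 0.1, 0.15, 0, 0.15, 0, 0.1, 0.1), labs))
    stim_kernel["CShape", ] <- unit(stats::setNames(
      c(0.2, 0.2, 0.1, 0.1, 0.1, 0, 0.1, 0.1, 0.1), labs))
    stim_kernel["Roll", ] <- unit(stats::setNames(
      c(0.4, 0.2, 0, 0, 0, 0.2, 0, 0.1, 0.1), labs))
    stim_kernel["BackUp", ] <- unit(stats::setNames(
      c(0.3, 0.2, 0.1, 0.1, 0.05, 0.05, 0, 0, 0.2), labs))
    stim_kernel["Stop", ] <- unit(stats::setNames(
      c(0.3, 0.25, 0.15, 0.1, 0.05, 0.05, 0, 0.1, 0), labs))
  }
  if (is.null(mean_durations)) {
    mean_durations <- c(Crawl = 3, HeadCast = 2, StaticBend = 2, Hunch = 1,
                        HeadAndTail = 1, CShape = 1.5, Roll = 2,
                        BackUp = 1.5, Stop = 2)
  }
  stopifnot(dropout >= 0, dropout <= 1,
            all(abs(rowSums(baseline_kernel)[rowSums(baseline_kernel) > 0] -
                      1) < 1e-8),
            all(abs(rowSums(stim_kernel)[rowSums(stim_kernel) > 0] - 1) <
                  1e-8))
  structure(list(n_larvae = n_larvae, duration = duration,
                 baseline_initial = baseline_initial,
                 baseline_kernel = baseline_kernel,
                 stim_initial = stim_initial, stim_kernel = stim_kernel,
                 mean_durations = mean_durations, noise = noise,
                 dropout = dropout, crawl_speed_mult = crawl_speed_mult,
                 frame_rate = frame_rate, K = K, L = L, seed = seed),
            class = "population_config")
}

draw_label <- function(probs) sample(names(probs), 1L, prob = probs)

# script for one larva: baseline Markov chain truncated at stimulus onset,
# then the stimulus-epoch chain to the end of the recording
draw_script <- function(config, onset) {
  md <- config$mean_durations
  # draw one epoch's motif chain, clip the last motif to the epoch end;
  # a clipped remnant shorter than 0.3 s is absorbed into the previous
  # motif so every scripted interval spans at least one frame
  draw_epoch <- function(span, initial, kernel, params_for) {
    lab <- character(0); dur <- numeric(0); par <- list()
    t <- 0
    cur <- draw_label(initial)
    while (t < span - 1e-9) {
      d <- min(md[[cur]] * stats::runif(1, 0.7, 1.3), span - t)
      lab <- c(lab, cur); dur <- c(dur, d)
      par <- c(par, list(params_for(cur)))
      t <- t + d
      if (t < span - 1e-9) {
        row <- kernel[cur, ]
        cur <- if (sum(row) > 0) draw_label(row) else draw_label(initial)
      }
    }
    if (length(dur) > 1 && dur[length(dur)] < 0.3) {
      dur[length(dur) - 1L] <- dur[length(dur) - 1L] + dur[length(dur)]
      lab <- lab[-length(lab)]; dur <- dur[-length(dur)]
      par <- par[-length(par)]
    }
    list(lab = lab, dur = dur, par = par)
  }
  no_par <- function(cur) list()
  stim_par <- function(cur)
    if (cur == "Crawl" && config$crawl_speed_mult != 1)
      list(speed_mult = config$crawl_speed_mult) else list()
  b <- draw_epoch(onset, config$baseline_initial, config$baseline_kernel,
                  no_par)
  s <- draw_epoch(config$duration - onset, config$stim_initial,
                  config$stim_kernel, stim_par)
  behavior_script(c(b$lab, s$lab), c(b$dur, s$dur), c(b$par, s$par))
}

#' Simulate a larval population under a stimulus protocol
#'
#' Each larva follows a motif sequence drawn from the baseline transition
#' kernel before stimulus onset and from the stimulus kernel afterwards
#' (the first post-onset motif from \code{stim_initial}); a configured
#' fraction of larvae is untracked before the onset of stimulation (their
#' pre-onset frames are flagged invalid).
#'
#' @param config a \code{\link{population_config}}.
#' @param protocol a \code{\link{stimulus_protocol}}; the first epoch's
#'   onset splits baseline from stimulus behavior.
#' @return list with \code{trackset} (a \code{track_set}) and \code{truth}
#'   (data frame larva_id, start, end, label).
#' @export
simulate_population <- function(config, protocol = stimulus_protocol()) {
  stopifnot(inherits(config, "population_config"))
  if (config$n_larvae < 1) stop("n_larvae must be >= 1")
  onset <- protocol$onset[1]
  set.seed(config$seed)
  larva_seeds <- sample.int(.Machine$integer.max, config$n_larvae)
  dropped <- stats::runif(config$n_larvae) < config$dropout
  scripts <- vector("list", config$n_larvae)
  for (i in seq_len(config$n_larvae)) scripts[[i]] <- draw_script(config, onset)
  tracks <- vector("list", config$n_larvae)
  truths <- vector("list", config$n_larvae)
  for (i in seq_len(config$n_larvae)) {
    id <- sprintf("larva%03d", i)
    sim <- simulate_larva(scripts[[i]], noise = config$noise,
                          seed = larva_seeds[i], larva_id = id,
                          frame_rate = config$frame_rate, K = config$K,
                          L = config$L)
    tr <- sim$track
    if (dropped[i]) tr$valid[tr$t <= onset + 0.5] <- FALSE
    tracks[[i]] <- tr
    truths[[i]] <- sim$truth
  }
  truth <- do.call(rbind, truths)
  rownames(truth) <- NULL
  list(trackset = track_set(tracks, protocol, "synthetic"),
       truth = truth, dropped = sprintf("larva%03d", which(dropped)))
}

# -- Connectome ---------------------------------------------------------------

#' Construct a synapse table
#'
#' @param edges data frame: pre_id, post_id, synapse_count, connection_type.
#' @param neurons data frame: id, name, class, side, hemilateral_partner_id,
#'   node_count, neuromere.
#' @return a \code{synapse_table}.
#' @export
synapse_table <- function(edges, neurons) {
  stopifnot(all(c("pre_id", "post_id", "synapse_count") %in% names(edges)),
            all(c("id", "class", "side", "node_count") %in% names(neurons)))
  if (is.null(edges$connection_type))
    edges$connection_type <- rep("unknown", nrow(edges))
  if (anyDuplicated(neurons$id)) stop("duplicate neuron ids")
  if (nrow(edges)) {
    if (any(edges$synapse_count < 1) ||
        any(edges$synapse_count != round(edges$synapse_count)))
      stop("synapse_count must be a positive integer")
    miss <- setdiff(unique(c(edges$pre_id, edges$post_id)), neurons$id)
    if (length(miss))
      stop("edge endpoints missing from neuron list: ",
           paste(miss, collapse = ", "))
  }
  structure(list(edges = edges, neurons = neurons), class = "synapse_table")
}

#' @export
print.synapse_table <- function(x, ...) {
  cat(sprintf("<synapse_table> %d neurons, %d edges, %d synapses\n",
              nrow(x$neurons), nrow(x$edges), sum(x$edges$synapse_count)))
  invisible(x)
}

#' Simulate a hemilateral-paired synthetic connectome
#'
#' Generates a target hemilateral pair receiving input from class-annotated
#' upstream neurons (with left/right homologs), with a configurable fraction
#' of upstream neurons left as low-node-count fragments, plus a downstream
#' pathway (premotor interneurons and motor neurons) for hop-distance
#' analysis.  In \code{mode = "construct"} the class input fractions are hit
#' exactly; in \code{mode = "sample"} synapse counts are multinomial draws.
#'
#' @param params list: \code{class_fractions} (named, sums to 1) of input
#'   synapses per class, \code{n_per_class} upstream pairs per class,
#'   \code{total_input} synapses onto the target pair,
#'   \code{fragment_fraction} of non-sensory upstream neurons below the
#'   node-count threshold, \code{mode} "construct" or "sample".
#' @param seed integer seed.
#' @return a \code{synapse_table}; ground-truth class fractions in
#'   \code{attr(, "truth")}.
#' @export
simulate_connectome <- function(params = list(), seed = 1) {
  set.seed(seed)
  cf <- params$class_fractions %||%
    c(sensory = 0.15, local = 0.45, brain = 0.1, SEZ = 0.05,
      ascending = 0.15, descending = 0.1)
  stopifnot(abs(sum(cf) - 1) < 1e-9)
  npc <- params$n_per_class %||% 2L
  total <- params$total_input %||% 400L
  ffrac <- params$fragment_fraction %||% 0
  mode <- params$mode %||% "construct"

  tgt <- data.frame(id = c("target_l", "target_r"), name = "target",
                    class = "local", side = c("l", "r"),
                    hemilateral_partner_id = c("target_r", "target_l"),
                    node_count = 8000L, neuromere = "a1",
                    stringsAsFactors = FALSE)
  ups <- do.call(rbind, lapply(names(cf), function(cl) {
    do.call(rbind, lapply(seq_len(npc), function(k) {
      base <- sprintf("%s%02d", cl, k)
      data.frame(id = paste0(base, c("_l", "_r")), name = base, class = cl,
                 side = c("l", "r"),
                 hemilateral_partner_id = paste0(base, c("_r", "_l")),
                 node_count = 5000L, neuromere = "a1",
                 stringsAsFactors = FALSE)
    }))
  }))
  nonsens <- which(ups$class != "sensory")
  nfrag <- round(ffrac * length(nonsens))
  if (nfrag > 0) {
    frag <- sample(nonsens, nfrag)
    ups$node_count[frag] <- sample(200:1499, nfrag, replace = TRUE)
  }
  # class synapse totals
  if (mode == "construct") {
    ctot <- round(cf * total)
  } else {
    ctot <- stats::setNames(
      as.vector(stats::rmultinom(1, total, cf)), names(cf))
  }
  edges <- do.call(rbind, lapply(names(cf), function(cl) {
    pres <- ups$id[ups$class == cl]
    cnt <- ctot[[cl]]
    if (cnt == 0) return(NULL)
    per <- diff(round(seq(0, cnt, length.out = length(pres) + 1L)))
    keep <- per > 0
    data.frame(pre_id = pres[keep],
               post_id = rep(c("target_l", "target_r"),
                             length.out = sum(keep)),
               synapse_count = per[keep], connection_type = "axo-dendritic",
               stringsAsFactors = FALSE)
  }))
  # downstream pathway: target -> premotor -> motor, plus one direct edge
  down <- data.frame(
    id = c("premotor01_l", "premotor01_r", "motor01_l", "motor01_r",
           "motor02_l", "motor02_r"),
    name = c("premotor01", "premotor01", "motor01", "motor01",
             "motor02", "motor02"),
    class = c("local", "local", "motor", "motor", "motor", "motor"),
    side = c("l", "r", "l", "r", "l", "r"),
    hemilateral_partner_id = c("premotor01_r", "premotor01_l", "motor01_r",
                               "motor01_l", "motor02_r", "motor02_l"),
    node_count = 6000L, neuromere = "a1", stringsAsFactors = FALSE)
  dedges <- data.frame(
    pre_id = c("target_l", "target_r", "premotor01_l", "premotor01_r",
               "target_l"),
    post_id = c("premotor01_l", "premotor01_r", "motor01_l", "motor01_r",
                "motor02_l"),
    synapse_count = c(8L, 8L, 6L, 6L, 4L),
    connection_type = "axo-dendritic", stringsAsFactors = FALSE)
  tab <- synapse_table(rbind(edges, dedges), rbind(tgt, ups, down))
  attr(tab, "truth") <- list(class_fractions = ctot / sum(ctot),
                             class_totals = ctot,
                             target_ids = c("target_l", "target_r"))
  tab
}

# -- Fluorescence -------------------------------------------------------------

#' Simulate calcium fluorescence traces with known response amplitude
#'
#' Emulates the stimulation experiment layout: a baseline recording, a
#' stimulation epoch, and a post-stimulus segment, repeated several times per
#' larva.  The noiseless response peaks at exactly \code{amplitude} in
#' dF/F0 units.  A configurable fraction of traces receives an injected
#' pre-stimulus transient (activity before stimulation) for testing the
#' exclusion rule.
#'
#' @param params list: \code{n_larvae}, \code{n_reps} (scalar or per-larva
#'   vector), \code{baseline} F0 level, \code{amplitude} peak dF/F0,
#'   \code{noise_sd} additive noise SD (fluorescence units),
#'   \code{pre_activity_fraction} of traces with a pre-stimulus transient,
#'   \code{pre_activity_amplitude} (dF/F0 units), \code{pre_s},
#'   \code{stim_s}, \code{post_s} segment lengths (default 5/5/5 s),
#'   \code{rate} sampling rate (Hz).
#' @param seed integer seed.
#' @return data frame larva_id, repetition, t, F, stim_onset, stim_duration;
#'   ids of transient-injected traces in \code{attr(, "pre_active")}.
#' @export
simulate_fluorescence <- function(params = list(), seed = 1) {
  set.seed(seed)
  nl <- params$n_larvae %||% 6L
  reps <- params$n_reps %||% 4L
  if (length(reps) == 1L) reps <- rep(reps, nl)
  f0 <- params$baseline %||% 100
  a <- params$amplitude %||% 1
  sdn <- params$noise_sd %||% 0
  paf <- params$pre_activity_fraction %||% 0
  paa <- params$pre_activity_amplitude %||% 0.5
  pre_s <- params$pre_s %||% 5; stim_s <- params$stim_s %||% 5
  post_s <- params$post_s %||% 5
  rate <- params$rate %||% 5
  tt <- seq(0, pre_s + stim_s + post_s - 1 / rate, by = 1 / rate)
  resp <- function(t) {
    s <- numeric(length(t))
    dur <- pmax(t - pre_s, 0)
    s[t >= pre_s & t < pre_s + stim_s] <-
      pmin(dur[t >= pre_s & t < pre_s + stim_s], 1)
    decay <- t >= pre_s + stim_s
    s[decay] <- exp(-(t[decay] - pre_s - stim_s) / 1.5) *
      min(stim_s, 1)
    s
  }
  trace_ids <- unlist(lapply(seq_len(nl), function(i)
    paste0("larva", i, "_rep", seq_len(reps[i]))))
  n_active <- round(paf * length(trace_ids))
  active <- if (n_active > 0) sample(trace_ids, n_active) else character(0)
  out <- do.call(rbind, lapply(seq_len(nl), function(i) {
    do.call(rbind, lapply(seq_len(reps[i]), function(r) {
      id <- paste0("larva", i, "_rep", r)
      s <- resp(tt)
      if (id %in% active) s <- s + paa / a * exp(-((tt - 2)^2) / (2 * 0.25))
      FF <- f0 * (1 + a * s)
      if (sdn > 0) FF <- FF + stats::rnorm(length(tt), 0, sdn)
      data.frame(larva_id = paste0("larva", i), repetition = r, t = tt,
                 F = FF, stim_onset = pre_s, stim_duration = stim_s,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  attr(out, "pre_active") <- active
  attr(out, "truth") <- list(amplitude = a, baseline = f0)
  out
}
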