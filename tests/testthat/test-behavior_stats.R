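mk_intervals <- function(id, start, end, label) {
  data.frame(larva_id = id, start = start, end = end, refined_label = label,
             stringsAsFactors = FALSE)
}

test_that("ethogram bins take the label covering their midpoint", {
  tr <- rigid_track("a", n = 60)                       # 0 .. 5.9 s
  ts <- track_set(list(tr))
  iv <- mk_intervals("a", 0, 5, "Crawl")
  e <- build_ethogram(iv, ts, bin_s = 1)
  expect_equal(e$label[1:5], rep("Crawl", 5))
  # beyond the interval: untracked marker, never a label
  expect_true(all(e$label[e$t > 5] == "untracked"))
  # bin straddling two intervals gets the midpoint interval's label
  iv2 <- mk_intervals("a", c(0, 0.7), c(0.7, 2), c("Stop", "Hunch"))
  e2 <- build_ethogram(iv2, ts, bin_s = 1)
  expect_equal(e2$label[1], "Stop")     # midpoint 0.5 in [0, 0.7)
  e3 <- build_ethogram(mk_intervals("a", c(0, 0.3), c(0.3, 2),
                                    c("Stop", "Hunch")), ts, bin_s = 1)
  expect_equal(e3$label[1], "Hunch")    # midpoint 0.5 in [0.3, 2)
  # overlap rejected
  expect_error(build_ethogram(mk_intervals("a", c(0, 1), c(2, 3),
                                           c("Stop", "Hunch")), ts),
               "overlapping")
})

test_that("cumulative probability counts tracked-at-onset larvae once", {
  tracks <- lapply(sprintf("l%02d", 1:10), function(id)
    rigid_track(id, n = 100))                          # 0 .. 9.9 s
  # larva l11 starts tracking only after the window start
  late <- rigid_track("l11", n = 50)
  late$t <- late$t + 5.2
  ts <- track_set(c(tracks, list(late)))
  iv <- rbind(
    mk_intervals("l01", 5.5, 6.0, "Hunch"),
    mk_intervals("l02", 5.2, 5.8, "Hunch"),
    mk_intervals("l03", 6.0, 6.4, "Hunch"),
    mk_intervals("l04", c(5.1, 6.5), c(5.4, 6.9), c("Hunch", "Hunch")),
    mk_intervals("l11", 5.5, 6.0, "Hunch"))            # untracked at onset
  cp <- cumulative_probability(iv, ts, "Hunch", c(5, 8))
  expect_equal(cp$n, 10)                    # l11 excluded from denominator
  expect_equal(cp$p, 0.4)                   # l04 counted once
  expect_setequal(cp$performers, c("l01", "l02", "l03", "l04"))
  # action entirely outside the window does not count
  cp2 <- cumulative_probability(iv, ts, "Hunch", c(5, 5.05))
  expect_equal(cp2$p, 0)
  expect_error(cumulative_probability(iv, track_set(list(late)), "Hunch",
                                      c(0, 1)), "no larvae tracked")
})

test_that("transition matrix counts in-window destination starts", {
  iv <- rbind(mk_intervals("A", c(0, 2), c(2, 3), c("CShape", "Roll")),
              mk_intervals("B", c(0, 2), c(2, 3), c("CShape", "Crawl")))
  tm <- transition_matrix(iv)
  expect_equal(unname(tm$prob["CShape", "Roll"]), 0.5)
  expect_equal(unname(tm$prob["CShape", "Crawl"]), 0.5)
  # single interval per larva -> empty matrix
  tm1 <- transition_matrix(mk_intervals("A", 0, 2, "Crawl"))
  expect_equal(sum(tm1$counts), 0)
  # destination start outside the window is not counted
  tmw <- transition_matrix(iv, window = c(0, 1))
  expect_equal(sum(tmw$counts), 0)
  # adjacent same-label intervals are merged: no self transitions
  iv2 <- mk_intervals("A", c(0, 1, 2), c(1, 2, 3),
                      c("Crawl", "Crawl", "Hunch"))
  tm2 <- transition_matrix(iv2)
  expect_equal(sum(diag(tm2$counts)), 0)
  expect_equal(unname(tm2$counts["Crawl", "Hunch"]), 1)
  # sub-threshold cells are retained but flagged hidden
  many <- do.call(rbind, lapply(1:49, function(i)
    mk_intervals(paste0("x", i), c(0, 1), c(1, 2), c("Crawl", "Hunch"))))
  rare <- mk_intervals("y", c(0, 1), c(1, 2), c("Crawl", "Roll"))
  tm3 <- transition_matrix(rbind(many, rare))
  expect_equal(unname(tm3$prob["Crawl", "Roll"]), 0.02)
  expect_true(tm3$hidden["Crawl", "Roll"])
  expect_false(tm3$hidden["Crawl", "Hunch"])
  # rows over observed transitions sum to 1 (recount oracle)
  rs <- rowSums(tm3$prob, na.rm = TRUE)
  expect_equal(unname(rs[rowSums(tm3$counts) > 0]), 1)
})

test_that("chi-square matches the closed-form 2x2 statistic", {
  expect_equal(chi2_compare(rbind(c(10, 90), c(10, 90)))$chi2, 0)
  expect_equal(chi2_compare(rbind(c(10, 90), c(10, 90)))$p, 1)
  expect_equal(chi2_compare(rbind(c(5, 5), c(5, 5)))$chi2, 0)
  r <- chi2_compare(rbind(c(30, 70), c(10, 90)))
  expect_equal(r$chi2, 12.5, tolerance = 1e-12)
  expect_equal(r$df, 1)
  set.seed(31)
  for (i in 1:25) {
    m <- matrix(rpois(4, 40) + 1, 2)
    expect_equal(chi2_compare(m)$chi2, oracle_chi2_2x2(m),
                 tolerance = 1e-9)
  }
  expect_error(chi2_compare(rbind(c(0, 0), c(1, 2))), "zero margin")
  expect_error(chi2_compare(rbind(c(-1, 2), c(1, 2))), "nonnegative")
})

test_that("BH adjustment matches exhaustive step-up enumeration", {
  r <- bh_adjust(c(0.01, 0.02, 0.04), alpha = 0.05)
  expect_true(all(r$reject))
  expect_equal(bh_adjust(0.03)$adjusted, 0.03)
  expect_false(any(bh_adjust(c(1, 1, 1))$reject))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # planned-comparison mode reports raw p-values
  pl <- bh_adjust(c(0.04, 0.04, 0.04, 0.04), planned = TRUE)
  expect_equal(pl$adjusted, rep(0.04, 4))
  set.seed(17)
  for (i in 1:50) {
    n <- sample(1:8, 1)
    p <- round(runif(n), 3)
    a <- runif(1, 0.01, 0.2)
    got <- bh_adjust(p, alpha = a)
    expect_equal(got$reject, oracle_bh_reject(p, a))
    # adjusted p-values are monotone in the raw ordering
    o <- order(p)
    expect_true(all(diff(got$adjusted[o]) > -1e-12))
  }
})

test_that("KS statistic equals the ECDF supremum oracle", {
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(c(0, 0), c(1, 1))$D, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(2, 3, 4))$D, 1 / 3,
               tolerance = 1e-12)
  expect_error(ks_two_sample(numeric(0), 1), "nonempty")
  set.seed(23)
  for (i in 1:100) {
    x <- rnorm(sample(5:40, 1))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    expect_equal(ks_two_sample(x, y)$D, oracle_ks_D(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Gaussian KDE integrates to one and hits the normal density", {
  set.seed(41)
  d <- kde_density(rnorm(1e4))
  expect_equal(d$density[which.min(abs(d$x))], dnorm(0), tolerance = 0.03)
  # trapezoid integral over the returned grid
  integ <- sum(diff(d$x) * (d$density[-1] + d$density[-nrow(d)]) / 2)
  expect_equal(integ, 1, tolerance = 1e-3)
  # single point: kernel centred there
  d1 <- kde_density(2.5, bandwidth = 0.1)
  expect_equal(d1$x[which.max(d1$density)], 2.5, tolerance = 0.01)
  expect_warning(kde_density(rep(1, 10)), "zero-variance")
  expect_error(kde_density(numeric(0)), "empty")
})

test_that("stimulus-evoked fast crawls shift the speed distribution", {
  protocol <- stimulus_protocol(onset = 30, duration = 30)
  cfg <- population_config(n_larvae = 25, duration = 60, dropout = 0,
                           crawl_speed_mult = 1.5, seed = 8)
  pop <- simulate_population(cfg, protocol)
  iv <- data.frame(larva_id = pop$truth$larva_id, start = pop$truth$start,
                   end = pop$truth$end, refined_label = pop$truth$label,
                   stringsAsFactors = FALSE)
  res <- crawl_speed_comparison(pop$trackset, iv,
                                window_before = c(0, 30),
                                window_during = c(30, 60))
  expect_equal(mean(res$during) / mean(res$before), 1.5, tolerance = 0.15)
  expect_lt(res$ks$p, 0.01)
  # identical windows give D = 0
  same <- crawl_speed_comparison(pop$trackset, iv,
                                 window_before = c(0, 30),
                                 window_during = c(0, 30))
  expect_equal(same$ks$D, 0)
  expect_error(crawl_speed_comparison(pop$trackset,
                                      iv[iv$refined_label != "Crawl", ],
                                      window_before = c(0, 30),
                                      window_during = c(30, 60)),
               "window_before")
})
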