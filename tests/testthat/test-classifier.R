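test_that("rule-based base layer recognizes unambiguous motifs", {
  sim <- simulate_larva(behavior_script(c("Crawl", "Stop"), c(5, 3)),
                        seed = 2)
  iv <- base_classify(compute_frame_features(sim$track))
  # the crawl span opens with a Crawl interval and Stop dominates its span
  expect_equal(iv$coarse_label[1], "Crawl")
  expect_lt(iv$start[1], 0.2)
  stop_iv <- iv[iv$coarse_label == "Stop", , drop = FALSE]
  expect_gt(sum(pmin(stop_iv$end, 8) - pmax(stop_iv$start, 5)), 2)
})

test_that("pass-through mode returns external coarse intervals unchanged", {
  iv <- data.frame(larva_id = "a", start = c(0, 2), end = c(2, 5),
                   coarse_label = c("Crawl", "Bend"),
                   stringsAsFactors = FALSE)
  expect_identical(base_classify(NULL, coarse_intervals = iv), iv)
  bad <- iv; bad$start[2] <- 1
  expect_error(base_classify(NULL, coarse_intervals = bad), "overlapping")
})

test_that("static-bend auto-tag applies the low-speed rule on boundaries", {
  protocol <- stimulus_protocol(onset = 10, duration = 10)
  mk_iv <- function(start, end) {
    data.frame(larva_id = "a", start = start, end = end,
               coarse_label = "Bend", stringsAsFactors = FALSE)
  }
  tt <- seq(0, 25, by = 0.1)
  # during-stimulus Bend, speed 0.01 everywhere -> tagged
  s1 <- fake_series("a", tt, rep(0.01, length(tt)))
  expect_warning(
    tag1 <- auto_tag_training(mk_iv(11, 13), s1, protocol, seed = 1),
    "no pre-stimulus Bends")
  expect_equal(tag1$tag, "StaticBend")
  # speed 0.05 on 60% of frames (below threshold only 40%) -> not tagged
  v <- rep(c(0.05, 0.05, 0.05, 0.01, 0.01), length.out = length(tt))
  s2 <- fake_series("a", tt, v)
  expect_warning(tag2 <- auto_tag_training(mk_iv(11, 13), s2, protocol,
                                           seed = 1))
  expect_false("StaticBend" %in% tag2$tag)
  # exactly 50% of frames below threshold -> tagged (rule is >= half)
  v3 <- rep(c(0.05, 0.01), length.out = length(tt))
  s3 <- fake_series("a", tt, v3)
  expect_warning(tag3 <- auto_tag_training(mk_iv(11, 13), s3, protocol,
                                           seed = 1))
  expect_equal(tag3$tag, "StaticBend")
  # pre-stimulus Bend is never tagged StaticBend, but feeds the Head Cast
  # sample; fixed seed reproduces the sample
  iv4 <- mk_iv(c(1, 4, 11), c(3, 6, 13))
  t4a <- auto_tag_training(iv4, s1, protocol, seed = 7, n_headcast = 1)
  t4b <- auto_tag_training(iv4, s1, protocol, seed = 7, n_headcast = 1)
  expect_identical(t4a, t4b)
  expect_equal(sum(t4a$tag == "HeadCast"), 1)
  expect_true(all(t4a$end[t4a$tag == "HeadCast"] <= 10))
})

test_that("refinement training errors on missing or single classes", {
  sim <- simulate_population(population_config(n_larvae = 8, seed = 2),
                             stimulus_protocol())
  feats <- compute_features(sim$trackset)
  coarse <- base_classify(NULL, coarse_intervals = data.frame(
    larva_id = sim$truth$larva_id, start = sim$truth$start,
    end = sim$truth$end, coarse_label = coarse_from_refined(sim$truth$label),
    stringsAsFactors = FALSE))
  tagged <- auto_tag_training(coarse, feats, stimulus_protocol(), seed = 1,
                              truth = sim$truth)
  x <- interval_features(tagged, feats)
  x$tag <- tagged$tag
  # all classes present but some below the default minimum -> error names them
  expect_error(train_refinement(x, list(min_per_class = 1e6), seed = 1),
               "insufficient training examples")
  # single-class input
  x1 <- x[x$tag == "HeadCast", , drop = FALSE]
  expect_error(train_refinement(x1, list(min_per_class = 1), seed = 1),
               "StaticBend|newHunch|Hunch")
})

test_that("two-layer refinement recovers synthetic labels deterministically", {
  protocol <- stimulus_protocol()
  train_pop <- simulate_population(population_config(n_larvae = 50, seed = 21),
                                   protocol)
  test_pop <- simulate_population(population_config(n_larvae = 15, seed = 22),
                                  protocol)
  tf <- compute_features(train_pop$trackset)
  sf <- compute_features(test_pop$trackset)
  ctrain <- data.frame(larva_id = train_pop$truth$larva_id,
                       start = train_pop$truth$start,
                       end = train_pop$truth$end,
                       coarse_label = coarse_from_refined(train_pop$truth$label),
                       stringsAsFactors = FALSE)
  ctest <- data.frame(larva_id = test_pop$truth$larva_id,
                      start = test_pop$truth$start,
                      end = test_pop$truth$end,
                      coarse_label = coarse_from_refined(test_pop$truth$label),
                      refined_label = NA_character_, subtype = "none",
                      stringsAsFactors = FALSE)
  tagged <- auto_tag_training(ctrain, tf, protocol, seed = 3,
                              truth = train_pop$truth)
  x <- interval_features(tagged, tf)
  x$tag <- tagged$tag
  model <- train_refinement(x, list(min_per_class = 5), seed = 4)
  refined <- refine(ctest, sf, model)
  # non-Bend/Hunch coarse labels map one-to-one, untouched by the forests
  expect_true(all(refined$refined_label[refined$coarse_label == "Stop"] ==
                    "Stop"))
  expect_true(all(refined$refined_label[refined$coarse_label == "Back"] ==
                    "BackUp"))
  # refinement map is closed: Bend/Hunch only to the refined five
  expect_true(all(refined$refined_label[
    refined$coarse_label %in% c("Bend", "Hunch")] %in%
      c("HeadCast", "StaticBend", "Hunch", "HeadAndTail", "CShape")))
  # intervals tile the input exactly
  expect_equal(refined$start, ctest$start)
  expect_equal(refined$end, ctest$end)
  # high recovery on zero-noise data
  ev <- evaluate_classification(refined, test_pop$truth)
  expect_gt(ev$macro_f1, 0.9)
  # determinism: same data + seed -> identical predictions
  model2 <- train_refinement(x, list(min_per_class = 5), seed = 4)
  refined2 <- refine(ctest, sf, model2)
  expect_identical(refined$refined_label, refined2$refined_label)
  # empty interval list -> empty output
  empty <- refine(ctest[0, ], sf, model)
  expect_equal(nrow(empty), 0)
  # schema mismatch -> error
  expect_error(predict(model, data.frame(bogus = 1)), "schema mismatch")
  # print/summary methods run
  expect_output(print(model), "Two-layer")
  expect_output(summary(model), "Out-of-bag")
})

test_that("evaluation yields identity confusion for perfect predictions", {
  truth <- data.frame(larva_id = "a", start = c(0, 2, 5),
                      end = c(2, 5, 6),
                      label = c("Crawl", "HeadCast", "Hunch"),
                      stringsAsFactors = FALSE)
  pred <- data.frame(larva_id = "a", start = truth$start, end = truth$end,
                     refined_label = truth$label, stringsAsFactors = FALSE)
  ev <- evaluate_classification(pred, truth)
  expect_equal(ev$macro_f1, 1)
  expect_true(all(ev$confusion[ev$confusion > 0] ==
                    diag(ev$confusion)[rowSums(ev$confusion) > 0]))
  # all-one-class prediction: recall 1 for that class, 0 for the others
  pred2 <- pred; pred2$refined_label <- "Crawl"
  ev2 <- evaluate_classification(pred2, truth)
  expect_equal(unname(ev2$recall["Crawl"]), 1)
  expect_equal(unname(ev2$recall["Hunch"]), 0)
  # known relabeling matches the hand-computed matrix (durations 2, 3, 1 s)
  pred3 <- pred
  pred3$refined_label <- c("HeadCast", "Hunch", "Crawl")
  ev3 <- evaluate_classification(pred3, truth)
  expect_equal(unname(ev3$confusion["Crawl", "HeadCast"]), 20)
  expect_equal(unname(ev3$confusion["HeadCast", "Hunch"]), 30)
  expect_equal(unname(ev3$confusion["Hunch", "Crawl"]), 10)
})

test_that("head-cast subtypes follow the tail-speed threshold", {
  protocol <- stimulus_protocol(onset = 30, duration = 20)
  script <- behavior_script(
    c("Crawl", "HeadCast", "HeadCast", "Crawl"), c(2, 4, 4, 2),
    params = list(list(), list(), list(fast = TRUE), list()))
  sim <- simulate_larva(script, seed = 5)
  f <- compute_frame_features(sim$track)
  iv <- data.frame(larva_id = "larva1", start = sim$truth$start,
                   end = sim$truth$end,
                   coarse_label = coarse_from_refined(sim$truth$label),
                   stringsAsFactors = FALSE)
  fx <- interval_features(iv, f)
  # slow variant: tail speed comparable to CoM; fast: clearly above 0.08
  expect_lt(fx$v_tail_mean[2], 0.08)
  expect_gt(fx$v_tail_mean[3], 0.08)
})
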