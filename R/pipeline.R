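# End-to-end orchestration: simulate -> features -> train -> classify ->
# statistics, deterministic under one seed.

#' Run configuration
#'
#' One global seed is fanned out to per-stage child seeds (drawn once from
#' the global seed), so any stage can be rerun in isolation reproducibly.
#'
#' @param seed global integer seed.
#' @param n_train,n_test larvae in the (seed-disjoint) training and test
#'   populations.
#' @param noise list(point_sd, heading_drift) passed to the generator.
#' @param dropout fraction untracked at stimulus onset.
#' @param crawl_speed_mult post-onset Crawl speed multiplier.
#' @param base \code{"truth"}: coarse intervals derived from generator
#'   truth (pass-through base layer); \code{"rules"}: threshold-rule base
#'   layer.
#' @param hyperparams refinement hyperparameters
#'   (\code{\link{train_refinement}}).
#' @param windows named list of post-onset analysis windows (s after
#'   onset); defaults to the 1 s, 3 s and 5 s presets.
#' @param bin_s ethogram bin width.
#' @param protocol a \code{\link{stimulus_protocol}}.
#' @return a \code{run_config} list.
#' @export
run_config <- function(seed = 1, n_train = 60, n_test = 60,
                       noise = list(point_sd = 0.01, heading_drift = 0.02),
                       dropout = 0.1, crawl_speed_mult = 1.5,
                       base = c("truth", "rules"), hyperparams = list(),
                       windows = list(w1s = 1, w3s = 3, w5s = 5),
                       bin_s = 0.5, protocol = stimulus_protocol()) {
  base <- match.arg(base)
  if (n_train < 1 || n_test < 1) stop("population sizes must be >= 1")
  structure(list(seed = seed, n_train = n_train, n_test = n_test,
                 noise = noise, dropout = dropout,
                 crawl_speed_mult = crawl_speed_mult, base = base,
                 hyperparams = hyperparams, windows = windows,
                 bin_s = bin_s, protocol = protocol),
            class = "run_config")
}

stage_seeds <- function(seed, n = 6L) {
  set.seed(seed)
  sample.int(2^30, n)
}

coarse_intervals_from_truth <- function(truth) {
  new_action_intervals(truth$larva_id, truth$start, truth$end,
                       coarse_from_refined(truth$label))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulates a training and a test population under the stimulus protocol,
#' computes features, builds the refinement training set (auto-tagged Head
#' Casts and Static Bends; Hunch / Head-and-Tail / C-shape from ground
#' truth), fits the two-layer model, refines the test population's coarse
#' intervals, and computes the population statistics (ethogram, cumulative
#' action probabilities per window, transition matrix over the first
#' seconds after onset, crawl-speed comparison).  With \code{out_dir} set,
#' all outputs are written as deterministic CSV/JSON files.
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir optional output directory.
#' @return list of stage outputs (invisible when writing to disk).
#' @export
run_experiment <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  ss <- stage_seeds(config$seed)
  onset <- config$protocol$onset[1]

  pop_cfg <- function(n, sd1) population_config(
    n_larvae = n, noise = config$noise, dropout = config$dropout,
    crawl_speed_mult = config$crawl_speed_mult, seed = sd1)
  train_pop <- simulate_population(pop_cfg(config$n_train, ss[1]),
                                   config$protocol)
  test_pop <- simulate_population(pop_cfg(config$n_test, ss[2]),
                                  config$protocol)

  train_feats <- compute_features(train_pop$trackset)
  test_feats <- compute_features(test_pop$trackset)

  coarse_train <- if (config$base == "truth")
    coarse_intervals_from_truth(train_pop$truth)
  else base_classify(train_feats)
  coarse_test <- if (config$base == "truth")
    coarse_intervals_from_truth(test_pop$truth)
  else base_classify(test_feats)

  tagged <- auto_tag_training(coarse_train, train_feats, config$protocol,
                              seed = ss[3], truth = train_pop$truth)
  train_x <- interval_features(tagged, train_feats)
  train_x$tag <- tagged$tag
  model <- train_refinement(train_x, config$hyperparams, seed = ss[4])

  refined <- refine(coarse_test, test_feats, model)
  eval_res <- evaluate_classification(refined, test_pop$truth)

  etho <- build_ethogram(refined, test_pop$trackset, config$bin_s)
  probs <- do.call(rbind, lapply(names(config$windows), function(wn) {
    w <- c(onset, onset + config$windows[[wn]])
    do.call(rbind, lapply(refined_labels(), function(a) {
      cp <- cumulative_probability(refined, test_pop$trackset, a, w)
      data.frame(window = wn, action = a, p = cp$p, n = cp$n,
                 stringsAsFactors = FALSE)
    }))
  }))
  tm <- transition_matrix(refined, window = c(onset, onset + 3))
  speed_cmp <- crawl_speed_comparison(
    test_pop$trackset, refined, test_feats,
    window_before = c(0, onset), window_during = c(onset, onset + 30))

  res <- list(config = config, model = model, refined = refined,
              truth = test_pop$truth, evaluation = eval_res,
              ethogram = etho, probabilities = probs, transitions = tm,
              crawl_speed = speed_cmp, dropped = test_pop$dropped)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(d, f) utils::write.csv(
      d, file.path(out_dir, f), row.names = FALSE)
    write_track_table(test_pop$trackset, file.path(out_dir, "tracks.tsv"))
    wcsv(test_pop$truth, "truth.csv")
    wcsv(refined, "intervals.csv")
    wcsv(as.data.frame(etho), "ethogram.csv")
    wcsv(probs, "probabilities.csv")
    wcsv(as.data.frame(as.table(tm$prob),
                       stringsAsFactors = FALSE), "transitions.csv")
    metrics <- list(
      macro_f1 = eval_res$macro_f1,
      recall = as.list(eval_res$recall),
      precision = as.list(eval_res$precision),
      ks_crawl_speed = speed_cmp$ks)
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    cfg_out <- config
    cfg_out$protocol <- as.data.frame(config$protocol)
    yaml::write_yaml(cfg_out, file.path(out_dir, "config.yaml"))
    return(invisible(res))
  }
  res
}
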