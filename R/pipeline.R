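#' Default pipeline configuration
#'
#' One configuration object drives the full analysis. Defaults mirror the
#' study design this pipeline implements: 1-km spatial thinning, 10,000
#' target-group background points (scaled down by `background_n` for small
#' synthetic worlds), cloglog output, MTSS + 0.8 binary thresholds, 7 Jenks
#' cost classes, and warming scenarios applied to the temperature layers
#' while topography and land cover are held constant.
#'
#' @param world List: `n_rows`, `n_cols`, `seed` for the synthetic world.
#' @param n_presence,bias_strength Occurrence sampling settings.
#' @param n_target_group Target-group record count.
#' @param thin_km Minimum thinning distance (km).
#' @param background_n Background point count.
#' @param density_sigma Density-raster kernel width (cells).
#' @param screen Logical: run the two-step variable screen.
#' @param feature_classes,rm_values Tuning grid.
#' @param cv_scheme `"kfold10"` or `"spatial_block"`.
#' @param criterion `"aicc_min"` or `"sequential"`.
#' @param spec_args Knot/clamp settings for [feature_spec()].
#' @param scenarios Named list of `list(delta_T, precip_scale)` entries.
#' @param optimal_threshold Optimal-habitat threshold (default 0.8).
#' @param jenks_classes Number of cost classes (default 7).
#' @param cost_at_threshold Suitability-cost ceiling at MTSS (default 1000).
#' @param seed Master seed for every stochastic stage.
#' @return A `run_config` list.
#' @export
run_config <- function(world = list(n_rows = 60, n_cols = 80, seed = 101),
                       n_presence = 250, bias_strength = 1,
                       n_target_group = 2000,
                       thin_km = 1, background_n = 1500, density_sigma = 5,
                       screen = FALSE,
                       feature_classes = "LQ", rm_values = 1,
                       cv_scheme = "kfold10", criterion = "aicc_min",
                       spec_args = list(n_hinge_knots = 6, n_threshold_knots = 6),
                       scenarios = list(
                         warm1 = list(delta_T = 1, precip_scale = 0.95),
                         warm2 = list(delta_T = 2, precip_scale = 0.9),
                         warm3 = list(delta_T = 3, precip_scale = 0.85)),
                       optimal_threshold = 0.8, jenks_classes = 7,
                       cost_at_threshold = 1000, seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Fields absent from the file keep their [run_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(run_config, y)
}

#' Run the full habitat-suitability and range-shift pipeline
#'
#' Executes the stages in analysis order on a synthetic world: generate
#' world -> sample + thin occurrences -> target-group density raster ->
#' background sampling -> (optional) variable screen -> candidate-model
#' tuning and selection -> final fit and evaluation -> scenario projection
#' -> per-scenario cost surfaces, cost distance and dispersal limits ->
#' scenario summary. Every stochastic stage is seeded from `config$seed`,
#' so two runs with the same config are bit-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory: writes `summary.csv`,
#'   `candidates.csv`, `model.json`, suitability/mask ASCII grids and a
#'   `run_log.txt` with per-stage timings and the config hash.
#' @param quiet Suppress progress messages.
#' @return List with `world`, `occurrences`, `background`, `screen`,
#'   `candidates`, `selected`, `model`, `evaluation`, `suitability` (named
#'   list of grids), `limits`, `mtss`, `summary` (tibble).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time(); log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf("[%6.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                   sprintf(fmt, ...))
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  cfg <- config
  say("world: %dx%d seed %d", cfg$world$n_rows, cfg$world$n_cols, cfg$world$seed)
  world <- make_world(cfg$world$n_rows, cfg$world$n_cols, cfg$world$seed)

  occ_raw <- sample_occurrences(world, cfg$n_presence,
                                bias_strength = cfg$bias_strength,
                                seed = cfg$seed + 1)
  occ <- thin_occurrences(occ_raw, cfg$thin_km, seed = cfg$seed + 2)
  say("occurrences: %d sampled, %d after %g-km thinning",
      nrow(occ_raw), nrow(occ), cfg$thin_km)

  tg <- sample_target_group(world, cfg$n_target_group, seed = cfg$seed + 3)
  tg <- thin_occurrences(tg, cfg$thin_km, seed = cfg$seed + 4)
  bias <- density_raster(tg, stack_template(world$stack),
                         kernel_sigma_cells = cfg$density_sigma)
  bg <- sample_background(bias, cfg$background_n, seed = cfg$seed + 5)
  say("background: %d points from density raster of %d target-group records",
      nrow(bg), nrow(tg))

  stack <- world$stack
  screen_rep <- NULL
  if (isTRUE(cfg$screen)) {
    screen_rep <- screen_variables(occ, bg, stack, seed = cfg$seed + 6)
    stack <- align_stack(stack$layers[screen_rep$final_variables])
    say("screen: retained %s", paste(screen_rep$final_variables, collapse = ", "))
  }

  cand <- tune_candidates(occ, bg, stack,
                          feature_classes = cfg$feature_classes,
                          rm_values = cfg$rm_values,
                          scheme = cfg$cv_scheme, seed = cfg$seed + 7,
                          spec_args = cfg$spec_args)
  sel <- select_candidate(cand, cfg$criterion)
  say("tuning: %d candidates; selected %s rm %g (%s)",
      nrow(cand), sel$feature_classes, sel$rm, cfg$criterion)

  spec <- do.call(feature_spec, c(list(classes = sel$feature_classes),
                                  cfg$spec_args))
  model <- fit_maxent(occ, bg, stack, spec = spec, rm = sel$rm,
                      on_nonconvergence = "warn")

  scen_stacks <- c(list(current = stack),
                   lapply(cfg$scenarios, function(s) {
                     full <- make_scenario(world, s$delta_T, s$precip_scale)
                     align_stack(full$layers[names(stack$layers)])
                   }))
  suit <- lapply(scen_stacks, function(s) predict.sdm_maxent(model, s))

  # per-scenario MTSS from that scenario's presence/background scores
  mtss <- vapply(names(scen_stacks), function(id) {
    sp <- predict_points(model, scen_stacks[[id]], occ$lon, occ$lat)
    sb <- predict_points(model, scen_stacks[[id]], bg$lon, bg$lat)
    mtss_threshold(sp[!is.na(sp)], sb[!is.na(sb)])
  }, numeric(1))
  say("mtss: current %.4f", mtss[["current"]])

  limits <- lapply(names(scen_stacks), function(id) {
    cost <- suitability_cost(suit[[id]], mtss[[id]],
                             cost_at_threshold = cfg$cost_at_threshold)
    acc <- cost_distance(cost, occ)
    limit_mask(acc, cfg$jenks_classes)
  })
  names(limits) <- names(scen_stacks)
  say("dispersal limits computed for %d scenarios", length(limits))

  elev <- world$stack$layers$elevation
  summary <- summarize_scenarios(suit, limits, mtss, elev,
                                 optimal_threshold = cfg$optimal_threshold)

  sc_p <- predict_points(model, stack, occ$lon, occ$lat)
  sc_b <- predict_points(model, stack, bg$lon, bg$lat)
  sc_p <- sc_p[!is.na(sc_p)]; sc_b <- sc_b[!is.na(sc_b)]
  thr <- mtss[["current"]]
  evaluation <- tibble::tibble(
    train_auc = auc_mw(sc_p, sc_b),
    mean_test_auc = sel$mean_test_auc, auc_diff = sel$auc_diff,
    or10 = sel$or10,
    tss = tss(sum(sc_p >= thr), sum(sc_p < thr),
              sum(sc_b < thr), sum(sc_b >= thr)),
    mtss = thr
  )
  say("evaluation: train AUC %.3f, TSS %.3f", evaluation$train_auc,
      evaluation$tss)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(cand, file.path(out_dir, "candidates.csv"),
                     row.names = FALSE)
    write_maxent_json(model, file.path(out_dir, "model.json"))
    for (id in names(suit)) {
      write_ascii_grid(suit[[id]], file.path(out_dir, paste0("suitability_", id, ".asc")))
      write_ascii_grid(limits[[id]]$mask, file.path(out_dir, paste0("limit_", id, ".asc")))
    }
    cfg_file <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(unclass(cfg), cfg_file)
    say("outputs written to %s (config hash %s)", out_dir,
        substr(unname(tools::md5sum(cfg_file)), 1, 12))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }

  list(world = world, occurrences = occ, background = bg,
       screen = screen_rep, candidates = cand, selected = sel, model = model,
       evaluation = evaluation, suitability = suit, limits = limits,
       mtss = mtss, summary = summary)
}

#' Plot the scenario summary as range-contraction curves
#'
#' @param summary Tibble from [summarize_scenarios()] / [run_pipeline()].
#' @return A ggplot of suitable and optimal areas per scenario.
#' @export
plot_range_change <- function(summary) {
  df <- tidyr::pivot_longer(summary, c("suitable_km2", "optimal_km2"),
                            names_to = "habitat", values_to = "area_km2")
  df$habitat <- sub("_km2", "", df$habitat)
  df$scenario <- factor(df$scenario, levels = summary$scenario)
  ggplot2::ggplot(df, ggplot2::aes(.data$scenario, .data$area_km2,
                                   group = .data$habitat,
                                   colour = .data$habitat)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = expression(Area ~ (km^2)), colour = "Habitat")
}
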