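# File-based pipeline driver: sigma-profiles -> descriptors -> mixture
# descriptors -> kinetic fits -> QSPR model -> evaluation report, each
# stage reading only files written by earlier stages so a run directory is
# a complete, reproducible record.

#' Assemble a pipeline configuration
#'
#' Either point the pipeline at existing inputs (`profiles_dir`,
#' `recipes_yaml`, `kinetics_csv`) or set `simulate = TRUE` to have the
#' synthetic-data generator write a full input tree first. All randomness
#' (simulation, splitting, architecture search, weight initialization)
#' flows from the single `seed`.
#'
#' @param out_dir Run directory (created if missing).
#' @param seed Integer master seed; required, no implicit randomness.
#' @param simulate Generate synthetic inputs into `out_dir/inputs`.
#' @param n_systems,water_levels,n_solid,sigma_noise Passed to
#'   [synthetic_spec()] when simulating.
#' @param profiles_dir Directory of two-column sigma-profile files.
#' @param area_convention Profile ordinate convention, see
#'   [read_sigma_profile()]; never guessed.
#' @param recipes_yaml YAML recipe file (see the pipeline vignette for the
#'   schema).
#' @param kinetics_csv Long CSV of residual activities: label, time_days,
#'   residual_percent.
#' @param censor_policy Passed to [censor_series()].
#' @param selection_threshold Spearman |rho| cutoff for input selection;
#'   `NULL` uses all ten descriptors.
#' @param calibration,seed_split Calibration size (count or fraction) and
#'   split seed for [split_spec()]; `seed_split` defaults to `seed`.
#' @param n_candidates Architecture-search budget.
#' @param epochs,learn_rate Training schedule, see [train_mlp()].
#' @param denominator RPD/RER denominator, see [prediction_metrics()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed, simulate = FALSE,
                            n_systems = 10L, water_levels = c(10, 30, 50),
                            n_solid = 2L, sigma_noise = 0.05,
                            profiles_dir = NULL,
                            area_convention = "area",
                            recipes_yaml = NULL, kinetics_csv = NULL,
                            censor_policy = "drop_over_100",
                            selection_threshold = 0.4,
                            calibration = 0.65, seed_split = NULL,
                            n_candidates = 10L, epochs = 1500L,
                            learn_rate = 0.1,
                            denominator = "sep") {
  if (missing(seed) || is.null(seed))
    stop("an explicit seed is required")
  if (!simulate) {
    for (p in c(profiles_dir, recipes_yaml, kinetics_csv))
      if (!file.exists(p)) stop("input path does not exist: ", p)
    if (is.null(profiles_dir) || is.null(recipes_yaml) || is.null(kinetics_csv))
      stop("without simulate = TRUE, profiles_dir, recipes_yaml and kinetics_csv are required")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = isTRUE(simulate), n_systems = n_systems,
                 water_levels = water_levels, n_solid = n_solid,
                 sigma_noise = sigma_noise,
                 profiles_dir = profiles_dir,
                 area_convention = area_convention,
                 recipes_yaml = recipes_yaml, kinetics_csv = kinetics_csv,
                 censor_policy = censor_policy,
                 selection_threshold = selection_threshold,
                 calibration = calibration,
                 seed_split = if (is.null(seed_split)) as.integer(seed) else as.integer(seed_split),
                 n_candidates = n_candidates, epochs = epochs,
                 learn_rate = learn_rate, denominator = denominator),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.stage <- function(name, log, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  el <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  cat(sprintf("[%s] stage %-12s finished in %.2f s\n",
              format(Sys.time(), "%H:%M:%S"), name, el), file = log,
      append = TRUE)
  res
}

# write the synthetic input tree: profiles/, recipes.yaml, decays.csv,
# truth.json
.simulate_inputs <- function(config, input_dir) {
  spec <- synthetic_spec(seed = config$seed, n_systems = config$n_systems,
                         water_levels = config$water_levels,
                         n_solid = config$n_solid,
                         sigma_noise = config$sigma_noise)
  lib <- synth_library(spec)
  prof_dir <- file.path(input_dir, "profiles")
  dir.create(prof_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(lib$profiles))
    write_sigma_profile(lib$profiles[[nm]], file.path(prof_dir, paste0(nm, ".txt")))

  sys_yaml <- lapply(lib$systems, function(s) list(
    index = s$index,
    constituents = lapply(s$constituents, function(cc)
      list(name = cc$name, role = cc$role, molar_mass = cc$molar_mass)),
    molar_parts = as.list(s$molar_parts),
    solid_at = as.list(s$solid_at)))
  yaml::write_yaml(list(water_levels = as.list(config$water_levels),
                        systems = sys_yaml),
                   file.path(input_dir, "recipes.yaml"))

  truth <- synth_qspr_truth(lib$table, family = "mlp",
                            seed = config$seed + 101L)
  rows <- vector("list", nrow(lib$table))
  for (i in seq_len(nrow(lib$table))) {
    s <- synth_decay_series(truth$k[i], spec,
                            seed = (config$seed + 500L + i) %% .Machine$integer.max,
                            label = lib$table$label[i])
    rows[[i]] <- data.frame(label = s$label, time_days = s$times,
                            residual_percent = s$residual,
                            stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, rows), file.path(input_dir, "decays.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(k_true_per_day = truth$k,
                            labels = lib$table$label,
                            family = truth$family),
                       file.path(input_dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  list(profiles_dir = prof_dir,
       recipes_yaml = file.path(input_dir, "recipes.yaml"),
       kinetics_csv = file.path(input_dir, "decays.csv"))
}

# rebuild constituent objects from the recipes YAML plus the descriptor CSV
.recipes_from_files <- function(recipes_yaml, descriptor_csv) {
  spec <- yaml::read_yaml(recipes_yaml)
  dtab <- utils::read.csv(descriptor_csv, stringsAsFactors = FALSE)
  lookup <- function(nm) {
    row <- dtab[dtab$name == nm, ]
    if (nrow(row) != 1L)
      stop("constituent '", nm, "' missing from descriptor table")
    descriptor_vector(as.numeric(row[paste0("S", 1:10)]),
                      truncated_mass = row$truncated_mass, name = nm)
  }
  systems <- lapply(spec$systems, function(s) {
    cons <- lapply(s$constituents, function(cc)
      constituent(cc$name, role = cc$role, molar_mass = cc$molar_mass,
                  descriptors = lookup(cc$name)))
    des_system(s$index, cons, unlist(s$molar_parts),
               solid_at = unlist(s$solid_at))
  })
  water <- constituent("water", role = "water", molar_mass = 18.015,
                       descriptors = lookup("water"))
  list(systems = systems, water = water,
       water_levels = unlist(spec$water_levels))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: (optional) simulate inputs; integrate constituent
#' sigma-profiles into descriptors (`descriptors.csv`); enumerate recipes
#' and compute mixture descriptors (`mixture_descriptors.csv`); fit
#' first-order inactivation kinetics (`kinetic_fits.csv`); select inputs,
#' split, and run the architecture search (`model.json`); evaluate on the
#' held-out prediction set (`report.json`, `report.csv`). Every stage
#' writes its output before the next starts and consumes only files, so
#' rerunning with the same configuration and inputs reproduces identical
#' outputs; `manifest.json` records the configuration hash, seed and stage
#' timings.
#'
#' @param config A [pipeline_config()], or the path to a YAML file of one.
#' @return Invisibly, a list with the run directory, file paths, the
#'   trained model and the evaluation report.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(out, "pipeline.log")
  cat("pipeline run, seed", config$seed, "\n", file = log)

  config_path <- file.path(out, "config.json")
  jsonlite::write_json(unclass(config), config_path, digits = NA,
                       auto_unbox = TRUE, null = "null")

  if (config$simulate) {
    paths <- .stage("simulate", log,
                    .simulate_inputs(config, file.path(out, "inputs")))
    config$profiles_dir <- paths$profiles_dir
    config$recipes_yaml <- paths$recipes_yaml
    config$kinetics_csv <- paths$kinetics_csv
  }

  descriptors_csv <- file.path(out, "descriptors.csv")
  .stage("descriptors", log, {
    files <- sort(list.files(config$profiles_dir, full.names = TRUE))
    if (!length(files)) stop("no profile files in ", config$profiles_dir)
    descs <- lapply(files, function(f)
      integrate_descriptors(read_sigma_profile(f, config$area_convention)))
    write_descriptor_table(descs, descriptors_csv)
  })

  mixture_csv <- file.path(out, "mixture_descriptors.csv")
  .stage("mix", log, {
    rec <- .recipes_from_files(config$recipes_yaml, descriptors_csv)
    recipes <- enumerate_library(rec$systems, rec$water_levels)
    utils::write.csv(mixture_descriptor_table(recipes, rec$water),
                     mixture_csv, row.names = FALSE)
  })

  fits_csv <- file.path(out, "kinetic_fits.csv")
  .stage("fit-kinetics", log, {
    decays <- utils::read.csv(config$kinetics_csv, stringsAsFactors = FALSE)
    set.seed(config$seed + 1L)  # jittered restarts, if any
    utils::write.csv(fit_kinetics_table(decays, policy = config$censor_policy),
                     fits_csv, row.names = FALSE)
  })

  model_json <- file.path(out, "model.json")
  split_json <- file.path(out, "split.json")
  search <- .stage("train", log, {
    mixt <- utils::read.csv(mixture_csv, stringsAsFactors = FALSE)
    fits <- utils::read.csv(fits_csv, stringsAsFactors = FALSE)
    merged <- merge(mixt, fits[, c("label", "k_per_h")], by = "label")
    merged <- merged[is.finite(merged$k_per_h) & merged$k_per_h > 0, ]
    merged <- merged[order(merged$label), ]
    ds <- qspr_dataset(merged[, paste0("S", 1:10)], merged$k_per_h,
                       transform = "log10")
    inputs <- if (is.null(config$selection_threshold)) 1:10 else
      select_inputs(spearman_matrix(ds), config$selection_threshold)
    sp <- split_spec(calibration = config$calibration,
                     seed = config$seed_split)
    split <- split_dataset(ds, sp)
    jsonlite::write_json(c(split$calibration,
                           list(prediction = split$prediction,
                                labels = merged$label)),
                         split_json, digits = NA)
    res <- random_search(ds, split, n_candidates = config$n_candidates,
                         seed = config$seed, inputs = inputs,
                         epochs = config$epochs,
                         learn_rate = config$learn_rate)
    save_model(res$model, model_json)
    utils::write.csv(res$leaderboard, file.path(out, "leaderboard.csv"),
                     row.names = FALSE)
    c(res, list(dataset = ds, split = split, inputs = inputs,
                labels = merged$label))
  })

  report_json <- file.path(out, "report.json")
  report <- .stage("evaluate", log, {
    model <- load_model(model_json)
    ds <- search$dataset
    split <- search$split
    pidx <- split$prediction
    obs <- ds$y[pidx]
    prd <- predict(model, ds$x[pidx, search$inputs, drop = FALSE],
                   type = "transformed")
    pm <- prediction_metrics(obs, prd, n_predictors = length(search$inputs),
                              denominator = config$denominator)
    blocks <- rep(NA_character_, nrow(ds$x))
    blocks[split$calibration$train] <- "train"
    blocks[split$calibration$test] <- "test"
    blocks[split$calibration$validation] <- "validation"
    cidx <- which(!is.na(blocks))
    cal <- calibration_metrics(
      ds$y[cidx],
      predict(model, ds$x[cidx, search$inputs, drop = FALSE],
              type = "transformed"),
      blocks[cidx])
    write_evaluation_report(pm, report_json, calibration = cal,
                            network = model$architecture$name)
    cls <- classify_model(pm)
    utils::write.csv(
      data.frame(network = model$architecture$name,
                 hidden = model$architecture$hidden_activation,
                 output = model$architecture$output_activation,
                 r2_train = cal$r2[cal$block == "train"],
                 r2_test = cal$r2[cal$block == "test"],
                 r2_validation = cal$r2[cal$block == "validation"],
                 r2_pred = pm$r2_pred, r2_pred_adj = pm$r2_pred_adj,
                 rmsep = pm$rmsep, sep = pm$sep, rpd = pm$rpd,
                 rer = pm$rer, quality = cls$quality,
                 usability = cls$usability),
      file.path(out, "report.csv"), row.names = FALSE)
    pm
  })

  manifest <- list(
    config_md5 = unname(tools::md5sum(config_path)),
    seed = config$seed,
    stages = c("simulate"[config$simulate], "descriptors", "mix",
               "fit-kinetics", "train", "evaluate"),
    outputs = list(descriptors = basename(descriptors_csv),
                   mixture_descriptors = basename(mixture_csv),
                   kinetic_fits = basename(fits_csv),
                   model = basename(model_json),
                   report = basename(report_json)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(list(out_dir = out, model = search$model, report = report,
                 leaderboard = search$leaderboard,
                 files = c(descriptors = descriptors_csv,
                           mixtures = mixture_csv, fits = fits_csv,
                           model = model_json, report = report_json,
                           manifest = file.path(out, "manifest.json"))))
}
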