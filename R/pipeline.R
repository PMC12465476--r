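#' Default run configuration
#'
#' The pipeline is configured by a single list (serialisable as YAML):
#' file paths, screening thresholds, panel quota, model options and seeds.
#' Command-line flags of the bundled runner script override config values.
#'
#' @return nested named list of defaults.
#' @export
default_run_config <- function() {
  list(
    out_dir = "renomark_out",
    paths = list(atlas = NULL, sample_sheet = NULL, plate = NULL,
                 cohort = NULL),
    screen = list(tau_target = 0.5, tau_background = 0.15,
                  tau_blood = 0.05, min_margin = 0.3),
    quota = list(pan_renal = 1, endothelial = 6, epithelial = 2),
    min_replicates = 2,
    model = list(alpha = 0.05, cv_folds = NULL),
    atlas_sim = list(n_null_blocks = 2000, missing_rate = 0.05),
    cohort_sim = list(counting_noise = FALSE),
    seed = 1
  )
}

#' Read a run configuration from YAML
#'
#' Missing keys fall back to [default_run_config()].
#'
#' @param path YAML path, or `NULL` for pure defaults.
#' @return config list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    merge_cfg <- function(base, over) {
      for (k in names(over)) {
        base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]])) {
          merge_cfg(base[[k]], over[[k]])
        } else {
          over[[k]]
        }
      }
      base
    }
    cfg <- merge_cfg(cfg, user)
  }
  cfg
}

log_msg <- function(con, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run a pipeline stage
#'
#' Chains the package's stages under one entry point. Subcommands:
#' `simulate-atlas`, `screen`, `simulate-plate`, `quantify`,
#' `simulate-cohort`, `diagnose`, and `all`
#' (simulate-atlas, screen, simulate-cohort, diagnose). Stage outputs land
#' in `config$out_dir` together with a run log recording the package
#' version, config digest, seeds and input digests.
#'
#' @param subcommand one of the stage names above.
#' @param config config list (see [default_run_config()]) or a YAML path.
#' @param seed overrides `config$seed` when non-`NULL`.
#' @return invisibly, a named list of written artifact paths.
#' @export
run_pipeline <- function(subcommand = "all", config = default_run_config(),
                         seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!is.null(seed)) config$seed <- seed
  stages <- c("simulate-atlas", "screen", "simulate-plate", "quantify",
              "simulate-cohort", "diagnose", "all")
  if (!subcommand %in% stages) {
    stop("unknown subcommand '", subcommand, "'; expected one of: ",
         paste(stages, collapse = ", "))
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  con <- file(log_path, open = "a")
  on.exit(close(con))
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfg_file)
  log_msg(con, "renomark ", as.character(utils::packageVersion("renomark")),
          " | stage: ", subcommand, " | seed: ", config$seed,
          " | config digest: ", unname(tools::md5sum(cfg_file)))
  unlink(cfg_file)

  run_stage <- function(stage) {
    tryCatch(do.call(paste0("stage_", gsub("-", "_", stage)),
                     list(config, con)),
             error = function(e) {
               log_msg(con, "stage '", stage, "' FAILED: ",
                       conditionMessage(e))
               stop("pipeline stage '", stage, "' failed: ",
                    conditionMessage(e), call. = FALSE)
             })
  }
  arts <- list()
  todo <- if (subcommand == "all") {
    c("simulate-atlas", "screen", "simulate-cohort", "diagnose")
  } else {
    subcommand
  }
  for (stage in todo) {
    arts[[stage]] <- run_stage(stage)
    # chain the freshly written artifacts into the next stage's inputs
    if (stage == "simulate-atlas") {
      config$paths$atlas <- arts[[stage]][["atlas"]]
      config$paths$sample_sheet <- arts[[stage]][["sample_sheet"]]
    }
    if (stage == "simulate-cohort") {
      config$paths$cohort <- arts[[stage]][["cohort"]]
    }
  }
  log_msg(con, "stage '", subcommand, "' complete")
  invisible(arts)
}

require_path <- function(path, what) {
  if (is.null(path)) stop("no ", what, " path configured")
  if (!file.exists(path)) stop(what, " file not found: ", path)
  path
}

stage_simulate_atlas <- function(config, con) {
  spec <- atlas_gen_spec(
    n_null_blocks = config$atlas_sim$n_null_blocks,
    missing_rate = config$atlas_sim$missing_rate,
    seed = config$seed
  )
  sim <- gen_atlas(spec)
  out <- config$out_dir
  paths <- c(atlas = file.path(out, "atlas_beta.tsv"),
             sample_sheet = file.path(out, "atlas_samples.tsv"),
             truth = file.path(out, "atlas_truth.yaml"))
  write_atlas(sim$atlas, paths[["atlas"]], paths[["sample_sheet"]])
  write_truth(sim$truth, paths[["truth"]])
  log_msg(con, "simulated atlas: ", nrow(sim$atlas$blocks), " blocks, ",
          nrow(sim$atlas$samples), " samples -> ", paths[["atlas"]])
  paths
}

stage_screen <- function(config, con) {
  atlas <- read_atlas(require_path(config$paths$atlas, "atlas"),
                      require_path(config$paths$sample_sheet,
                                   "sample sheet"))
  atlas <- filter_blocks_by_replication(atlas, config$min_replicates)
  cfg <- screen_config(tau_target = config$screen$tau_target,
                       tau_background = config$screen$tau_background,
                       tau_blood = config$screen$tau_blood,
                       min_margin = config$screen$min_margin)
  specs <- default_target_specs()
  screens <- lapply(specs, function(sp) screen_markers(atlas, sp, cfg))
  panel <- select_panel(screens, quota = unlist(config$quota))
  out <- config$out_dir
  paths <- c(panel = file.path(out, "panel.yaml"))
  for (nm in names(screens)) {
    p <- file.path(out, paste0("screen_", nm, ".tsv"))
    write_screen_report(screens[[nm]], p)
    paths[[paste0("screen_", nm)]] <- p
  }
  write_panel(panel, paths[["panel"]])
  log_msg(con, "screen: ",
          paste(vapply(screens, nrow, 1L), collapse = "/"),
          " passing markers (", paste(names(screens), collapse = "/"),
          ") -> ", paths[["panel"]])
  paths
}

stage_simulate_plate <- function(config, con) {
  panel <- default_panel()
  markers <- panel_markers(panel)
  set.seed(config$seed)
  # one healthy-like and one injury-like sample around plausible ratios
  truth <- rbind(
    data.frame(sample_id = "healthy_cfDNA", assay_name = c(markers, "ALB"),
               copies = c(rep(2, length(markers)), 2000)),
    data.frame(sample_id = "injury_cfDNA", assay_name = c(markers, "ALB"),
               copies = c(rep(40, length(markers)), 2000))
  )
  sim <- gen_dpcr_plate(truth, panel, seed = config$seed, controls = TRUE)
  out <- config$out_dir
  paths <- c(plate = file.path(out, "plate.csv"),
             truth = file.path(out, "plate_truth.yaml"))
  write_plate(sim$plate, paths[["plate"]])
  write_truth(sim$truth, paths[["truth"]])
  log_msg(con, "simulated plate: ", nrow(sim$plate), " reactions -> ",
          paths[["plate"]])
  paths
}

stage_quantify <- function(config, con) {
  plate <- read_plate(require_path(config$paths$plate, "plate"))
  panel <- default_panel()
  q <- quantify_reactions(plate[plate$control_type == "sample", ,
                                drop = FALSE], panel)
  out <- config$out_dir
  paths <- c(quant = file.path(out, "quantification.csv"))
  utils::write.csv(q, paths[["quant"]], row.names = FALSE)
  if (any(plate$control_type != "sample")) {
    ctrl <- validate_controls(plate, panel)
    paths[["controls"]] <- file.path(out, "control_report.csv")
    utils::write.csv(ctrl, paths[["controls"]], row.names = FALSE)
    log_msg(con, "controls: ", sum(ctrl$pass), "/", nrow(ctrl),
            " assay checks passed")
  }
  log_msg(con, "quantified ", nrow(q), " reactions -> ", paths[["quant"]])
  paths
}

stage_simulate_cohort <- function(config, con) {
  spec <- cohort_gen_spec(counting_noise =
                            isTRUE(config$cohort_sim$counting_noise),
                          seed = config$seed)
  sim <- gen_cohort(spec)
  out <- config$out_dir
  paths <- c(cohort = file.path(out, "cohort.csv"),
             truth = file.path(out, "cohort_truth.yaml"))
  write_cohort(sim$records, paths[["cohort"]])
  write_truth(sim$truth["spec"], paths[["truth"]])
  log_msg(con, "simulated cohort: ", nrow(sim$records), " records (",
          sum(sim$records$rejection), " rejections) -> ", paths[["cohort"]])
  paths
}

stage_diagnose <- function(config, con) {
  records <- read_cohort(require_path(config$paths$cohort, "cohort"))
  markers <- panel_markers(default_panel())
  markers <- intersect(markers, names(records))
  if (length(markers) == 0) stop("cohort has no panel marker columns")
  out <- config$out_dir
  paths <- character(0)
  for (outcome in c("rejection", "any_banff_lesion")) {
    cmp <- compare_models(records, outcome, markers,
                          alpha = config$model$alpha,
                          cv_folds = config$model$cv_folds,
                          seed = config$seed)
    dir <- file.path(out, paste0("models_", outcome))
    write_model_report(cmp, dir)
    uni <- univariate_screen(records, outcome,
                             c("egfr", "dsa", markers), markers = markers)
    utils::write.csv(uni, file.path(dir, "univariate.csv"),
                     row.names = FALSE)
    paths[[outcome]] <- dir
    log_msg(con, outcome, " AUCs: ",
            paste(sprintf("%s=%.3f", cmp$auc_table$model,
                          cmp$auc_table$auc), collapse = ", "))
  }
  paths
}
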