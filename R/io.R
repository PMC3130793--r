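#' Read and write long-format community tables
#'
#' The on-disk dialect is a plain CSV with header columns
#' `metacommunity_id, patch_id, composition, p_sup_level, p_sup, np_ratio,
#' replicate, species, biovolume_um3_per_ml`.
#'
#' @param path File path.
#' @return `read_community_csv` returns the table as a `data.frame` with
#'   `p_sup_level` as an ordered-by-concentration factor.
#' @export
read_community_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("metacommunity_id", "patch_id", "composition", "p_sup_level",
           "p_sup", "np_ratio", "replicate", "species",
           "biovolume_um3_per_ml")
  missing_col <- setdiff(req, names(tab))
  if (length(missing_col) > 0L) {
    stop("community CSV is missing column(s): ",
         paste(missing_col, collapse = ", "))
  }
  lev <- unique(tab[, c("p_sup_level", "p_sup")])
  tab$p_sup_level <- factor(tab$p_sup_level,
                            levels = lev$p_sup_level[order(lev$p_sup)])
  tab
}

#' @rdname read_community_csv
#' @param table Community table to write.
#' @export
write_community_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an experiment configuration from a YAML file
#'
#' Keys mirror the arguments of [experiment_config()] and
#' [default_schedule()] (`p_main`, `p_extra`, `np_ratios`, `compositions`,
#' `extra_compositions`, `replicates`, `total_inoculum`, `patch_volume`,
#' and a `schedule` block with `duration`, `exchange_days`,
#' `exchange_volumes`, `dispersal_days`, `dispersal_volume`); absent keys
#' fall back to the published defaults. An optional `seed` key is carried
#' through.
#'
#' @param path YAML file path.
#' @return List with elements `config` (`bef_config`), `schedule`
#'   (`bef_schedule`) and `seed` (or `NULL`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  cfg_args <- y[intersect(names(y),
                          names(formals(experiment_config)))]
  if (!is.null(cfg_args$p_main)) cfg_args$p_main <- unlist(cfg_args$p_main)
  if (!is.null(cfg_args$p_extra)) cfg_args$p_extra <- unlist(cfg_args$p_extra)
  config <- do.call(experiment_config, cfg_args)
  sch_args <- if (is.null(y$schedule)) list() else
    y$schedule[intersect(names(y$schedule), names(formals(default_schedule)))]
  schedule <- do.call(default_schedule, sch_args)
  list(config = config, schedule = schedule, seed = y$seed)
}

#' @rdname read_config
#' @param config A `bef_config`.
#' @param schedule A `bef_schedule`.
#' @param seed Optional integer seed to record.
#' @export
write_config <- function(config, schedule = default_schedule(), seed = NULL,
                         path) {
  y <- list(
    p_main = as.list(config$p_main), p_extra = as.list(config$p_extra),
    np_ratios = config$np_ratios, compositions = config$compositions,
    extra_compositions = config$extra_compositions,
    replicates = config$replicates, total_inoculum = config$total_inoculum,
    patch_volume = config$patch_volume,
    schedule = list(duration = schedule$duration,
                    exchange_days = schedule$exchange_days,
                    exchange_volumes = schedule$exchange_volumes,
                    dispersal_days = schedule$dispersal_days,
                    dispersal_volume = schedule$dispersal_volume)
  )
  if (!is.null(seed)) y$seed <- seed
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run a simulation and write its outputs
#'
#' Pipeline command: simulates the experiment and writes `design.csv`,
#' `community_true.csv`, `community_observed.csv` and a `manifest.json`
#' (seed, config hash, schedule, file list, package version) to `out_dir`.
#'
#' @param config Path to a YAML config file, a `bef_config`, or `NULL` for
#'   the default design.
#' @param seed Integer seed (required for a reproducible manifest).
#' @param out_dir Output directory (created if needed).
#' @param traits Trait table.
#' @return The `bef_sim` object, invisibly.
#' @export
run_simulation <- function(config = NULL, seed = 1, out_dir = ".",
                           traits = default_traits()) {
  schedule <- default_schedule()
  if (is.character(config)) {
    cf <- read_config(config)
    schedule <- cf$schedule
    if (!is.null(cf$seed)) seed <- cf$seed
    config <- cf$config
  } else if (is.null(config)) {
    config <- experiment_config()
  }
  stopifnot(inherits(config, "bef_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_experiment(config, traits, schedule, seed = seed)
  files <- c(design = "design.csv", true = "community_true.csv",
             observed = "community_observed.csv")
  utils::write.csv(sim$design, file.path(out_dir, files["design"]),
                   row.names = FALSE, quote = FALSE)
  write_community_csv(sim$true, file.path(out_dir, files["true"]))
  write_community_csv(sim$observed, file.path(out_dir, files["observed"]))
  cfg_file <- file.path(out_dir, "config.yaml")
  write_config(config, schedule, seed, cfg_file)
  manifest <- list(
    seed = seed,
    config_hash = .hash_file(cfg_file),
    schedule = unclass(schedule),
    outputs = as.list(unname(files)),
    package_version = as.character(utils::packageVersion("metabef")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(sim)
}

.hash_file <- function(path) {
  # small stable content hash without extra dependencies
  x <- readBin(path, "raw", file.info(path)$size)
  h <- 5381
  for (b in as.integer(x)) h <- (h * 33 + b) %% 2^31
  sprintf("djb2-%d", h)
}

#' Analyse a community table and write result CSVs
#'
#' Pipeline command: validates and analyses a community table and writes
#' `local_metrics.csv`, `metacommunity_metrics.csv`,
#' `diversity_effects_local.csv`, `diversity_effects_metacommunity.csv`,
#' `effect_tests_local.csv`, `effect_tests_metacommunity.csv`, one
#' `anova_*.csv` per fitted ANOVA, and `correlations.csv`.
#'
#' @param input Path to a community CSV, a `data.frame`, or a `bef_sim`.
#' @param out_dir Output directory.
#' @param ... Passed to [bef_analysis()].
#' @return The `bef_analysis` object, invisibly.
#' @export
run_analysis <- function(input, out_dir = ".", ...) {
  tab <- if (is.character(input)) read_community_csv(input)
         else if (inherits(input, "bef_sim")) input$observed
         else input
  fit <- bef_analysis(tab, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) utils::write.csv(df, file.path(out_dir, name),
                                            row.names = FALSE)
  wr(fit$metrics$local, "local_metrics.csv")
  wr(fit$metrics$metacommunity, "metacommunity_metrics.csv")
  wr(fit$effects$local, "diversity_effects_local.csv")
  wr(fit$effects$metacommunity, "diversity_effects_metacommunity.csv")
  wr(fit$effect_tests$local, "effect_tests_local.csv")
  wr(fit$effect_tests$metacommunity, "effect_tests_metacommunity.csv")
  for (nm in names(fit$anova)) {
    if (!is.null(fit$anova[[nm]])) {
      wr(as.data.frame(fit$anova[[nm]]), paste0("anova_", nm, ".csv"))
    }
  }
  cors <- list()
  for (sc in names(fit$correlations)) {
    co <- fit$correlations[[sc]]
    for (kind in names(co)) {
      if (is.null(co[[kind]])) next
      cors[[length(cors) + 1L]] <- data.frame(
        scale = sc, kind = kind, r = co[[kind]]$r, p = co[[kind]]$p,
        n = co[[kind]]$n)
    }
  }
  if (length(cors)) wr(do.call(rbind, cors), "correlations.csv")
  invisible(fit)
}

#' Render summary figures from an analysis directory
#'
#' Pipeline command: reads the CSVs written by [run_analysis()] and renders
#' two PDF panels — `metrics_vs_psup.pdf` (mixture biovolume, RUE and
#' evenness against phosphorus supply at both scales) and
#' `diversity_effects.pdf` (net, complementarity, selection, delta RUE and
#' delta evenness per P level). Reruns overwrite deterministically. If the
#' diversity-effect table is empty (e.g. a monoculture-only experiment) the
#' effect panel is skipped with a warning.
#'
#' @param analysis_dir Directory holding [run_analysis()] outputs.
#' @param out_dir Output directory for figures (defaults to
#'   `analysis_dir`).
#' @return Character vector of files written, invisibly.
#' @export
run_report <- function(analysis_dir, out_dir = analysis_dir) {
  need <- file.path(analysis_dir,
                    c("metacommunity_metrics.csv", "local_metrics.csv"))
  if (!all(file.exists(need))) {
    stop("analysis outputs not found in ", analysis_dir,
         " (run run_analysis() first)")
  }
  meta <- utils::read.csv(need[1])
  loc <- utils::read.csv(need[2])
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()

  f1 <- file.path(out_dir, "metrics_vs_psup.pdf")
  grDevices::pdf(f1, width = 9, height = 6)
  graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  mm <- meta[meta$composition == "MIX", ]
  ml <- loc[loc$composition == "MIX", ]
  if (nrow(mm) > 0) {
    .panel_mean_se(mm$p_sup, log(mm$mean_patch_biovolume), "P supply",
                   "ln biovolume", "Metacommunity biovolume")
    .panel_mean_se(mm$p_sup, log(mm$rue), "P supply", "ln RUE",
                   "Metacommunity RUE")
    .panel_mean_se(mm$p_sup, mm$evenness, "P supply", "evenness",
                   "Metacommunity evenness")
  }
  if (nrow(ml) > 0) {
    .panel_mean_se(ml$p_sup, log(ml$total_biovolume), "P supply",
                   "ln biovolume", "Local biovolume")
    .panel_mean_se(ml$p_sup, log(ml$rue), "P supply", "ln RUE", "Local RUE")
    .panel_mean_se(ml$p_sup, ml$evenness, "P supply", "evenness",
                   "Local evenness")
  }
  grDevices::dev.off()
  written <- c(written, f1)

  eff_file <- file.path(analysis_dir, "diversity_effects_metacommunity.csv")
  eff <- if (file.exists(eff_file)) utils::read.csv(eff_file) else
    data.frame()
  if (nrow(eff) > 0) {
    f2 <- file.path(out_dir, "diversity_effects.pdf")
    grDevices::pdf(f2, width = 9, height = 6)
    graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
    for (s in c("net", "complementarity", "selection", "delta_rue",
                "delta_even")) {
      .panel_mean_se(eff$p_sup, eff[[s]], "P supply", s,
                     paste("Metacommunity", s), hline = 0)
    }
    grDevices::dev.off()
    written <- c(written, f2)
  } else {
    warning("diversity-effect table is empty; effect panels skipped")
  }
  invisible(written)
}
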