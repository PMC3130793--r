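test_that("the analysis object carries all pipeline components", {
  fit <- memo("fit", bef_analysis(fixture_sim()))
  expect_s3_class(fit, "bef_analysis")
  expect_equal(nrow(fit$metrics$local), 180)
  expect_equal(nrow(fit$effects$metacommunity), 9)
  expect_equal(nrow(fit$effect_tests$metacommunity), 15)
  # mixture-only metacommunity ANOVA: 5 P levels, 15 units, error df 10
  a1 <- fit$anova$metacommunity_mixture_biovolume
  expect_equal(a1$df, c(4, 10))
  # local-scale ANOVAs use the conservative divisor
  a2 <- fit$anova$local_mixture_biovolume
  expect_equal(attr(a2, "df_divisor"), 3)
  err_df <- a2$df[a2$term == "Error"]
  expect_equal(a2$df_err_adj[1], err_df / 3)
  # correlations are computed at both scales on 15 and 45 mixture units
  expect_equal(fit$correlations$metacommunity$raw$n, 15)
  expect_equal(fit$correlations$local$raw$n, 45)
  expect_output(print(fit), "Metacommunity BEF analysis")
  expect_output(summary(fit), "t tests")
})

test_that("tables with negative biovolume abort the analysis", {
  tab <- fixture_sim()$observed
  tab$biovolume_um3_per_ml[10] <- -1
  expect_error(suppressMessages(bef_analysis(tab)), "validation")
})

test_that("a monoculture-only table analyses with empty partition output", {
  tab <- fixture_sim()$observed
  tab <- tab[tab$composition != "MIX", ]
  fit <- bef_analysis(tab)
  expect_equal(nrow(fit$effects$metacommunity), 0)
  expect_null(fit$anova$metacommunity_mixture_biovolume)
  expect_s3_class(fit$anova$metacommunity_composition_biovolume, "bef_anova")
})

test_that("community tables round-trip through CSV", {
  tab <- fixture_sim()$observed
  f <- tempfile(fileext = ".csv")
  write_community_csv(tab, f)
  back <- read_community_csv(f)
  expect_equal(back$biovolume_um3_per_ml, tab$biovolume_um3_per_ml)
  expect_equal(as.character(back$p_sup_level), as.character(tab$p_sup_level))
  expect_equal(levels(back$p_sup_level), c("I", "II", "III", "IV", "V"))
})

test_that("config files round-trip through YAML", {
  cfg <- experiment_config(replicates = 2)
  f <- tempfile(fileext = ".yaml")
  write_config(cfg, default_schedule(), seed = 7, path = f)
  back <- read_config(f)
  expect_equal(back$config$p_main, cfg$p_main)
  expect_equal(back$config$replicates, 2L)
  expect_equal(back$seed, 7L)
  expect_equal(back$schedule$dispersal_days, c(13, 20, 27))
  expect_error(read_config(tempfile()), "not found")
})

test_that("simulate and analyze pipeline commands write their outputs", {
  out <- file.path(tempdir(), "mbf-run")
  unlink(out, recursive = TRUE)
  sim <- run_simulation(seed = 3, out_dir = out)
  expect_true(all(file.exists(file.path(out,
    c("design.csv", "community_true.csv", "community_observed.csv",
      "config.yaml", "manifest.json")))))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$seed, 3)
  expect_true(all(unlist(man$outputs) %in% list.files(out)))

  # identical seeds give byte-identical community tables
  out2 <- file.path(tempdir(), "mbf-run2")
  unlink(out2, recursive = TRUE)
  run_simulation(seed = 3, out_dir = out2)
  expect_identical(
    readLines(file.path(out, "community_observed.csv")),
    readLines(file.path(out2, "community_observed.csv")))

  res <- file.path(tempdir(), "mbf-res")
  unlink(res, recursive = TRUE)
  fit <- run_analysis(file.path(out, "community_observed.csv"), out_dir = res)
  expect_true(all(file.exists(file.path(res,
    c("local_metrics.csv", "metacommunity_metrics.csv",
      "diversity_effects_metacommunity.csv", "effect_tests_metacommunity.csv",
      "correlations.csv")))))
  effects <- read.csv(file.path(res, "diversity_effects_metacommunity.csv"))
  expect_equal(nrow(effects), 9)
  expect_true(all(c("net", "complementarity", "selection", "delta_rue",
                    "delta_even") %in% names(effects)))

  figs <- run_report(res)
  expect_true(all(file.exists(figs)))
  expect_true(any(grepl("metrics_vs_psup.pdf", figs)))

  # reports on effect-free analyses skip the effect panels with a warning
  res2 <- file.path(tempdir(), "mbf-res2")
  unlink(res2, recursive = TRUE)
  tab <- sim$observed
  run_analysis(tab[tab$composition != "MIX", ], out_dir = res2)
  expect_warning(run_report(res2), "skipped")
})

test_that("the command-line wrapper runs end to end", {
  cli <- system.file("cli", "metabef.R", package = "metabef")
  skip_if(cli == "", "CLI script not installed")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- file.path(tempdir(), "mbf-cli")
  unlink(out, recursive = TRUE)
  lib <- paste(.libPaths(), collapse = .Platform$path.sep)
  env <- paste0("R_LIBS=", shQuote(lib))
  loadable <- system2(rscript,
                      c("-e", shQuote("library(metabef)")),
                      stdout = FALSE, stderr = FALSE, env = env)
  skip_if(loadable != 0, "package not installed in a library visible to subprocesses")
  status <- system2(rscript, c(cli, "simulate", "--seed", "5", "--out", out),
                    stdout = FALSE, stderr = FALSE, env = env)
  expect_equal(status, 0)
  expect_true(file.exists(file.path(out, "community_observed.csv")))
  # missing config file exits with status 2
  status2 <- system2(rscript, c(cli, "simulate", "--config", "no-such.yaml",
                                "--out", out),
                     stdout = FALSE, stderr = FALSE, env = env)
  expect_equal(status2, 2)
})
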