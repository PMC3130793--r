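test_that("growth is exponential in the saturated limit and zero at mu_max 0", {
  tr <- default_traits()
  # zero growth leaves the state untouched
  tr0 <- tr; tr0$mu_max <- 0
  p <- toy_patch(c(AN = 1000, CL = 1000, CY = 1000, FR = 1000, GY = 1000))
  p0 <- grow_step(p, tr0, dt = 1)
  expect_equal(p0$biovolume, p$biovolume)
  expect_equal(p0$p_conc, p$p_conc)

  # single species, N and P far above half-saturation, small dt:
  # growth factor approaches exp(mu_max dt) before any drawdown capping
  p1 <- toy_patch(c(AN = 1000, CL = 0, CY = 0, FR = 0, GY = 0),
                  p_sup = 500, np_ratio = 16, composition = "AN")
  p1$n_conc <- 8000
  g <- grow_step(p1, tr, dt = 0.1)
  mu <- tr$mu_max[tr$species == "AN"]
  expect_equal(unname(g$biovolume["AN"]), 1000 * exp(mu * 0.1),
               tolerance = 1e-2)

  # a nitrogen fixer keeps growing at N = 0 when P saturates
  p2 <- toy_patch(c(AN = 0, CL = 0, CY = 1000, FR = 0, GY = 0),
                  p_sup = 500, composition = "CY")
  p2$n_conc <- 0
  g2 <- grow_step(p2, tr, dt = 0.1)
  mu_cy <- tr$mu_max[tr$species == "CY"]
  f_p <- 500 / (tr$k_p[tr$species == "CY"] + 500)
  expect_equal(unname(g2$biovolume["CY"]), 1000 * exp(mu_cy * f_p * 0.1),
               tolerance = 1e-2)
})

test_that("resource drawdown conserves mass and never overdraws a pool", {
  tr <- default_traits()
  set.seed(11)
  for (i in 1:20) {
    p <- toy_patch(setNames(runif(5, 0, 5e6),
                            c("AN", "CL", "CY", "FR", "GY")),
                   p_sup = runif(1, 0.05, 5), np_ratio = sample(c(2, 16, 128), 1))
    for (day in 1:5) {
      before <- p
      p <- grow_step(p, tr, dt = 1)
      nonfix <- !tr$n_fixer
      dB <- p$biovolume - before$biovolume
      p_used <- sum(tr$q_p[match(names(dB), tr$species)] * dB) * 1e-3
      n_used <- sum((tr$q_n * !tr$n_fixer)[match(names(dB), tr$species)] * dB) * 1e-3
      expect_gte(p$p_conc, 0)
      expect_gte(p$n_conc, 0)
      # consumed + remaining equals the pre-step pool
      expect_equal(p$p_conc + p_used, before$p_conc, tolerance = 1e-9)
      expect_equal(p$n_conc + n_used, before$n_conc, tolerance = 1e-9)
    }
  }
})

test_that("media exchange dilutes biomass and mixes nutrients toward fresh", {
  p <- toy_patch(c(AN = 100, CL = 50, CY = 0, FR = 0, GY = 0))
  ex <- media_exchange(p, 10)
  expect_equal(unname(ex$biovolume[c("AN", "CL")]), c(80, 40))
  # fresh equal to current concentration is a fixed point
  p2 <- toy_patch(); p2$n_conc <- 3; p2$p_conc <- 0.5
  ex2 <- media_exchange(p2, 10, fresh = c(n = 3, p = 0.5))
  expect_equal(ex2$n_conc, 3)
  expect_equal(ex2$p_conc, 0.5)
  # zero volume is the identity
  ex3 <- media_exchange(p, 0)
  expect_equal(ex3$biovolume, p$biovolume)
  expect_error(media_exchange(p, 50), "volume")
  # default fresh medium restores the design stoichiometry direction
  p3 <- toy_patch(); p3$p_conc <- 0
  ex4 <- media_exchange(p3, 10)
  expect_equal(ex4$p_conc, 10 / 50 * p3$design$p_sup)
})

test_that("dispersal mixes 5% of each patch and conserves totals", {
  mk <- function(an) toy_patch(c(AN = an, CL = 0, CY = 0, FR = 0, GY = 0))
  patches <- list(mk(100), mk(0), mk(0))
  out <- dispersal_event(patches, 2.5)
  got <- vapply(out, function(p) unname(p$biovolume["AN"]), numeric(1))
  expect_equal(got, c(96.667, 1.667, 1.667), tolerance = 1e-4)
  expect_equal(sum(got), 100, tolerance = 1e-12)

  # equal patches are a fixed point
  eq <- dispersal_event(list(mk(7), mk(7), mk(7)), 2.5)
  expect_equal(vapply(eq, function(p) unname(p$biovolume["AN"]), numeric(1)),
               rep(7, 3))

  # conservation for arbitrary states, every species and nutrient
  set.seed(3)
  ps <- lapply(1:3, function(i)
    toy_patch(setNames(runif(5, 0, 1e6), c("AN", "CL", "CY", "FR", "GY"))))
  for (i in 1:3) { ps[[i]]$n_conc <- runif(1, 0, 50); ps[[i]]$p_conc <- runif(1, 0, 5) }
  before_b <- Reduce(`+`, lapply(ps, `[[`, "biovolume"))
  before_n <- sum(vapply(ps, `[[`, numeric(1), "n_conc"))
  after <- dispersal_event(ps, 2.5)
  expect_equal(Reduce(`+`, lapply(after, `[[`, "biovolume")), before_b,
               tolerance = 1e-12)
  expect_equal(sum(vapply(after, `[[`, numeric(1), "n_conc")), before_n,
               tolerance = 1e-12)
  expect_error(dispersal_event(ps[1:2], 2.5), "exactly 3")
})

test_that("event operations commute with species relabelling", {
  tr <- default_traits()
  perm <- c("GY", "AN", "FR", "CY", "CL")
  bv <- c(AN = 2e5, CL = 1e5, CY = 3e5, FR = 5e4, GY = 4e5)
  p <- toy_patch(bv)
  g <- grow_step(p, tr, dt = 1)
  # permute trait rows and the sample: results must match after unpermuting
  trp <- tr[match(perm, tr$species), ]
  pp <- toy_patch(bv[perm])
  gp <- grow_step(pp, trp, dt = 1)
  expect_equal(gp$biovolume[names(g$biovolume)], g$biovolume,
               tolerance = 1e-12)
})

test_that("a zero-growth experiment ends at the dilution product of the inoculum", {
  tr0 <- default_traits(); tr0$mu_max <- 0
  sim <- simulate_experiment(traits = tr0, seed = 5, observe = FALSE)
  tot <- tapply(sim$true$biovolume_um3_per_ml, sim$true$patch_id, sum)
  # exchanges remove 5,5,10,10 of 50 mL: x0 * 0.9^2 * 0.8^2; dispersal mixes
  # equal totals so leaves every flask unchanged
  expect_equal(as.numeric(tot), rep(231000 * 0.9^2 * 0.8^2, length(tot)),
               tolerance = 1e-9)
})

test_that("the same seed reproduces the experiment exactly", {
  a <- simulate_experiment(seed = 99)
  b <- simulate_experiment(seed = 99)
  expect_identical(a$observed, b$observed)
  expect_identical(a$true, b$true)
  c2 <- simulate_experiment(seed = 100)
  expect_false(identical(a$observed$biovolume_um3_per_ml,
                         c2$observed$biovolume_um3_per_ml))
})

test_that("observation draws Poisson counts around the target total", {
  tr <- default_traits()
  sample_bv <- setNames(rep(2e6, 5), tr$species)
  set.seed(1)
  totals <- replicate(200, sum(observe_counts(sample_bv, tr, 1000)$cells_counted))
  # expected total is the target; Poisson SE of the mean over 200 reps
  expect_lt(abs(mean(totals) - 1000), 3 * sqrt(1000 / 200) + 1)
  # absent species never appear
  zero <- sample_bv; zero["GY"] <- 0
  cnt <- observe_counts(zero, tr, 1000)
  expect_equal(cnt$cells_counted[cnt$species == "GY"], 0)
  # all-zero community yields zero counts without error
  none <- observe_counts(setNames(numeric(5), tr$species), tr, 400)
  expect_true(all(none$cells_counted == 0))
  # noise-free tables carry exact proportions
  sim <- fixture_sim_true()
  expect_identical(sim$observed, sim$true)
})

test_that("mass balance holds across a growth-only stretch of the experiment", {
  # run without exchanges/dispersal: initial N,P = final + consumed
  sch <- default_schedule(duration = 12, exchange_days = numeric(0),
                          exchange_volumes = numeric(0),
                          dispersal_days = numeric(0))
  cfg <- main_config()
  sim <- simulate_experiment(cfg, schedule = sch, seed = 1, observe = FALSE)
  tr <- sim$traits
  d <- sim$design
  bv <- matrix(sim$true$biovolume_um3_per_ml, ncol = 5, byrow = TRUE)
  b0 <- matrix(0, nrow(d), 5)
  mixrow <- d$composition == "MIX"
  b0[cbind(which(!mixrow), match(d$composition[!mixrow], tr$species))] <- 231e3
  b0[mixrow, ] <- 231e3 / 5
  dB <- bv - b0
  p_used <- drop(dB %*% tr$q_p) * 1e-3
  n_used <- drop(dB %*% (tr$q_n * !tr$n_fixer)) * 1e-3
  expect_equal(sim$nutrients$p_conc + p_used, d$p_sup, tolerance = 1e-9)
  expect_equal(sim$nutrients$n_conc + n_used, d$p_sup * d$np_ratio,
               tolerance = 1e-9)
})
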