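test_that("additive partition reproduces hand-computed cases", {
  # equal proportional overyielding: all in complementarity
  p1 <- additive_partition(c(a = 60, b = 120), c(a = 100, b = 200))
  expect_equal(p1$net, 30)
  expect_equal(p1$complementarity, 30)
  expect_equal(p1$selection, 0)

  # dominance shift toward the low-yield species: negative selection
  p2 <- additive_partition(c(a = 80, b = 80), c(a = 100, b = 200))
  expect_equal(p2$net, 10)
  expect_equal(p2$complementarity, 30)
  expect_equal(p2$selection, -20)

  # mixture exactly at expectation: everything zero
  M <- c(a = 150, b = 50, c = 300)
  sh <- c(a = 1 / 3, b = 1 / 3, c = 1 / 3)
  p3 <- additive_partition(M * sh, M, sh)
  expect_equal(p3$net, 0)
  expect_equal(p3$complementarity, 0, tolerance = 1e-12)
  expect_equal(p3$selection, 0, tolerance = 1e-12)

  expect_error(additive_partition(c(a = 1), c(a = 0)), "> 0")
  expect_error(additive_partition(c(a = 1, b = 1), c(a = 1, c = 1)),
               "species sets")
})

test_that("partition identity matches the brute-force relative-yield sum", {
  # oracle: net = sum(dRY_i * M_i); complementarity + selection must equal it
  set.seed(33)
  for (i in 1:300) {
    n <- sample(2:5, 1)
    M <- setNames(runif(n, 10, 1e3), letters[1:n])
    mix <- setNames(runif(n, 0, 400), letters[1:n])
    p <- additive_partition(mix, M)
    oracle_net <- sum(p$delta_ry * M)
    expect_equal(p$net, oracle_net, tolerance = 1e-9 * max(1, abs(oracle_net)))
    expect_equal(p$complementarity + p$selection, p$net,
                 tolerance = 1e-9 * max(1, abs(p$net)))
  }
})

test_that("partition components scale linearly with yield units", {
  M <- c(a = 120, b = 310, c = 75)
  mix <- c(a = 60, b = 90, c = 80)
  p <- additive_partition(mix, M)
  for (k in c(0.01, 7, 1e6)) {
    pk <- additive_partition(mix * k, M * k)
    expect_equal(pk$net, k * p$net)
    expect_equal(pk$complementarity, k * p$complementarity)
    expect_equal(pk$selection, k * p$selection)
  }
})

test_that("expected mixture yield and proportions follow monoculture shares", {
  e <- expected_mixture_yield(c(a = 100, b = 200))
  expect_equal(e$y_exp, 150)
  expect_equal(e$proportions, c(a = 1 / 3, b = 2 / 3))
  expect_equal(expected_mixture_yield(c(a = 5, b = 5, c = 5))$proportions,
               c(a = 1, b = 1, c = 1) / 3)
  expect_equal(expected_mixture_yield(c(only = 42))$y_exp, 42)
  expect_error(expected_mixture_yield(numeric(0)), "empty")
})

test_that("delta RUE is the net effect on the phosphorus-use scale", {
  expect_equal(delta_rue(120, c(100, 100)), 20)
  expect_equal(delta_rue(100, c(100, 100)), 0)
  # algebraic identity: delta_RUE * p_sup = net diversity effect
  set.seed(5)
  for (i in 1:20) {
    M <- setNames(runif(5, 1e5, 1e7), c("AN", "CL", "CY", "FR", "GY"))
    mix <- setNames(runif(5, 0, 5e6), names(M))
    p_sup <- runif(1, 0.1, 5)
    part <- additive_partition(mix, M)
    expect_equal(delta_rue(part$y_obs / p_sup, M / p_sup) * p_sup, part$net,
                 tolerance = 1e-9 * abs(part$net))
  }
})

test_that("delta evenness compares observed against expected proportions", {
  M <- c(a = 400, b = 100, c = 50, d = 25, e = 25)
  # observed perfectly even: delta must be positive
  expect_gt(delta_evenness(setNames(rep(100, 5), names(M)), M), 0)
  # observed identical to expected: zero
  expect_equal(delta_evenness(M / 2, M), 0, tolerance = 1e-12)
  # strongly dominated mixture against an even expectation: J'obs - 1 < 0
  even_M <- setNames(rep(100, 5), names(M))
  obs <- setNames(c(0.97, 0.01, 0.01, 0.005, 0.005), names(M))
  expect_equal(delta_evenness(obs, even_M), pielou_evenness(obs) - 1)
  expect_lt(delta_evenness(obs, even_M), 0)
  # undefined on either side propagates NA
  expect_true(is.na(delta_evenness(c(a = 1, b = 0), c(a = 10, b = 10))))
})

test_that("one-sample t follows the exact t distribution", {
  r <- one_sample_t(c(1, 2, 3))
  expect_equal(r$t, 3.4641, tolerance = 1e-4)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * pt(-3.4641, 2), tolerance = 1e-4)
  expect_error(one_sample_t(c(2, 2, 2)), "variance")
  expect_error(one_sample_t(1), "2 replicate")
})

test_that("diversity effects pair mixture and monoculture replicates", {
  sim <- fixture_sim_true()
  eff <- diversity_effects(sim$true)
  # metacommunity scale: 3 main P levels x 3 replicates
  expect_equal(nrow(eff$metacommunity), 9)
  # local scale: 3 P x 3 N:P x 3 replicates
  expect_equal(nrow(eff$local), 27)
  expect_equal(eff$metacommunity$net,
               eff$metacommunity$y_obs - eff$metacommunity$y_exp)
  expect_equal(eff$metacommunity$net,
               eff$metacommunity$complementarity + eff$metacommunity$selection,
               tolerance = 1e-9)

  # one metacommunity replicate recomputed by hand
  r1 <- eff$metacommunity[1, ]
  tab <- sim$true
  cell <- tab[tab$p_sup == r1$p_sup & tab$replicate == r1$replicate, ]
  mono <- cell[cell$composition == cell$species, ]
  M <- tapply(mono$biovolume_um3_per_ml, mono$species, sum) / 3
  mix <- cell[cell$composition == "MIX", ]
  mixv <- tapply(mix$biovolume_um3_per_ml, mix$species, sum) / 3
  expect_equal(r1$y_obs, sum(mixv))
  expect_equal(r1$y_exp, mean(M))
  expect_equal(r1$net, sum(mixv) - mean(M))

  # t tests: one row per P level x statistic, df = replicates - 1
  # (computed on the noisy table: noise-free replicates are identical and
  # have zero variance)
  tt <- effect_tests(diversity_effects(fixture_sim()$observed))$metacommunity
  expect_equal(nrow(tt), 3 * 5)
  expect_true(all(tt$df == 2))
  expect_true(all(tt$n == 3))
})

test_that("monoculture-only tables give empty effect tables, not errors", {
  sim <- fixture_sim_true()
  monos <- sim$true[sim$true$composition != "MIX", ]
  eff <- diversity_effects(monos)
  expect_equal(nrow(eff$metacommunity), 0)
  expect_equal(nrow(eff$local), 0)
})
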