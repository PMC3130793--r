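# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Default full experiment, observed with counting noise.
fixture_sim <- function() memo("sim", simulate_experiment(seed = 42))

# Noise-free run of the default experiment.
fixture_sim_true <- function() {
  memo("sim_true", simulate_experiment(seed = 42, observe = FALSE))
}

# Main design only (no extra P levels), used by replicated suites.
main_config <- function() experiment_config(p_extra = NULL)

# Trait table with all five species made exchangeable (identical growth
# parameters); community dynamics are then invariant to species identity.
uniform_traits <- function(interaction_bonus = 1) {
  tr <- default_traits(interaction_bonus)
  tr$mu_max <- 0.45
  tr$k_n <- 2
  tr$k_p <- 0.2
  tr$q_n <- 2.4e-4
  tr$q_p <- 1.3e-5
  tr$n_fixer <- FALSE
  tr
}

# A tiny hand-rolled patch for unit tests on the event operations.
toy_patch <- function(biovolume = c(AN = 100, CL = 0, CY = 0, FR = 0, GY = 0),
                      p_sup = 0.81, np_ratio = 16, composition = "MIX") {
  dp <- data.frame(metacommunity_id = "m", patch_id = "p",
                   composition = composition, p_sup_level = "III",
                   p_sup = p_sup, np_ratio = np_ratio, replicate = 1,
                   stringsAsFactors = FALSE)
  st <- initial_patch_state(dp, default_traits(), total_inoculum = 1)
  st$biovolume[] <- biovolume[names(st$biovolume)]
  st
}
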