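#' Event schedule for the 31-day experiment
#'
#' Default schedule: medium exchange on days 3 and 6 (5 mL of 50) and days
#' 10 and 17 (10 mL), dispersal among the three patches of each
#' metacommunity on days 13, 20 and 27 (2.5 mL from each patch, pooled and
#' redistributed), sampling at the end of day 31 after all events.
#'
#' @param duration Experiment length, days.
#' @param exchange_days,exchange_volumes Parallel vectors: day of each
#'   medium exchange and the volume replaced (mL).
#' @param dispersal_days Days on which dispersal happens.
#' @param dispersal_volume Volume taken from each patch at dispersal, mL.
#' @return An object of class `bef_schedule`.
#' @export
default_schedule <- function(duration = 31,
                             exchange_days = c(3, 6, 10, 17),
                             exchange_volumes = c(5, 5, 10, 10),
                             dispersal_days = c(13, 20, 27),
                             dispersal_volume = 2.5) {
  if (length(exchange_days) != length(exchange_volumes)) {
    stop("exchange_days and exchange_volumes must have the same length")
  }
  if (any(c(exchange_days, dispersal_days) > duration) ||
      any(c(exchange_days, dispersal_days) < 1)) {
    stop("all event days must lie within the experiment duration")
  }
  if (any(exchange_volumes <= 0) || dispersal_volume <= 0) {
    stop("event volumes must be > 0")
  }
  structure(list(duration = duration, exchange_days = exchange_days,
                 exchange_volumes = exchange_volumes,
                 dispersal_days = dispersal_days,
                 dispersal_volume = dispersal_volume),
            class = "bef_schedule")
}

# Vectorised daily growth over a flask x species biovolume matrix.
# B um3/mL; N, P umol/L; quotas umol per 1e6 um3, so consumption per litre
# of culture is q * dB * 1e-3 (1000 mL/L over 1e6 um3 per quota unit).
.grow_matrix <- function(B, N, P, traits, is_mix, dt) {
  n <- nrow(B)
  fN <- outer(N, traits$k_n, function(nn, k) nn / (k + nn))
  fN[, traits$n_fixer] <- 1
  fP <- outer(P, traits$k_p, function(pp, k) pp / (k + pp))
  bonus <- ifelse(is_mix, 1, 0) %o% (traits$interaction_bonus - 1) + 1
  mu <- sweep(pmin(fN, fP) * bonus, 2, traits$mu_max, `*`)
  dB <- B * (exp(mu * dt) - 1)
  nonfix <- !traits$n_fixer
  dem_P <- drop(dB %*% traits$q_p) * 1e-3
  dem_N <- drop(dB[, nonfix, drop = FALSE] %*% traits$q_n[nonfix]) * 1e-3
  sP <- ifelse(dem_P > P, P / dem_P, 1)
  sN <- ifelse(dem_N > N, N / dem_N, 1)
  # Liebig bottleneck: scale growth by the factor that exhausts the scarce
  # pool; the N factor applies to non-fixers only (fixation bypasses N).
  s <- matrix(sP, n, nrow(traits))
  s[, nonfix] <- pmin(s[, nonfix, drop = FALSE], sN)
  dB <- dB * s
  P <- pmax(P - drop(dB %*% traits$q_p) * 1e-3, 0)
  N <- pmax(N - drop(dB[, nonfix, drop = FALSE] %*% traits$q_n[nonfix]) * 1e-3, 0)
  list(B = B + dB, N = N, P = P)
}

#' One growth step for a single patch
#'
#' Discrete-time Monod growth under Liebig's law of the minimum. Each
#' species grows at `mu = mu_max * min(f_N, f_P)` (times its
#' `interaction_bonus` in mixture flasks), where `f_R = R / (k_R + R)` and
#' `f_N` is identically 1 for nitrogen fixers; biovolume is multiplied by
#' `exp(mu * dt)`. Growth draws down dissolved N and P according to fixed
#' quotas; if demand would overdraw a pool, growth increments are scaled by
#' the common factor that exactly exhausts it (the N factor applying to
#' non-fixers only), so resources never go negative.
#'
#' @param patch A `bef_patch` (see [initial_patch_state()]).
#' @param traits Trait table matching the patch's species.
#' @param dt Time step in days (> 0).
#' @return The updated `bef_patch`.
#' @export
grow_step <- function(patch, traits = default_traits(), dt = 1) {
  if (dt <= 0) stop("dt must be > 0")
  stopifnot(inherits(patch, "bef_patch"))
  traits <- traits[match(names(patch$biovolume), traits$species), ]
  is_mix <- as.character(patch$design$composition) == "MIX"
  st <- .grow_matrix(matrix(patch$biovolume, 1), patch$n_conc, patch$p_conc,
                     traits, is_mix, dt)
  patch$biovolume[] <- st$B[1, ]
  patch$n_conc <- st$N
  patch$p_conc <- st$P
  patch
}

#' Medium exchange for a single patch
#'
#' Removes `volume` mL of well-mixed culture and replaces it with fresh
#' medium: every biovolume concentration is scaled by `(V - v)/V` and each
#' nutrient becomes the volume-weighted mixture of the current and fresh
#' concentrations.
#'
#' @param patch A `bef_patch`.
#' @param volume Volume replaced, mL; must satisfy `0 <= volume < V`.
#' @param fresh Named vector `c(n = , p = )` of fresh-medium concentrations
#'   (µmol L⁻¹); defaults to the patch's design medium
#'   (`p_sup`, `p_sup * np_ratio`).
#' @return The updated `bef_patch`.
#' @export
media_exchange <- function(patch, volume, fresh = NULL) {
  stopifnot(inherits(patch, "bef_patch"))
  V <- patch$volume
  if (volume < 0 || volume >= V) stop("volume must satisfy 0 <= volume < patch volume")
  if (is.null(fresh)) {
    fresh <- c(n = patch$design$p_sup * patch$design$np_ratio,
               p = patch$design$p_sup)
  }
  keep <- (V - volume) / V
  patch$biovolume <- patch$biovolume * keep
  patch$n_conc <- keep * patch$n_conc + (volume / V) * fresh[["n"]]
  patch$p_conc <- keep * patch$p_conc + (volume / V) * fresh[["p"]]
  patch
}

#' Dispersal among the three patches of a metacommunity
#'
#' Emulates removing `volume` mL from each of the three patches, pooling
#' and mixing the removed volumes, and redistributing one share back to
#' each patch: every species (and each nutrient) concentration becomes
#' `((V - v) * x_i + v * mean(x)) / V`. Per-species and nutrient totals
#' across the metacommunity are conserved exactly.
#'
#' @param patches List of exactly 3 `bef_patch` objects of equal volume.
#' @param volume Volume moved from each patch, mL (`0 < v < V`).
#' @return The list of updated patches.
#' @export
dispersal_event <- function(patches, volume = 2.5) {
  if (!is.list(patches) || length(patches) != 3L ||
      !all(vapply(patches, inherits, logical(1), "bef_patch"))) {
    stop("dispersal requires a metacommunity of exactly 3 patches")
  }
  V <- unique(vapply(patches, `[[`, numeric(1), "volume"))
  if (length(V) != 1L) stop("patches must share the same volume")
  if (volume <= 0 || volume >= V) stop("volume must satisfy 0 < volume < patch volume")
  f <- volume / V
  bv <- do.call(rbind, lapply(patches, `[[`, "biovolume"))
  nn <- vapply(patches, `[[`, numeric(1), "n_conc")
  pp <- vapply(patches, `[[`, numeric(1), "p_conc")
  bv_new <- (1 - f) * bv + f * matrix(colMeans(bv), 3, ncol(bv), byrow = TRUE)
  nn_new <- (1 - f) * nn + f * mean(nn)
  pp_new <- (1 - f) * pp + f * mean(pp)
  for (i in 1:3) {
    patches[[i]]$biovolume[] <- bv_new[i, ]
    patches[[i]]$n_conc <- nn_new[i]
    patches[[i]]$p_conc <- pp_new[i]
  }
  patches
}

#' Simulate Utermoehl-chamber counting of a community sample
#'
#' Chooses an effective examined volume so that the expected total number
#' of cells equals the counting target (400 for monocultures, 1000 for
#' mixtures in the default protocol), then draws per-species counts from
#' independent Poisson laws with means proportional to the true cell
#' concentrations.
#'
#' @param sample Named numeric vector of true biovolumes, µm³ mL⁻¹.
#' @param traits Trait table supplying `mean_cell_biovolume` per species.
#' @param target_count Target expected total cells (>= 1).
#' @return A `data.frame` of count records: `species`, `cells_counted`,
#'   `volume_examined_ml`, `dilution_factor`. An all-zero community yields
#'   zero counts.
#' @export
observe_counts <- function(sample, traits = default_traits(),
                           target_count = 1000) {
  if (target_count < 1) stop("target_count must be >= 1")
  cv <- traits$mean_cell_biovolume[match(names(sample), traits$species)]
  cells_per_ml <- sample / cv
  total <- sum(cells_per_ml)
  v_eff <- if (total > 0) target_count / total else 1
  counts <- stats::rpois(length(sample), cells_per_ml * v_eff)
  data.frame(species = names(sample), cells_counted = counts,
             volume_examined_ml = v_eff, dilution_factor = 1,
             stringsAsFactors = FALSE)
}

#' Simulate the full metacommunity experiment
#'
#' Runs the daily Monod–Liebig growth model over the whole enumerated
#' design for the scheduled duration, applying medium exchange and
#' dispersal on their scheduled days, and samples every flask at the end of
#' the final day (after all events). Returns both the noise-free ("true")
#' community table and a table observed through simulated Utermoehl
#' counting (Poisson noise; counting targets of 400 cells for monocultures
#' and 1000 for mixtures).
#'
#' @param config An [experiment_config()].
#' @param traits Trait table (see [default_traits()]).
#' @param schedule A [default_schedule()].
#' @param seed Integer seed making the run reproducible; `NULL` leaves the
#'   RNG state untouched.
#' @param observe Logical; if `FALSE` the observed table is the true table
#'   (noise-free mode).
#' @param target_count_mono,target_count_mix Counting targets.
#' @return An object of class `bef_sim`: list with `observed` and `true`
#'   long-format community tables (columns `metacommunity_id`, `patch_id`,
#'   `composition`, `p_sup_level`, `p_sup`, `np_ratio`, `replicate`,
#'   `species`, `biovolume_um3_per_ml`), the final `nutrients` per flask,
#'   and the `design`, `config`, `schedule`, `traits` and `seed` used.
#' @examples
#' sim <- simulate_experiment(seed = 1)
#' head(as.data.frame(sim))
#' @export
simulate_experiment <- function(config = experiment_config(),
                                traits = default_traits(),
                                schedule = default_schedule(),
                                seed = NULL, observe = TRUE,
                                target_count_mono = 400,
                                target_count_mix = 1000) {
  stopifnot(inherits(config, "bef_config"), inherits(schedule, "bef_schedule"))
  validate_traits(traits)
  if (any(c(schedule$exchange_volumes, schedule$dispersal_volume) >=
          config$patch_volume)) {
    stop("scheduled event volumes must be smaller than the patch volume")
  }
  if (!is.null(seed)) set.seed(seed)
  design <- enumerate_design(config)
  n <- nrow(design)
  sp <- traits$species
  S <- length(sp)
  is_mix <- design$composition == "MIX"

  B <- matrix(0, n, S, dimnames = list(NULL, sp))
  B[cbind(which(!is_mix), match(design$composition[!is_mix], sp))] <-
    config$total_inoculum
  B[is_mix, ] <- config$total_inoculum / S
  P <- design$p_sup
  N <- design$p_sup * design$np_ratio
  fresh_P <- design$p_sup
  fresh_N <- design$p_sup * design$np_ratio
  V <- config$patch_volume

  mc <- match(design$metacommunity_id, unique(design$metacommunity_id))
  n_mc <- max(mc)
  mc_size <- tabulate(mc)
  if (any(mc_size != length(config$np_ratios))) {
    stop("every metacommunity must have one patch per N:P ratio")
  }

  for (day in seq_len(schedule$duration)) {
    st <- .grow_matrix(B, N, P, traits, is_mix, dt = 1)
    B <- st$B; N <- st$N; P <- st$P
    ei <- match(day, schedule$exchange_days)
    if (!is.na(ei)) {
      v <- schedule$exchange_volumes[ei]
      keep <- (V - v) / V
      B <- B * keep
      N <- keep * N + (v / V) * fresh_N
      P <- keep * P + (v / V) * fresh_P
    }
    if (day %in% schedule$dispersal_days) {
      f <- schedule$dispersal_volume / V
      Bbar <- rowsum(B, mc) / mc_size
      B <- (1 - f) * B + f * Bbar[mc, , drop = FALSE]
      N <- (1 - f) * N + f * (rowsum(N, mc) / mc_size)[mc]
      P <- (1 - f) * P + f * (rowsum(P, mc) / mc_size)[mc]
    }
  }

  true_tab <- .long_table(design, B, sp)
  if (observe) {
    cv <- traits$mean_cell_biovolume
    cells <- sweep(B, 2, cv, `/`)
    total_cells <- rowSums(cells)
    target <- ifelse(is_mix, target_count_mix, target_count_mono)
    v_eff <- ifelse(total_cells > 0, target / total_cells, 1)
    lambda <- cells * v_eff
    counts <- matrix(stats::rpois(length(lambda), lambda), n, S)
    B_obs <- sweep(counts / v_eff, 2, cv, `*`)
    colnames(B_obs) <- sp
    obs_tab <- .long_table(design, B_obs, sp)
  } else {
    obs_tab <- true_tab
  }

  structure(
    list(observed = obs_tab, true = true_tab,
         nutrients = data.frame(patch_id = design$patch_id,
                                n_conc = N, p_conc = P,
                                stringsAsFactors = FALSE),
         design = design, config = config, schedule = schedule,
         traits = traits, seed = seed),
    class = "bef_sim"
  )
}

.long_table <- function(design, B, sp) {
  out <- design[rep(seq_len(nrow(design)), each = length(sp)), ]
  out$species <- rep(sp, nrow(design))
  out$biovolume_um3_per_ml <- as.vector(t(B))
  rownames(out) <- NULL
  out
}

#' @export
print.bef_sim <- function(x, ...) {
  cat("Simulated metacommunity experiment\n")
  cat("  flasks:", nrow(x$design), " metacommunities:",
      length(unique(x$design$metacommunity_id)), "\n")
  cat("  duration:", x$schedule$duration, "days;  seed:",
      if (is.null(x$seed)) "none" else x$seed, "\n")
  tot <- tapply(x$observed$biovolume_um3_per_ml, x$observed$patch_id, sum)
  cat("  observed flask biovolume (um3/mL): median",
      format(signif(stats::median(tot), 3)), "\n")
  invisible(x)
}

#' @export
as.data.frame.bef_sim <- function(x, ...) x$observed
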