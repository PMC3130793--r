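#' Additive partition of the net diversity effect
#'
#' Loreau–Hector partition of mixture overyielding. With monoculture yields
#' \eqn{M_i}, observed per-species mixture yields and initial (expected)
#' relative yields \eqn{RY_{E,i}} (the substitutive shares, 1/5 each by
#' default): \eqn{RY_{O,i} = Y_{O,i}/M_i}, \eqn{\Delta RY_i = RY_{O,i} -
#' RY_{E,i}}, and
#' \deqn{\Delta Y = Y_O - Y_E = N\,\overline{\Delta RY}\,\overline{M} +
#'   N\,\mathrm{cov}(\Delta RY, M),}
#' the first term being the complementarity effect and the second the
#' selection effect. The covariance divides by \eqn{N} (population form) so
#' the identity `net = complementarity + selection` is exact.
#'
#' @param mix_per_species Named vector of per-species yields in mixture
#'   (µm³ mL⁻¹).
#' @param mono_yields Named vector of monoculture yields, same species,
#'   all > 0.
#' @param init_shares Initial proportions sown; default equal shares.
#' @return An object of class `bef_partition`: list with `net`,
#'   `complementarity`, `selection`, `y_obs`, `y_exp`, `n_species`,
#'   `delta_ry`.
#' @examples
#' additive_partition(c(a = 80, b = 80), c(a = 100, b = 200))
#' @export
additive_partition <- function(mix_per_species, mono_yields,
                               init_shares = NULL) {
  sp <- names(mix_per_species)
  if (is.null(sp) || is.null(names(mono_yields))) {
    stop("samples must be named by species")
  }
  if (!setequal(sp, names(mono_yields))) {
    stop("mixture and monoculture species sets differ")
  }
  M <- mono_yields[sp]
  if (any(M <= 0)) stop("all monoculture yields must be > 0 (relative yield undefined)")
  N <- length(sp)
  if (is.null(init_shares)) {
    init_shares <- setNames(rep(1 / N, N), sp)
  } else {
    init_shares <- init_shares[sp]
    if (abs(sum(init_shares) - 1) > 1e-8) stop("init_shares must sum to 1")
  }
  ry_o <- mix_per_species / M
  d_ry <- ry_o - init_shares
  y_obs <- sum(mix_per_species)
  y_exp <- sum(init_shares * M)
  compl <- N * mean(d_ry) * mean(M)
  sel <- N * mean((d_ry - mean(d_ry)) * (M - mean(M)))
  structure(
    list(net = y_obs - y_exp, complementarity = compl, selection = sel,
         y_obs = y_obs, y_exp = y_exp, n_species = N, delta_ry = d_ry),
    class = "bef_partition"
  )
}

#' @export
print.bef_partition <- function(x, ...) {
  cat("Net diversity effect partition (", x$n_species, "species )\n")
  cat(sprintf("  observed yield:  %g\n  expected yield:  %g\n", x$y_obs, x$y_exp))
  cat(sprintf("  net:             %g\n  complementarity: %g\n  selection:       %g\n",
              x$net, x$complementarity, x$selection))
  invisible(x)
}

#' Expected mixture yield and proportions from monocultures
#'
#' The null expectation for a substitutive mixture: total yield
#' \eqn{Y_E = \sum s_i M_i} and expected species proportions
#' \eqn{p_{E,i} = M_i / \sum_j M_j} (for equal shares), i.e. the share each
#' species holds of the summed monoculture yields.
#'
#' @inheritParams additive_partition
#' @return List with `y_exp` and `proportions`.
#' @export
expected_mixture_yield <- function(mono_yields, init_shares = NULL) {
  if (length(mono_yields) == 0L) stop("empty species set")
  N <- length(mono_yields)
  if (is.null(init_shares)) init_shares <- rep(1 / N, N)
  w <- init_shares * mono_yields
  list(y_exp = sum(w), proportions = w / sum(w))
}

#' Net diversity effect for resource use efficiency
#'
#' `delta_RUE = observed mixture RUE - sum(share_i * monoculture RUE_i)`.
#' Because RUE divides yield by the shared phosphorus supply, this equals
#' the net diversity effect divided by `p_sup` when both are computed at
#' the same scale. RUE itself is not partitioned further: species-specific
#' contributions to mixture RUE cannot be separated.
#'
#' @param observed_rue Mixture RUE.
#' @param mono_rues Named vector of monoculture RUEs at the same P supply
#'   and scale.
#' @param init_shares Initial shares; default equal.
#' @return Numeric delta in RUE units.
#' @export
delta_rue <- function(observed_rue, mono_rues, init_shares = NULL) {
  if (is.null(init_shares)) init_shares <- rep(1 / length(mono_rues), length(mono_rues))
  observed_rue - sum(init_shares * mono_rues)
}

#' Net diversity effect for evenness
#'
#' Observed mixture evenness minus the evenness of the proportions expected
#' from monoculture growth ([expected_mixture_yield()]), i.e. how species
#' interactions in mixture changed dominance relative to interaction-free
#' expectation.
#'
#' @param observed_mix_sample Named vector of per-species mixture yields.
#' @param mono_yields Named vector of monoculture yields.
#' @param init_shares Initial shares; default equal.
#' @return Numeric delta, or `NA` when either evenness is undefined.
#' @export
delta_evenness <- function(observed_mix_sample, mono_yields,
                           init_shares = NULL) {
  exp_p <- expected_mixture_yield(mono_yields[names(observed_mix_sample)],
                                  init_shares)$proportions
  pielou_evenness(observed_mix_sample) - pielou_evenness(exp_p)
}

#' One-sample t test against zero
#'
#' Tests whether replicate diversity-effect estimates differ from zero:
#' `t = mean / (sd / sqrt(n))` on `n - 1` degrees of freedom, two-sided.
#'
#' @param values Numeric vector of replicate estimates (n >= 2, nonzero
#'   variance).
#' @return List with `t`, `df`, `p`, `mean`, `n`.
#' @export
one_sample_t <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("at least 2 replicate values are required")
  if (stats::sd(values) == 0) stop("zero sample variance: t undefined")
  ht <- stats::t.test(values, mu = 0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean = mean(values), n = length(values))
}

#' Observed-vs-expected diversity effects across the design
#'
#' For every replicate cell of the design that has the mixture and all five
#' monocultures, computes the additive partition of the net diversity
#' effect plus `delta_RUE` and `delta_evenness`, at both scales:
#' \describe{
#'   \item{local}{mixture flask against the monoculture flasks of the same
#'     `p_sup` × `np_ratio` × replicate cell;}
#'   \item{metacommunity}{per-species biovolumes averaged over the three
#'     patches of each metacommunity, mixture against the monoculture
#'     metacommunities of the same `p_sup` × replicate cell (mirroring the
#'     metacommunity RUE definition).}
#' }
#' Mixture replicate r is always paired with monoculture replicates r, so
#' each P level yields as many replicate deltas as there are replicates.
#'
#' @param table Long-format community table.
#' @return List of two data frames (`local`, `metacommunity`) with one row
#'   per replicate comparison: grouping keys, `y_obs`, `y_exp`, `net`,
#'   `complementarity`, `selection`, `delta_rue`, `delta_even`.
#' @export
diversity_effects <- function(table) {
  species <- sort(unique(table$species))
  list(local = .effects_one_scale(table, species, local = TRUE),
       metacommunity = .effects_one_scale(table, species, local = FALSE))
}

.effects_one_scale <- function(table, species, local) {
  gcols <- if (local) c("p_sup_level", "p_sup", "np_ratio", "replicate")
           else c("p_sup_level", "p_sup", "replicate")
  if (local) {
    agg <- stats::aggregate(
      table["biovolume_um3_per_ml"],
      table[c(gcols, "composition", "species")], sum)
  } else {
    # per-species mean over the three patches of each metacommunity
    agg <- stats::aggregate(
      table["biovolume_um3_per_ml"],
      table[c(gcols, "composition", "species")], function(x) sum(x) / 3)
  }
  cells <- unique(agg[gcols])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- rep(TRUE, nrow(agg))
    for (g in gcols) sel <- sel & agg[[g]] == cells[[g]][i]
    sub <- agg[sel, ]
    mix <- sub[sub$composition == "MIX", ]
    if (nrow(mix) == 0L) next
    mono <- sub[sub$composition == sub$species & sub$composition != "MIX", ]
    if (!setequal(mono$composition, species)) next
    mix_bv <- setNames(mix$biovolume_um3_per_ml, mix$species)[species]
    M <- setNames(mono$biovolume_um3_per_ml, mono$species)[species]
    if (any(M <= 0)) next
    part <- additive_partition(mix_bv, M)
    p_sup <- cells$p_sup[i]
    row <- cells[i, , drop = FALSE]
    row$y_obs <- part$y_obs
    row$y_exp <- part$y_exp
    row$net <- part$net
    row$complementarity <- part$complementarity
    row$selection <- part$selection
    row$delta_rue <- delta_rue(part$y_obs / p_sup, M / p_sup)
    row$delta_even <- delta_evenness(mix_bv, M)
    out[[length(out) + 1L]] <- row
  }
  if (length(out) == 0L) {
    res <- cells[0, , drop = FALSE]
    for (v in c("y_obs", "y_exp", "net", "complementarity", "selection",
                "delta_rue", "delta_even")) res[[v]] <- numeric(0)
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[do.call(order, res[gcols]), ]
}

#' One-sample t tests of diversity effects
#'
#' Summarises replicate diversity-effect estimates into per-group t tests
#' against zero (groups: `p_sup` at the metacommunity scale, `p_sup` ×
#' `np_ratio` at the local scale), for each of the five statistics (net,
#' complementarity, selection, delta_RUE, delta_evenness).
#'
#' @param effects Output of [diversity_effects()] (either scale's frame or
#'   the whole list).
#' @return A `data.frame` with grouping keys, `statistic`, `mean`, `t`,
#'   `df`, `p`, `n` (one row per group × statistic); or a list of two such
#'   frames if `effects` is the two-scale list.
#' @export
effect_tests <- function(effects) {
  if (is.list(effects) && !is.data.frame(effects)) {
    return(lapply(effects, effect_tests))
  }
  stats_cols <- c("net", "complementarity", "selection", "delta_rue",
                  "delta_even")
  gcols <- intersect(c("p_sup_level", "p_sup", "np_ratio"), names(effects))
  groups <- unique(effects[gcols])
  if (nrow(groups) == 0L) {
    out <- groups
    out$statistic <- character(0)
    for (v in c("mean", "t", "df", "p")) out[[v]] <- numeric(0)
    out$n <- integer(0)
    return(out)
  }
  out <- list()
  for (i in seq_len(nrow(groups))) {
    sel <- rep(TRUE, nrow(effects))
    for (g in gcols) sel <- sel & effects[[g]] == groups[[g]][i]
    for (s in stats_cols) {
      v <- effects[[s]][sel]
      v <- v[!is.na(v)]
      row <- groups[i, , drop = FALSE]
      row$statistic <- s
      if (length(v) >= 2L && stats::sd(v) > 0) {
        tt <- one_sample_t(v)
        row$mean <- tt$mean; row$t <- tt$t; row$df <- tt$df; row$p <- tt$p
        row$n <- tt$n
      } else {
        row$mean <- if (length(v)) mean(v) else NA_real_
        row$t <- NA_real_; row$df <- NA_real_; row$p <- NA_real_
        row$n <- length(v)
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
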