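#' Analyse a metacommunity community table
#'
#' The package's main entry point: takes a long-format flask × species
#' biovolume table (simulated or read from CSV), validates it, and runs the
#' full analysis at both spatial scales —
#' \enumerate{
#'   \item local and metacommunity summary metrics (total biovolume,
#'     realized evenness, resource use efficiency);
#'   \item observed-vs-expected diversity effects for every replicate
#'     (additive partition into complementarity and selection, delta RUE,
#'     delta evenness) with one-sample t tests per treatment group;
#'   \item balanced factorial ANOVAs of ln biovolume, ln RUE and evenness:
#'     phosphorus supply (× N:P at the local scale) for the mixture, and
#'     phosphorus supply × species composition (× N:P at the local scale)
#'     across all compositions, local-scale tests using the conservative
#'     error-df/3 criterion;
#'   \item raw and treatment-residual Pearson correlations between RUE and
#'     evenness at both scales.
#' }
#'
#' @param table Long-format community table with columns
#'   `metacommunity_id`, `patch_id`, `composition`, `p_sup_level`, `p_sup`,
#'   `np_ratio`, `replicate`, `species`, `biovolume_um3_per_ml`; or a
#'   `bef_sim` object (its observed table is used).
#' @param local_df_divisor Error-df divisor for local-scale ANOVAs
#'   (default 3; metacommunity-scale ANOVAs always use the actual df since
#'   metacommunities are independent units).
#' @param alpha Significance level.
#' @return An object of class `bef_analysis` with components `table`,
#'   `validation`, `metrics`, `effects`, `effect_tests`, `anova` (a list of
#'   `bef_anova` tables) and `correlations`.
#' @examples
#' sim <- simulate_experiment(seed = 1)
#' fit <- bef_analysis(sim)
#' summary(fit)
#' @export
bef_analysis <- function(table, local_df_divisor = 3, alpha = 0.05) {
  if (inherits(table, "bef_sim")) table <- table$observed
  val <- validate_table(table)
  if (any(val$severity == "error")) {
    print(val)
    stop("community table failed validation; see report above")
  }
  met <- community_metrics(table)
  eff <- diversity_effects(table)
  tst <- effect_tests(eff)

  loc <- met$local
  meta <- met$metacommunity
  mix_loc <- loc[loc$composition == "MIX", ]
  mix_meta <- meta[meta$composition == "MIX", ]
  comp_levels <- .full_comp_levels(meta)
  comp_meta <- meta[meta$p_sup_level %in% comp_levels, ]
  comp_loc <- loc[loc$p_sup_level %in% comp_levels, ]

  try_anova <- function(formula, data, div = 1) {
    tryCatch(balanced_anova(formula, data, df_divisor = div, alpha = alpha),
             error = function(e) NULL)
  }
  anovas <- list(
    metacommunity_mixture_biovolume = if (nrow(mix_meta) > 0)
      try_anova(ln_transform(mean_patch_biovolume) ~ p_sup_level, mix_meta),
    metacommunity_mixture_rue = if (nrow(mix_meta) > 0)
      try_anova(ln_transform(rue) ~ p_sup_level, mix_meta),
    metacommunity_mixture_evenness = if (nrow(mix_meta) > 0)
      try_anova(evenness ~ p_sup_level, mix_meta),
    local_mixture_biovolume = if (nrow(mix_loc) > 0)
      try_anova(ln_transform(total_biovolume) ~ p_sup_level * np_ratio,
                mix_loc, local_df_divisor),
    local_mixture_rue = if (nrow(mix_loc) > 0)
      try_anova(ln_transform(rue) ~ p_sup_level * np_ratio, mix_loc,
                local_df_divisor),
    local_mixture_evenness = if (nrow(mix_loc) > 0)
      try_anova(evenness ~ p_sup_level * np_ratio, mix_loc, local_df_divisor),
    metacommunity_composition_biovolume = if (nrow(comp_meta) > 0)
      try_anova(ln_transform(mean_patch_biovolume) ~ p_sup_level * composition,
                comp_meta),
    metacommunity_composition_rue = if (nrow(comp_meta) > 0)
      try_anova(ln_transform(rue) ~ p_sup_level * composition, comp_meta),
    local_composition_biovolume = if (nrow(comp_loc) > 0)
      try_anova(ln_transform(total_biovolume) ~
                  p_sup_level * np_ratio * composition, comp_loc,
                local_df_divisor),
    local_composition_rue = if (nrow(comp_loc) > 0)
      try_anova(ln_transform(rue) ~ p_sup_level * np_ratio * composition,
                comp_loc, local_df_divisor)
  )

  correlations <- list(
    metacommunity = .rue_evenness_cor(mix_meta, c("p_sup_level")),
    local = .rue_evenness_cor(mix_loc, c("p_sup_level", "np_ratio"))
  )

  structure(
    list(table = table, validation = val, metrics = met, effects = eff,
         effect_tests = tst, anova = anovas, correlations = correlations,
         local_df_divisor = local_df_divisor, alpha = alpha),
    class = "bef_analysis"
  )
}

# P levels at which every composition in the table is present
.full_comp_levels <- function(meta) {
  comps <- unique(meta$composition)
  tab <- table(meta$p_sup_level, meta$composition)
  rownames(tab)[apply(tab > 0, 1, all)]
}

.rue_evenness_cor <- function(d, cell_cols) {
  d <- d[!is.na(d$evenness) & d$rue > 0, ]
  if (nrow(d) < 3L) return(NULL)
  ln_rue <- log(d$rue)
  raw <- tryCatch(pearson_r(d$evenness, ln_rue), error = function(e) NULL)
  resid <- tryCatch({
    fac <- d[cell_cols]
    pearson_r(treatment_residuals(d$evenness, fac),
              treatment_residuals(ln_rue, fac))
  }, error = function(e) NULL)
  list(raw = raw, residual = resid)
}

#' @export
print.bef_analysis <- function(x, ...) {
  loc <- x$metrics$local
  cat("Metacommunity BEF analysis\n")
  cat("  flasks:", nrow(loc), " metacommunities:",
      nrow(x$metrics$metacommunity), "\n")
  cat("  compositions:", paste(sort(unique(loc$composition)), collapse = ", "),
      "\n")
  cat("  diversity-effect replicates: local", nrow(x$effects$local),
      ", metacommunity", nrow(x$effects$metacommunity), "\n")
  cat("  use summary() for effect tests, $anova for ANOVA tables\n")
  invisible(x)
}

#' @export
summary.bef_analysis <- function(object, ...) {
  cat("== Diversity-effect t tests (metacommunity scale) ==\n")
  tt <- object$effect_tests$metacommunity
  if (!is.null(tt) && nrow(tt) > 0) {
    tt$mean <- signif(tt$mean, 3); tt$t <- signif(tt$t, 3)
    tt$p <- signif(tt$p, 2)
    print.data.frame(tt, row.names = FALSE)
  } else cat("  (no mixture/monoculture comparisons available)\n")
  cat("\n== ANOVA: P_sup x composition, metacommunity biovolume ==\n")
  a <- object$anova$metacommunity_composition_biovolume
  if (!is.null(a)) print(a) else cat("  (not estimable)\n")
  cat("\n== RUE-evenness correlations ==\n")
  for (sc in names(object$correlations)) {
    co <- object$correlations[[sc]]
    if (is.null(co) || is.null(co$raw)) next
    cat(sprintf("  %s: raw r = %.3f (p = %.3f, n = %d)", sc, co$raw$r,
                co$raw$p, co$raw$n))
    if (!is.null(co$residual)) {
      cat(sprintf("; residual r = %.3f (p = %.3f)", co$residual$r,
                  co$residual$p))
    }
    cat("\n")
  }
  invisible(object)
}

#' Plot method for a BEF analysis
#'
#' Draws the headline summaries: mixture biovolume, RUE and evenness
#' against phosphorus supply at the metacommunity scale (mean ± 1 SE), and
#' the mean net, complementarity and selection effects per P level.
#'
#' @param x A `bef_analysis` object.
#' @param ... Passed to [graphics::par()].
#' @export
plot.bef_analysis <- function(x, ...) {
  meta <- x$metrics$metacommunity
  mix <- meta[meta$composition == "MIX", ]
  op <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1), ...)
  on.exit(graphics::par(op))
  .panel_mean_se(mix$p_sup, log(mix$mean_patch_biovolume),
                 "P supply (umol/L)", "ln biovolume", "Biovolume")
  .panel_mean_se(mix$p_sup, log(mix$rue), "P supply (umol/L)", "ln RUE", "RUE")
  .panel_mean_se(mix$p_sup, mix$evenness, "P supply (umol/L)", "evenness",
                 "Evenness")
  eff <- x$effects$metacommunity
  if (!is.null(eff) && nrow(eff) > 0) {
    for (s in c("net", "complementarity", "selection")) {
      .panel_mean_se(eff$p_sup, eff[[s]], "P supply (umol/L)",
                     paste(s, "effect (um3/mL)"), s, hline = 0)
    }
  }
  invisible(x)
}

.panel_mean_se <- function(xv, yv, xlab, ylab, main, hline = NULL) {
  ok <- !is.na(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) == 0) return(invisible())
  m <- tapply(yv, xv, mean)
  se <- tapply(yv, xv, function(z) stats::sd(z) / sqrt(length(z)))
  px <- as.numeric(names(m))
  graphics::plot(px, m, log = "x", pch = 19, xlab = xlab, ylab = ylab,
                 main = main,
                 ylim = range(c(m - se, m + se, hline), finite = TRUE))
  graphics::arrows(px, m - se, px, m + se, angle = 90, code = 3,
                   length = 0.03)
  if (!is.null(hline)) graphics::abline(h = hline, lty = 2)
}
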