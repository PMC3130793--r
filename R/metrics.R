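#' Pielou's evenness of a community sample
#'
#' \eqn{J' = H' / \ln S} where \eqn{H' = -\sum p_i \ln p_i} is the Shannon
#' entropy of the biovolume proportions and \eqn{S} is the number of
#' species actually present (positive biovolume). Realized evenness is
#' undefined for fewer than two species present or a zero total, in which
#' case `NA` is returned (never zero); monoculture flasks therefore carry
#' no evenness and drop out of downstream means.
#'
#' @param sample Numeric vector of biovolumes (or proportions); names are
#'   species labels.
#' @return Evenness in `[0, 1]`, or `NA_real_` when undefined.
#' @examples
#' pielou_evenness(c(a = 1, b = 1, c = 1)) # 1
#' pielou_evenness(c(a = 0.9, b = 0.1))    # 0.469
#' @export
pielou_evenness <- function(sample) {
  if (any(sample < 0, na.rm = TRUE)) stop("biovolumes must be >= 0")
  x <- sample[!is.na(sample) & sample > 0]
  if (length(x) < 2L) return(NA_real_)
  p <- x / sum(x)
  -sum(p * log(p)) / log(length(x))
}

#' Sum patch communities into a metacommunity sample
#'
#' Per-species biovolume totals across the three local patches of a
#' metacommunity; species missing from a patch count as zero.
#'
#' @param patches List of exactly 3 named biovolume vectors.
#' @return Named vector over the union of species.
#' @export
metacommunity_totals <- function(patches) {
  if (!is.list(patches) || length(patches) != 3L) {
    stop("a metacommunity consists of exactly 3 patches")
  }
  species <- unique(unlist(lapply(patches, names)))
  if (is.null(species)) stop("patch samples must be named by species")
  out <- setNames(numeric(length(species)), species)
  for (p in patches) out[names(p)] <- out[names(p)] + p
  out
}

#' Local resource use efficiency
#'
#' Final algal biovolume per unit of supplied phosphorus,
#' `RUE = biovolume / p_sup`.
#'
#' @param total_biovolume Flask total biovolume, µm³ mL⁻¹.
#' @param p_sup Phosphorus supply, µmol L⁻¹ (> 0).
#' @return RUE in µm³ mL⁻¹ per µmol L⁻¹.
#' @export
rue_local <- function(total_biovolume, p_sup) {
  if (any(p_sup <= 0)) stop("p_sup must be > 0")
  total_biovolume / p_sup
}

#' Metacommunity resource use efficiency
#'
#' Mean total biovolume across the three local patches divided by the
#' (shared) phosphorus supply.
#'
#' @param patch_totals Numeric vector of 3 patch total biovolumes.
#' @param p_sup Phosphorus supply, µmol L⁻¹ (> 0).
#' @return RUE in µm³ mL⁻¹ per µmol L⁻¹.
#' @export
rue_metacommunity <- function(patch_totals, p_sup) {
  if (length(patch_totals) != 3L) stop("exactly 3 patch totals are required")
  if (any(p_sup <= 0)) stop("p_sup must be > 0")
  mean(patch_totals) / p_sup
}

#' Natural-log transform with strict positivity
#'
#' Biovolume, resource and RUE responses are ln-transformed before ANOVA.
#' Non-positive values are an error, never silently offset or imputed.
#'
#' @param values Numeric vector, all > 0.
#' @return `log(values)`.
#' @export
ln_transform <- function(values) {
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("ln_transform requires strictly positive finite values")
  }
  log(values)
}

#' Local- and metacommunity-scale summary metrics
#'
#' Computes, for every flask, the total biovolume, realized richness,
#' Pielou evenness (NA for monocultures) and local RUE; and for every
#' metacommunity, the mean patch biovolume, evenness of the summed
#' community and metacommunity RUE.
#'
#' @param table Long-format community table (see [simulate_experiment()]).
#' @return List with `local` (one row per flask) and `metacommunity` (one
#'   row per metacommunity) data frames.
#' @export
community_metrics <- function(table) {
  key <- c("metacommunity_id", "patch_id", "composition", "p_sup_level",
           "p_sup", "np_ratio", "replicate")
  key <- intersect(key, names(table))
  sp_split <- split(seq_len(nrow(table)), table$patch_id)
  first <- vapply(sp_split, `[`, integer(1), 1L)
  local <- table[first, setdiff(key, "species"), drop = FALSE]
  samples <- lapply(sp_split, function(i)
    setNames(table$biovolume_um3_per_ml[i], table$species[i]))
  local$total_biovolume <- vapply(samples, sum, numeric(1))
  local$richness <- vapply(samples, function(s) sum(s > 0), numeric(1))
  local$evenness <- vapply(samples, pielou_evenness, numeric(1))
  local$rue <- rue_local(local$total_biovolume, local$p_sup)
  rownames(local) <- NULL

  mc_split <- split(seq_len(nrow(local)), local$metacommunity_id)
  meta_first <- vapply(mc_split, `[`, integer(1), 1L)
  meta <- local[meta_first,
                intersect(c("metacommunity_id", "composition", "p_sup_level",
                            "p_sup", "replicate"), names(local)),
                drop = FALSE]
  meta$mean_patch_biovolume <- vapply(mc_split, function(i)
    mean(local$total_biovolume[i]), numeric(1))
  meta$evenness <- vapply(names(mc_split), function(id) {
    pid <- local$patch_id[mc_split[[id]]]
    pielou_evenness(metacommunity_totals(samples[pid]))
  }, numeric(1))
  meta$rue <- vapply(names(mc_split), function(id) {
    i <- mc_split[[id]]
    rue_metacommunity(local$total_biovolume[i], local$p_sup[i][1])
  }, numeric(1))
  rownames(meta) <- NULL
  list(local = local[order(local$patch_id), ],
       metacommunity = meta[order(meta$metacommunity_id), ])
}
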