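#' Default species traits for the five-species algal pool
#'
#' Returns the trait table for the experimental species pool: a needle-like
#' chlorophyte (*Ankistrodesmus*, `AN`), a flagellated chlorophyte
#' (*Chlamydomonas*, `CL`), a nitrogen-fixing filamentous cyanobacterium
#' (*Cylindrospermum*, `CY`), an araphid diatom (*Fragilaria*, `FR`) and a
#' large dinoflagellate (*Gymnodinium*, `GY`). Cell geometry drives the
#' count-to-biovolume conversion; the growth columns parameterise the
#' Monod–Liebig simulator.
#'
#' Growth parameters encode the qualitative resource-use trade-offs of the
#' pool: the chlorophytes are nitrogen-demanding (high N quota and N
#' half-saturation), the cyanobacterium fixes nitrogen (dissolved N never
#' limits it) and grows fastest when phosphorus is plentiful, the diatom is
#' the superior competitor at scarce phosphorus (lowest P half-saturation
#' and quota; its silicate demand is folded into a modest maximum growth
#' rate), and the dinoflagellate is slow-growing throughout (its carbon
#' demand likewise folded into `mu_max`). Quotas are in µmol per 10^6 µm³
#' of biovolume; half-saturation constants in µmol L⁻¹; `mu_max` in day⁻¹.
#'
#' `interaction_bonus` is a multiplier on realised growth rate that is
#' active only in mixture flasks (default 1 = no interaction beyond
#' resource competition). Setting it above 1 injects a known amount of
#' facilitation/complementarity, which is how parameter-recovery and power
#' studies configure a "true" diversity effect.
#'
#' @param interaction_bonus Numeric scalar or length-5 vector recycled over
#'   species; growth multiplier applied in mixtures only.
#' @return A `data.frame` with one row per species: `species`, `genus`,
#'   `taxon_group`, `shape`, a `dimensions` list-column (µm), computed
#'   `mean_cell_biovolume` (µm³), and growth columns `mu_max`, `k_n`, `k_p`,
#'   `q_n`, `q_p`, `n_fixer`, `interaction_bonus`.
#' @examples
#' tr <- default_traits()
#' tr[, c("species", "mean_cell_biovolume", "mu_max", "n_fixer")]
#' @export
default_traits <- function(interaction_bonus = 1) {
  dims <- list(
    AN = c(diameter = 3, height = 40),
    CL = c(diameter = 8, height = 12),
    CY = c(diameter = 4, height = 8),
    FR = c(length = 25, width = 4, height = 5),
    GY = c(diameter = 30, height = 40)
  )
  shapes <- c(AN = "cylinder", CL = "prolate_spheroid", CY = "cylinder",
              FR = "box", GY = "cone_half_sphere")
  tr <- data.frame(
    species = names(dims),
    genus = c("Ankistrodesmus", "Chlamydomonas", "Cylindrospermum",
              "Fragilaria", "Gymnodinium"),
    taxon_group = c("Chlorophyta", "Chlorophyta", "Cyanobacteria",
                    "Bacillariophyta", "Dinophyta"),
    shape = unname(shapes),
    mu_max = c(0.55, 0.45, 0.60, 0.26, 0.24),
    k_n = c(2.0, 2.5, 1.0, 1.0, 2.0),
    k_p = c(0.35, 0.30, 0.40, 0.015, 0.20),
    q_n = c(3.6e-4, 3.4e-4, 1.5e-4, 1.1e-4, 2.8e-4),
    q_p = c(1.35e-5, 1.6e-5, 1.2e-5, 0.65e-5, 1.9e-5),
    n_fixer = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  tr$dimensions <- unname(dims)
  tr$mean_cell_biovolume <- mapply(
    function(s, d) cell_biovolume(s, d), tr$shape, tr$dimensions
  )
  tr$interaction_bonus <- rep_len(interaction_bonus, nrow(tr))
  validate_traits(tr)
  tr
}

#' Validate a species-trait table
#'
#' @param traits Trait `data.frame` in the layout of [default_traits()].
#' @return The trait table, invisibly, if valid; otherwise an error.
#' @keywords internal
validate_traits <- function(traits) {
  req <- c("species", "shape", "mu_max", "k_n", "k_p", "q_n", "q_p",
           "n_fixer", "mean_cell_biovolume", "interaction_bonus")
  missing_col <- setdiff(req, names(traits))
  if (length(missing_col) > 0L) {
    stop("trait table is missing column(s): ", paste(missing_col, collapse = ", "))
  }
  if (anyDuplicated(traits$species)) stop("duplicate species labels in trait table")
  if (any(traits$mu_max < 0)) stop("mu_max must be >= 0")
  if (any(traits$k_n <= 0) || any(traits$k_p <= 0)) {
    stop("half-saturation constants must be > 0")
  }
  if (any(traits$q_n < 0) || any(traits$q_p < 0)) stop("quotas must be >= 0")
  if (any(traits$mean_cell_biovolume <= 0)) stop("mean_cell_biovolume must be > 0")
  invisible(traits)
}
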