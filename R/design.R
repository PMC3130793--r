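#' Experiment configuration
#'
#' Builds the configuration object describing the factorial design: species
#' compositions (five monocultures plus the full mixture), phosphorus supply
#' levels, nitrogen:phosphorus supply ratios, replication, inoculum and
#' patch volume. Defaults reproduce the published design: three main P
#' levels (0.13, 0.81, 5.02 µmol L⁻¹) fully crossed with six compositions,
#' three N:P ratios (2, 16, 128) and three replicates, plus two extra P
#' levels (0.32, 2.02 µmol L⁻¹) run with the mixture only — 180 flasks in
#' 60 metacommunities of three N:P patches each.
#'
#' Phosphorus levels are referred to by roman numerals I–V in increasing
#' concentration; nitrogen is never configured directly but derived as
#' `p_sup * np_ratio` for each patch.
#'
#' @param p_main Named numeric vector of main P supply levels (µmol L⁻¹)
#'   crossed with every composition; names are the roman-numeral labels.
#' @param p_extra Named numeric vector of extra P supply levels crossed with
#'   `extra_compositions` only. May be empty.
#' @param np_ratios Numeric vector of N:P supply ratios, one patch per ratio
#'   within each metacommunity.
#' @param compositions Character vector of composition labels; species
#'   codes for monocultures plus `"MIX"` for the full mixture.
#' @param extra_compositions Compositions receiving the extra P levels.
#' @param replicates Integer number of replicate metacommunities per
#'   composition × P level.
#' @param total_inoculum Starting total biovolume per flask, µm³ mL⁻¹.
#' @param patch_volume Flask culture volume, mL.
#' @return An object of class `bef_config`.
#' @examples
#' cfg <- experiment_config()
#' nrow(enumerate_design(cfg)) # 180
#' @export
experiment_config <- function(p_main = c(I = 0.13, III = 0.81, V = 5.02),
                              p_extra = c(II = 0.32, IV = 2.02),
                              np_ratios = c(2, 16, 128),
                              compositions = c("AN", "CL", "CY", "FR", "GY", "MIX"),
                              extra_compositions = "MIX",
                              replicates = 3,
                              total_inoculum = 231e3,
                              patch_volume = 50) {
  if (length(p_main) == 0L) stop("at least one main P supply level is required")
  if (is.null(names(p_main)) || any(!nzchar(names(p_main)))) {
    stop("p_main must be a named vector (roman-numeral level labels)")
  }
  if (length(p_extra) > 0L &&
      (is.null(names(p_extra)) || any(!nzchar(names(p_extra))))) {
    stop("p_extra must be a named vector (roman-numeral level labels)")
  }
  all_p <- c(p_main, p_extra)
  if (anyDuplicated(names(all_p))) stop("duplicate P level labels")
  if (anyDuplicated(all_p)) stop("duplicate P level concentrations")
  if (any(all_p <= 0)) stop("P supply levels must be > 0")
  if (length(np_ratios) == 0L || any(np_ratios <= 0)) {
    stop("np_ratios must be positive and non-empty")
  }
  if (anyDuplicated(np_ratios)) stop("duplicate N:P ratios")
  if (length(compositions) == 0L || anyDuplicated(compositions)) {
    stop("compositions must be non-empty and unique")
  }
  if (length(p_extra) > 0L && !all(extra_compositions %in% compositions)) {
    stop("extra_compositions must be a subset of compositions")
  }
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) stop("replicates must be >= 1")
  if (total_inoculum <= 0) stop("total_inoculum must be > 0")
  if (patch_volume <= 0) stop("patch_volume must be > 0")
  structure(
    list(p_main = p_main, p_extra = p_extra, np_ratios = sort(np_ratios),
         compositions = compositions, extra_compositions = extra_compositions,
         replicates = replicates, total_inoculum = total_inoculum,
         patch_volume = patch_volume),
    class = "bef_config"
  )
}

#' @export
print.bef_config <- function(x, ...) {
  cat("Metacommunity experiment configuration\n")
  cat("  main P levels (umol/L):  ",
      paste(sprintf("%s=%g", names(x$p_main), x$p_main), collapse = ", "), "\n")
  if (length(x$p_extra) > 0L) {
    cat("  extra P levels (", paste(x$extra_compositions, collapse = ","),
        " only): ", paste(sprintf("%s=%g", names(x$p_extra), x$p_extra),
                          collapse = ", "), "\n", sep = "")
  }
  cat("  N:P ratios:              ", paste(x$np_ratios, collapse = ", "), "\n")
  cat("  compositions:            ", paste(x$compositions, collapse = ", "), "\n")
  cat("  replicates:              ", x$replicates, "\n")
  cat("  inoculum (um3/mL):       ", format(x$total_inoculum), "\n")
  cat("  patch volume (mL):       ", x$patch_volume, "\n")
  d <- enumerate_design(x)
  cat("  =>", nrow(d), "flasks in", length(unique(d$metacommunity_id)),
      "metacommunities\n")
  invisible(x)
}

#' Enumerate the full factorial design
#'
#' Expands the configuration into one row per flask. Each metacommunity is
#' a composition × P level × replicate cell and holds one patch per N:P
#' ratio; the extra P levels are crossed with the mixture only.
#' Identifiers are deterministic (`P{level}-{comp}-r{rep}` for
#' metacommunities, with `-NP{ratio}` inserted for patches) so repeated
#' runs are diffable.
#'
#' @param config A [experiment_config()] object.
#' @return A `data.frame` with columns `metacommunity_id`, `patch_id`,
#'   `composition`, `p_sup_level`, `p_sup`, `np_ratio`, `replicate`.
#' @examples
#' d <- enumerate_design(experiment_config())
#' table(d$p_sup_level)
#' @export
enumerate_design <- function(config) {
  stopifnot(inherits(config, "bef_config"))
  level_order <- names(sort(c(config$p_main, config$p_extra)))
  blocks <- list(
    expand.grid(composition = config$compositions,
                p_sup_level = names(config$p_main),
                np_ratio = config$np_ratios,
                replicate = seq_len(config$replicates),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  )
  if (length(config$p_extra) > 0L) {
    blocks[[2L]] <- expand.grid(composition = config$extra_compositions,
                                p_sup_level = names(config$p_extra),
                                np_ratio = config$np_ratios,
                                replicate = seq_len(config$replicates),
                                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, blocks)
  p_all <- c(config$p_main, config$p_extra)
  d$p_sup <- unname(p_all[d$p_sup_level])
  d$p_sup_level <- factor(d$p_sup_level, levels = level_order)
  d$metacommunity_id <- sprintf("P%s-%s-r%d", d$p_sup_level, d$composition,
                                d$replicate)
  d$patch_id <- sprintf("P%s-NP%g-%s-r%d", d$p_sup_level, d$np_ratio,
                        d$composition, d$replicate)
  d <- d[order(d$p_sup, d$composition, d$replicate, d$np_ratio),
         c("metacommunity_id", "patch_id", "composition", "p_sup_level",
           "p_sup", "np_ratio", "replicate")]
  rownames(d) <- NULL
  d
}

#' Initial state of one patch
#'
#' Applies the substitutive inoculation rule: a monoculture flask receives
#' the whole inoculum as its single species; the mixture receives the same
#' total evenly divided among the five species. Initial dissolved nitrogen
#' is derived from the patch's stoichiometry as `p_sup * np_ratio`.
#'
#' @param design_point One-row `data.frame` (a row of [enumerate_design()]).
#' @param traits Trait table; defines the species pool for `"MIX"`.
#' @param total_inoculum Total starting biovolume, µm³ mL⁻¹ (> 0).
#' @param patch_volume Culture volume, mL.
#' @return An object of class `bef_patch`: a list with `design`, `volume`
#'   (mL), `n_conc` and `p_conc` (µmol L⁻¹) and `biovolume` (named vector,
#'   µm³ mL⁻¹).
#' @examples
#' d <- enumerate_design(experiment_config())
#' p <- initial_patch_state(d[d$composition == "MIX", ][1, ], default_traits())
#' sum(p$biovolume) # 231000
#' @export
initial_patch_state <- function(design_point, traits = default_traits(),
                                total_inoculum = 231e3, patch_volume = 50) {
  if (total_inoculum <= 0) stop("total_inoculum must be > 0")
  comp <- as.character(design_point$composition)
  species <- traits$species
  bv <- setNames(numeric(length(species)), species)
  if (comp == "MIX") {
    bv[] <- total_inoculum / length(species)
  } else if (comp %in% species) {
    bv[comp] <- total_inoculum
  } else {
    stop("unknown composition label: ", comp)
  }
  structure(
    list(design = design_point, volume = patch_volume,
         n_conc = design_point$p_sup * design_point$np_ratio,
         p_conc = design_point$p_sup, biovolume = bv),
    class = "bef_patch"
  )
}

#' @export
print.bef_patch <- function(x, ...) {
  cat("Patch", x$design$patch_id, "-", x$volume, "mL\n")
  cat("  N =", format(x$n_conc), "umol/L, P =", format(x$p_conc), "umol/L\n")
  cat("  biovolume (um3/mL):\n")
  print(round(x$biovolume, 1))
  invisible(x)
}

#' Validate a long-format community table
#'
#' Structural checks on a flask × species biovolume table: required
#' columns, negative biovolumes, duplicated flask × species rows, species
#' outside the trait pool, and metacommunities that do not carry the full
#' set of N:P patches. Returns a report rather than throwing, so dirty
#' tables can be inspected.
#'
#' @param table Long-format `data.frame` with at least `metacommunity_id`,
#'   `patch_id`, `species`, `biovolume_um3_per_ml`, `np_ratio`.
#' @param np_ratios The N:P set every metacommunity must carry.
#' @param species Allowed species labels, or `NULL` to skip the check.
#' @return A `bef_validation` object: a `data.frame` of findings with
#'   columns `severity` (`"error"` or `"warning"`), `check` and `detail`;
#'   zero rows when the table is clean.
#' @export
validate_table <- function(table, np_ratios = c(2, 16, 128),
                           species = default_traits()$species) {
  findings <- list()
  add <- function(severity, check, detail) {
    findings[[length(findings) + 1L]] <<- data.frame(
      severity = severity, check = check, detail = detail,
      stringsAsFactors = FALSE)
  }
  req <- c("metacommunity_id", "patch_id", "species", "biovolume_um3_per_ml",
           "np_ratio")
  missing_col <- setdiff(req, names(table))
  if (length(missing_col) > 0L) {
    add("error", "missing_columns", paste(missing_col, collapse = ", "))
    return(.as_validation(do.call(rbind, findings)))
  }
  neg <- table$biovolume_um3_per_ml < 0 | !is.finite(table$biovolume_um3_per_ml)
  if (any(neg)) {
    add("error", "negative_biovolume",
        sprintf("%d record(s) with negative or non-finite biovolume (e.g. %s/%s)",
                sum(neg), table$patch_id[which(neg)[1L]],
                table$species[which(neg)[1L]]))
  }
  dup <- duplicated(table[, c("patch_id", "species")])
  if (any(dup)) {
    add("error", "duplicate_records",
        sprintf("%d duplicated patch x species row(s)", sum(dup)))
  }
  if (!is.null(species)) {
    unknown <- setdiff(unique(table$species), species)
    if (length(unknown) > 0L) {
      add("error", "unknown_species", paste(unknown, collapse = ", "))
    }
  }
  np_by_mc <- tapply(table$np_ratio, table$metacommunity_id,
                     function(x) sort(unique(x)), simplify = FALSE)
  bad <- names(np_by_mc)[!vapply(np_by_mc, function(x)
    length(x) == length(np_ratios) && all(x == sort(np_ratios)), logical(1))]
  for (mc in bad) {
    add("warning", "incomplete_metacommunity",
        sprintf("%s has N:P set {%s}, expected {%s}", mc,
                paste(np_by_mc[[mc]], collapse = ","),
                paste(sort(np_ratios), collapse = ",")))
  }
  .as_validation(if (length(findings)) do.call(rbind, findings) else NULL)
}

.as_validation <- function(df) {
  if (is.null(df)) {
    df <- data.frame(severity = character(), check = character(),
                     detail = character(), stringsAsFactors = FALSE)
  }
  class(df) <- c("bef_validation", "data.frame")
  df
}

#' @export
print.bef_validation <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("Community table validation: no findings\n")
  } else {
    cat("Community table validation:", nrow(x), "finding(s)\n")
    print.data.frame(x)
  }
  invisible(x)
}
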