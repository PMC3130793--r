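#' Cell biovolume from geometric shape
#'
#' Computes the volume of a single algal cell from its geometric shape and
#' linear dimensions, following the standard practice of assigning each
#' taxon a simple geometric solid and measuring its axes under the
#' microscope.
#'
#' Supported shapes and required dimensions (all in micrometres):
#' \describe{
#'   \item{`sphere`}{`diameter`; \eqn{V = \pi d^3 / 6}}
#'   \item{`prolate_spheroid`}{`diameter`, `height`; \eqn{V = \pi d^2 h / 6}}
#'   \item{`cylinder`}{`diameter`, `height`; \eqn{V = \pi d^2 h / 4}}
#'   \item{`box`}{`length`, `width`, `height`; \eqn{V = l w h}}
#'   \item{`cone_half_sphere`}{`diameter`, `height` (total, tip to dome);
#'     cone of height \eqn{h - d/2} topped by a hemisphere of diameter
#'     \eqn{d}: \eqn{V = \pi d^2 (h - d/2)/12 + \pi d^3/12}}
#' }
#'
#' @param shape Character scalar, one of the shapes above.
#' @param dimensions Named numeric vector of the shape's axes in µm.
#' @return Cell volume in µm³ (numeric scalar).
#' @examples
#' cell_biovolume("sphere", c(diameter = 10))
#' cell_biovolume("cylinder", c(diameter = 5, height = 10))
#' @export
cell_biovolume <- function(shape, dimensions) {
  shape <- match.arg(shape, names(.shape_axes))
  needed <- .shape_axes[[shape]]
  missing_axis <- setdiff(needed, names(dimensions))
  if (length(missing_axis) > 0L) {
    stop("shape '", shape, "' is missing dimension(s): ",
         paste(missing_axis, collapse = ", "))
  }
  d <- dimensions[needed]
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("all dimensions must be positive and finite")
  }
  switch(shape,
    sphere = pi * d[["diameter"]]^3 / 6,
    prolate_spheroid = pi * d[["diameter"]]^2 * d[["height"]] / 6,
    cylinder = pi * d[["diameter"]]^2 * d[["height"]] / 4,
    box = d[["length"]] * d[["width"]] * d[["height"]],
    cone_half_sphere = {
      dd <- d[["diameter"]]
      h <- d[["height"]]
      if (h <= dd / 2) stop("cone_half_sphere requires height > diameter/2")
      pi * dd^2 * (h - dd / 2) / 12 + pi * dd^3 / 12
    }
  )
}

.shape_axes <- list(
  sphere = "diameter",
  prolate_spheroid = c("diameter", "height"),
  cylinder = c("diameter", "height"),
  box = c("length", "width", "height"),
  cone_half_sphere = c("diameter", "height")
)

#' Mean cell biovolume from repeated measurements
#'
#' Averages per-cell volumes over a set of measured cells (conventionally 25
#' cells per species). The mean of volumes is used, not the volume of mean
#' dimensions, because the mean volume is the unbiased scale factor for the
#' biovolume summed over counted cells downstream.
#'
#' @param measurements List of named dimension vectors, one per measured cell.
#' @param shape Shape label passed to [cell_biovolume()].
#' @return Mean cell volume in µm³.
#' @examples
#' mean_cell_biovolume(
#'   list(c(diameter = 5, height = 10), c(diameter = 5, height = 20)),
#'   "cylinder"
#' )
#' @export
mean_cell_biovolume <- function(measurements, shape) {
  if (length(measurements) == 0L) stop("at least one measurement is required")
  mean(vapply(measurements, cell_biovolume, numeric(1), shape = shape))
}

#' Convert a microscope count record to a biovolume concentration
#'
#' Standard inverted-microscope (sedimentation chamber) bookkeeping: the
#' number of cells seen in an effective examined volume, corrected for any
#' dilution, times the species' mean cell volume.
#'
#' @param cells_counted Non-negative integer count of cells.
#' @param volume_examined_ml Effective volume examined, mL (> 0). Chamber
#'   geometry and grid fractions are folded into this single number.
#' @param mean_cell_biovolume Mean cell volume, µm³ (> 0).
#' @param dilution_factor Dilution applied before counting (>= 1).
#' @return Biovolume concentration in µm³ mL⁻¹.
#' @examples
#' counts_to_biovolume(400, 0.1, 100) # 400,000
#' @export
counts_to_biovolume <- function(cells_counted, volume_examined_ml,
                                mean_cell_biovolume, dilution_factor = 1) {
  if (any(cells_counted < 0)) stop("cells_counted must be >= 0")
  if (any(volume_examined_ml <= 0)) stop("volume_examined_ml must be > 0")
  if (any(mean_cell_biovolume <= 0)) stop("mean_cell_biovolume must be > 0")
  if (any(dilution_factor < 1)) stop("dilution_factor must be >= 1")
  cells_counted / volume_examined_ml * dilution_factor * mean_cell_biovolume
}
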