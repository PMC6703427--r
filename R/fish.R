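#' Cell abundance from CARD-FISH grid counts
#'
#' Converts microscopy counting-grid signal counts on a membrane filter
#' to cells per ml of sediment:
#' `cells/ml = mean_count_per_grid * (effective_filter_area / grid_area)
#'  * dilution_factor / sample_volume_ml`.
#' The result is linear in the mean count and the dilution factor and
#' inverse-linear in the filtered sample volume.
#'
#' @param mean_count_per_grid Mean number of signals per counting grid
#'   (>= 0), typically averaged over `n_grids` grids.
#' @param grid_area_um2 Area of one counting grid, um^2 (> 0).
#' @param effective_filter_area_um2 Filterable area of the membrane,
#'   um^2 (>= grid area).
#' @param sample_volume_ml Sediment volume applied to the filter, ml
#'   (> 0); the enumeration protocol modelled here used 1.3e-3 ml per
#'   filter.
#' @param dilution_factor Dilution applied before filtration (>= 1).
#' @param n_grids Number of grids counted (metadata; >= 1, protocol
#'   default 20).
#' @return One-row tibble with the inputs and `cells_per_ml`.
#' @examples
#' cells_per_ml(5, grid_area_um2 = 1.56e4,
#'              effective_filter_area_um2 = 2.27e8,
#'              sample_volume_ml = 1.3e-3)
#' @export
cells_per_ml <- function(mean_count_per_grid, grid_area_um2,
                         effective_filter_area_um2,
                         sample_volume_ml = 1.3e-3, dilution_factor = 1,
                         n_grids = 20) {
  if (mean_count_per_grid < 0) {
    stop("mean_count_per_grid must be >= 0", call. = FALSE)
  }
  if (grid_area_um2 <= 0 || effective_filter_area_um2 <= 0 ||
      sample_volume_ml <= 0) {
    stop("areas and volume must be > 0", call. = FALSE)
  }
  if (grid_area_um2 > effective_filter_area_um2) {
    stop("grid_area_um2 cannot exceed effective_filter_area_um2",
         call. = FALSE)
  }
  if (dilution_factor < 1) stop("dilution_factor must be >= 1", call. = FALSE)
  if (n_grids < 1) stop("n_grids must be >= 1", call. = FALSE)
  tibble::tibble(
    mean_count_per_grid = mean_count_per_grid,
    n_grids = n_grids,
    grid_area_um2 = grid_area_um2,
    effective_filter_area_um2 = effective_filter_area_um2,
    sample_volume_ml = sample_volume_ml,
    dilution_factor = dilution_factor,
    cells_per_ml = mean_count_per_grid *
      (effective_filter_area_um2 / grid_area_um2) *
      dilution_factor / sample_volume_ml
  )
}

#' Cells per spherical aggregate
#'
#' Estimates the number of coccoid cells in a spherical cell aggregate
#' from its two-dimensional diameter:
#' `cells = packing_fraction * (aggregate_diameter / cell_diameter)^3`.
#' The naive volume-ratio estimate uses packing 1 (the protocol's
#' assumption); `packing_presets()["random_close"]` (0.64) is the named
#' alternative for random close packing of spheres.
#'
#' @param aggregate_diameter_um Aggregate diameter, um (>= cell
#'   diameter).
#' @param cell_diameter_um Cell diameter, um (protocol default 1).
#' @param packing_fraction Fraction of the aggregate volume occupied by
#'   cells, in (0, 1].
#' @return One-row tibble with `cells` (rounded to nearest integer) and
#'   `cells_raw` (unrounded).
#' @examples
#' aggregate_cells(10)                          # 1000 cells
#' aggregate_cells(12, packing_fraction = 0.64) # 1106 cells
#' @export
aggregate_cells <- function(aggregate_diameter_um, cell_diameter_um = 1,
                            packing_fraction = 1) {
  if (cell_diameter_um <= 0) stop("cell diameter must be > 0", call. = FALSE)
  if (aggregate_diameter_um < cell_diameter_um) {
    stop("aggregate diameter cannot be smaller than the cell diameter",
         call. = FALSE)
  }
  if (packing_fraction <= 0 || packing_fraction > 1) {
    stop("packing_fraction must be in (0, 1]", call. = FALSE)
  }
  raw <- packing_fraction * (aggregate_diameter_um / cell_diameter_um)^3
  tibble::tibble(
    aggregate_diameter_um = aggregate_diameter_um,
    cell_diameter_um = cell_diameter_um,
    packing_fraction = packing_fraction,
    cells = round(raw),
    cells_raw = raw
  )
}

#' Named packing-fraction presets
#'
#' @return Named numeric vector: `naive` (1.0, plain volume ratio) and
#'   `random_close` (0.64, random close packing of equal spheres).
#' @export
packing_presets <- function() c(naive = 1.0, random_close = 0.64)
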