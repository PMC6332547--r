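#' Cumulative dose-volume histogram
#'
#' Cumulative DVH by voxel counting: for each dose bin edge, the percent of
#' the structure's volume receiving at least that dose. Bin edges start at
#' 0 Gy with constant width (default 0.1 Gy, finer than any reported metric
#' precision) and span the maximum dose inside the mask.
#'
#' Metrics themselves ([vx()], [mld()]) are computed from the voxel set
#' directly; the binned DVH is a reporting artifact with no discretization
#' feedback into the metrics.
#'
#' @param dose A [dose_grid()].
#' @param mask A non-empty [structure_mask()] on the same grid.
#' @param bin_width Bin width in Gy (> 0), default 0.1.
#' @return An object of class `dvh`: list with `bin_edges` (Gy),
#'   `cum_volume_pct`, `structure_volume_cm3`, `structure` and `bin_width`.
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.1) {
  check_dose_mask(dose, mask)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("`bin_width` must be a single positive dose in Gy", call. = FALSE)
  d <- dose$values[mask$voxels]
  edges <- seq(0, by = bin_width, length.out = ceiling(max(d) / bin_width) + 2L)
  cum <- 100 * vapply(edges, function(e) mean(d >= e), numeric(1))
  structure(list(bin_edges = edges, cum_volume_pct = cum,
                 structure_volume_cm3 = mask_volume_cm3(mask),
                 structure = mask$name, bin_width = bin_width),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> %s (%.1f cm3), %d edges of %.3g Gy, max dose bin %.1f Gy\n",
              x$structure, x$structure_volume_cm3, length(x$bin_edges),
              x$bin_width, max(x$bin_edges)))
  invisible(x)
}

#' Export a DVH as a two-column CSV
#'
#' Columns `dose_gy`, `volume_pct` — one file per patient per definition.
#'
#' @param dvh A `dvh` object from [compute_dvh()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dvh_csv <- function(dvh, path) {
  stopifnot(inherits(dvh, "dvh"))
  utils::write.csv(data.frame(dose_gy = dvh$bin_edges,
                              volume_pct = dvh$cum_volume_pct),
                   path, row.names = FALSE)
  invisible(path)
}

#' Vx: percent of structure volume receiving at least a threshold dose
#'
#' `vx(dose, mask, 5)` is V5, `vx(dose, mask, 20)` is V20. The comparison is
#' inclusive (dose >= threshold), matching the usual definition of the
#' percentage of normal-lung volume receiving equal to or greater than the
#' threshold.
#'
#' @inheritParams compute_dvh
#' @param threshold Dose threshold in Gy.
#' @return Percent of the mask's volume, in `[0, 100]`.
#' @export
vx <- function(dose, mask, threshold) {
  check_dose_mask(dose, mask)
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  100 * mean(dose$values[mask$voxels] >= threshold)
}

#' Mean lung dose (mean structure dose)
#'
#' Arithmetic mean of dose over the mask's voxels, in Gy.
#'
#' @inheritParams compute_dvh
#' @return Mean dose in Gy.
#' @export
mld <- function(dose, mask) {
  check_dose_mask(dose, mask)
  mean(dose$values[mask$voxels])
}

#' V5/V20/MLD for one normal-lung definition
#'
#' @inheritParams compute_dvh
#' @param definition Label of the lung definition the mask represents.
#' @return A one-row data.frame with columns `definition`, `v5`, `v20`, `mld`.
#' @export
dose_metrics <- function(dose, mask, definition = mask$name) {
  data.frame(definition = definition,
             v5  = vx(dose, mask, 5),
             v20 = vx(dose, mask, 20),
             mld = mld(dose, mask))
}

check_dose_mask <- function(dose, mask) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "structure_mask"))
  if (!same_grid(dose, mask))
    stop("dose grid and mask are not congruent (shape/spacing mismatch)",
         call. = FALSE)
  if (!any(mask$voxels))
    stop("mask '", mask$name, "' is empty: DVH metrics are undefined",
         call. = FALSE)
  invisible(TRUE)
}
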