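#' Dose grid constructor
#'
#' A `dose_grid` is a regular 3D scalar field of absorbed dose in Gray
#' together with the physical voxel spacing. It is the container every DVH
#' and every structure mask refers to.
#'
#' @param values Numeric 3D array of absorbed dose per voxel (Gy). All values
#'   must be finite and non-negative.
#' @param spacing Numeric vector of length 3: voxel edge lengths in mm along
#'   each array dimension. Strictly positive; anisotropic spacing is allowed.
#' @return An object of class `dose_grid` with elements `values`, `spacing`
#'   and `shape`.
#' @examples
#' g <- dose_grid(array(10, c(4, 4, 4)), spacing = c(2, 2, 3))
#' g$shape
#' @export
dose_grid <- function(values, spacing) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("dose values must be finite", call. = FALSE)
  if (any(values < 0))
    stop("dose values must be non-negative", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive lengths (mm)", call. = FALSE)
  structure(list(values = values, spacing = spacing, shape = dim(values)),
            class = "dose_grid")
}

#' Structure mask constructor
#'
#' A named boolean voxel mask congruent with a [dose_grid()]: lungs, GTV,
#' CTV, PTV, PGTV or any derived normal-lung definition.
#'
#' @param name Character label for the structure (e.g. `"LUNGS"`, `"PTV"`).
#' @param voxels Logical 3D array of voxel inclusion flags.
#' @param spacing Numeric length-3 voxel spacing in mm (must match the grid
#'   the mask is used with).
#' @return An object of class `structure_mask`.
#' @seealso [mask_volume_cm3()], [expand_margin()], [normal_lung_mask()]
#' @export
structure_mask <- function(name, voxels, spacing) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L || !is.logical(voxels))
    stop("`voxels` must be a logical 3D array", call. = FALSE)
  if (anyNA(voxels)) stop("mask voxels must not contain NA", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive lengths (mm)", call. = FALSE)
  structure(list(name = as.character(name)[1], voxels = voxels,
                 spacing = spacing, shape = dim(voxels)),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> %s: %d voxels (%.1f cm3), grid %s, spacing %s mm\n",
              x$name, sum(x$voxels), mask_volume_cm3(x),
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> grid %s, spacing %s mm, dose range %.2f-%.2f Gy\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Physical volume of a structure mask
#'
#' Volume is voxel count times voxel volume (voxel-center membership
#' convention, no partial-volume weighting).
#'
#' @param mask A [structure_mask()].
#' @return Volume in cm^3.
#' @export
mask_volume_cm3 <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  sum(mask$voxels) * prod(mask$spacing) / 1000
}

# grids/masks are congruent when shape and spacing agree
same_grid <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-9))
}

# All integer voxel offsets whose physical voxel-center distance is <= margin.
# This is the exact Euclidean structuring element for anisotropic spacing.
ball_offsets <- function(margin, spacing) {
  r <- floor(margin / spacing + 1e-9)
  off <- expand.grid(i = -r[1]:r[1], j = -r[2]:r[2], k = -r[3]:r[3])
  d2 <- (off$i * spacing[1])^2 + (off$j * spacing[2])^2 + (off$k * spacing[3])^2
  off[d2 <= margin^2 + 1e-9, , drop = FALSE]
}

#' Uniform margin expansion of a structure mask
#'
#' Euclidean dilation in physical units: every voxel whose center lies within
#' `margin` millimetres of the center of any voxel of the input mask is set.
#' This is the geometric operation behind GTV-to-CTV microscopic margins and
#' CTV/GTV-to-PTV/PGTV setup margins. The result is always a superset of the
#' input and is clipped at the grid boundary (a warning is raised when
#' clipping discards part of the dilation).
#'
#' @param mask A [structure_mask()].
#' @param margin Non-negative margin in mm.
#' @return A [structure_mask()] on the same grid; the name gains a
#'   `+<margin>mm` suffix.
#' @examples
#' vox <- array(FALSE, c(5, 5, 5)); vox[3, 3, 3] <- TRUE
#' m <- structure_mask("GTV", vox, spacing = c(1, 1, 1))
#' sum(expand_margin(m, 1)$voxels)  # 7: face-connected cross
#' @export
expand_margin <- function(mask, margin) {
  stopifnot(inherits(mask, "structure_mask"))
  if (!is.numeric(margin) || length(margin) != 1L || is.na(margin) || margin < 0)
    stop("`margin` must be a single non-negative length in mm", call. = FALSE)
  if (!any(mask$voxels)) {
    warning("expanding an empty mask: returned unchanged")
    return(mask)
  }
  out_name <- if (margin > 0) sprintf("%s+%gmm", mask$name, margin) else mask$name
  if (margin == 0)
    return(structure_mask(out_name, mask$voxels, mask$spacing))

  off <- ball_offsets(margin, mask$spacing)
  dims <- mask$shape
  res <- array(FALSE, dims)
  clipped <- FALSE
  idx <- which(mask$voxels, arr.ind = TRUE)
  rng <- apply(idx, 2, range)
  for (r in seq_len(nrow(off))) {
    di <- off$i[r]; dj <- off$j[r]; dk <- off$k[r]
    # target slab = source slab shifted by (di, dj, dk), clipped to the grid
    si <- max(1L, 1L - di):min(dims[1], dims[1] - di)
    sj <- max(1L, 1L - dj):min(dims[2], dims[2] - dj)
    sk <- max(1L, 1L - dk):min(dims[3], dims[3] - dk)
    if (!clipped &&
        (rng[1, 1] + di < 1 || rng[2, 1] + di > dims[1] ||
         rng[1, 2] + dj < 1 || rng[2, 2] + dj > dims[2] ||
         rng[1, 3] + dk < 1 || rng[2, 3] + dk > dims[3]))
      clipped <- TRUE
    res[si + di, sj + dj, sk + dk] <-
      res[si + di, sj + dj, sk + dk] | mask$voxels[si, sj, sk]
  }
  if (clipped)
    warning(sprintf("dilation of '%s' by %g mm clipped at grid boundary",
                    mask$name, margin))
  structure_mask(out_name, res, mask$spacing)
}

#' Construct a normal-lung mask under one of the three definitions
#'
#' The three normal-lung definitions compared throughout the package are
#' Total Lung (both lungs, nothing subtracted), Lung-PGTV and Lung-PTV
#' (lungs minus the intrapulmonary part of the PGTV or PTV). Subtraction
#' follows the overlap rule: only voxels of the target that lie inside the
#' lungs are removed, so an extrapulmonary target leaves the lungs untouched.
#'
#' @param lungs [structure_mask()] of the bilateral lungs.
#' @param target [structure_mask()] of the PTV or PGTV; ignored (may be
#'   `NULL`) for `mode = "TOTAL_LUNG"`.
#' @param mode One of `"TOTAL_LUNG"`, `"LUNG_MINUS_PGTV"`, `"LUNG_MINUS_PTV"`.
#' @return A [structure_mask()]; always a subset of `lungs`.
#' @export
normal_lung_mask <- function(lungs, target = NULL,
                             mode = c("TOTAL_LUNG", "LUNG_MINUS_PGTV",
                                      "LUNG_MINUS_PTV")) {
  mode <- match.arg(mode)
  stopifnot(inherits(lungs, "structure_mask"))
  if (mode == "TOTAL_LUNG")
    return(structure_mask("TOTAL_LUNG", lungs$voxels, lungs$spacing))
  if (is.null(target) || !inherits(target, "structure_mask"))
    stop("`target` mask required for ", mode, call. = FALSE)
  if (!same_grid(lungs, target))
    stop("`lungs` and `target` must live on the same grid", call. = FALSE)
  structure_mask(mode, lungs$voxels & !target$voxels, lungs$spacing)
}

#' The three lung definitions at once
#'
#' Convenience wrapper returning the Total Lung, Lung-PGTV and Lung-PTV masks
#' for a given lungs/PTV/PGTV triple.
#'
#' @param lungs,ptv,pgtv [structure_mask()]s on a common grid.
#' @return Named list of three [structure_mask()]s:
#'   `TOTAL_LUNG`, `LUNG_MINUS_PGTV`, `LUNG_MINUS_PTV`.
#' @export
lung_definitions <- function(lungs, ptv, pgtv) {
  list(TOTAL_LUNG      = normal_lung_mask(lungs, mode = "TOTAL_LUNG"),
       LUNG_MINUS_PGTV = normal_lung_mask(lungs, pgtv, "LUNG_MINUS_PGTV"),
       LUNG_MINUS_PTV  = normal_lung_mask(lungs, ptv, "LUNG_MINUS_PTV"))
}

#' Save / load a dose grid and masks as flat binary + JSON sidecar
#'
#' Serialization format for phantom output: one little-endian float64 `.raw`
#' file per array plus a `meta.json` sidecar recording shape, spacing (mm),
#' dtype and structure names. DICOM-RT is deliberately not supported.
#'
#' @param dose A [dose_grid()].
#' @param masks Named list of [structure_mask()]s on the same grid.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_phantom_dir <- function(dose, masks, dir) {
  stopifnot(inherits(dose, "dose_grid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeBin(as.vector(dose$values), file.path(dir, "dose.raw"),
           size = 8, endian = "little")
  for (nm in names(masks))
    writeBin(as.double(masks[[nm]]$voxels), file.path(dir, paste0(nm, ".raw")),
             size = 8, endian = "little")
  meta <- list(shape = dose$shape, spacing_mm = dose$spacing,
               dtype = "float64-le", structures = as.list(names(masks)))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_phantom_dir
#' @export
load_phantom_dir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  shp <- as.integer(meta$shape); n <- prod(shp)
  rd <- function(f) array(readBin(file.path(dir, f), "double", n = n,
                                  size = 8, endian = "little"), shp)
  dose <- dose_grid(rd("dose.raw"), meta$spacing_mm)
  masks <- lapply(meta$structures, function(nm)
    structure_mask(nm, rd(paste0(nm, ".raw")) != 0, meta$spacing_mm))
  names(masks) <- meta$structures
  list(dose = dose, masks = masks)
}
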