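#' Thorax phantom configuration
#'
#' Geometric configuration for the synthetic thorax: two ellipsoidal lungs,
#' a spherical GTV inside one lung, margin-derived CTV/PTV/PGTV, and a dose
#' field that is flat at prescription inside the PTV and falls off
#' exponentially with Euclidean distance outside it.
#'
#' Default margins follow common thoracic planning practice: an 8 mm
#' GTV-to-CTV microscopic margin (6 mm would be typical for squamous
#' histology) and a 5 mm uniform setup margin for both CTV-to-PTV and
#' GTV-to-PGTV. The prescription must lie in \[50, 70\] Gy.
#'
#' @param shape Integer vector of 3 voxel counts.
#' @param spacing Voxel edge lengths in mm (length 3).
#' @param lung_centers List of two numeric xyz centers (mm) for the lung
#'   ellipsoids.
#' @param lung_semiaxes Numeric xyz semi-axes (mm), shared by both lungs.
#' @param gtv_center Numeric xyz center (mm) of the spherical GTV; must lie
#'   strictly inside a lung.
#' @param gtv_radius GTV radius (mm).
#' @param ctv_margin GTV-to-CTV margin (mm), default 8.
#' @param setup_margin Setup margin (mm) for PTV and PGTV, default 5.
#' @param prescription_gy Prescription dose (Gy) delivered inside the PTV.
#' @param falloff_mm Exponential falloff length-scale of dose with distance
#'   outside the PTV (mm); `Inf` gives a uniform dose field.
#' @param dose_noise_sd Lognormal sd of the multiplicative perturbation on
#'   the effective falloff distance (0 = deterministic dose).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(36L, 44L, 36L),
                           spacing = c(5, 5, 5),
                           lung_centers = list(c(50, 110, 95), c(130, 110, 95)),
                           lung_semiaxes = c(38, 88, 65),
                           gtv_center = c(130, 110, 95),
                           gtv_radius = 18,
                           ctv_margin = 8,
                           setup_margin = 5,
                           prescription_gy = 60,
                           falloff_mm = 20,
                           dose_noise_sd = 0.05) {
  stopifnot(length(shape) == 3L, all(shape >= 4),
            length(spacing) == 3L, all(spacing > 0),
            length(lung_centers) == 2L, length(lung_semiaxes) == 3L,
            all(lung_semiaxes > 0), length(gtv_center) == 3L,
            gtv_radius > 0, ctv_margin >= 0, setup_margin >= 0,
            falloff_mm > 0, dose_noise_sd >= 0)
  if (prescription_gy < 50 || prescription_gy > 70)
    stop("`prescription_gy` must lie in [50, 70] Gy", call. = FALSE)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 lung_centers = lung_centers, lung_semiaxes = lung_semiaxes,
                 gtv_center = gtv_center, gtv_radius = gtv_radius,
                 ctv_margin = ctv_margin, setup_margin = setup_margin,
                 prescription_gy = prescription_gy, falloff_mm = falloff_mm,
                 dose_noise_sd = dose_noise_sd),
            class = "phantom_config")
}

# physical voxel-center coordinates of every voxel, as an n x 3 matrix
voxel_centers <- function(shape, spacing) {
  cbind(
    (as.vector(slice.index(array(0, shape), 1)) - 0.5) * spacing[1],
    (as.vector(slice.index(array(0, shape), 2)) - 0.5) * spacing[2],
    (as.vector(slice.index(array(0, shape), 3)) - 0.5) * spacing[3])
}

ellipsoid_mask <- function(shape, spacing, center, semiaxes) {
  xyz <- voxel_centers(shape, spacing)
  inside <- ((xyz[, 1] - center[1]) / semiaxes[1])^2 +
    ((xyz[, 2] - center[2]) / semiaxes[2])^2 +
    ((xyz[, 3] - center[3]) / semiaxes[3])^2 <= 1
  array(inside, shape)
}

# Boundary voxels of a mask: in mask, with at least one in-grid 6-neighbour
# outside the mask. The nearest mask voxel to any external grid point is
# always such a voxel (stepping one voxel toward the query point strictly
# reduces the distance), so distances-to-mask only need the boundary set.
# Off-grid neighbours are treated as in-mask: they can never be query points.
mask_boundary <- function(vox) {
  dims <- dim(vox)
  has_outside_nb <- array(FALSE, dims)
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      ii <- seq_len(dims[1]); jj <- seq_len(dims[2]); kk <- seq_len(dims[3])
      if (ax == 1) ii <- ii[ii + s >= 1 & ii + s <= dims[1]]
      if (ax == 2) jj <- jj[jj + s >= 1 & jj + s <= dims[2]]
      if (ax == 3) kk <- kk[kk + s >= 1 & kk + s <= dims[3]]
      di <- if (ax == 1) s else 0L; dj <- if (ax == 2) s else 0L
      dk <- if (ax == 3) s else 0L
      has_outside_nb[ii, jj, kk] <- has_outside_nb[ii, jj, kk] |
        !vox[ii + di, jj + dj, kk + dk]
    }
  }
  vox & has_outside_nb
}

# Euclidean distance (mm) from every voxel center to the nearest voxel
# center of `vox`; 0 inside. Running minimum over the boundary voxel set.
distance_to_mask <- function(vox, spacing) {
  dims <- dim(vox)
  xyz <- voxel_centers(dims, spacing)
  bidx <- which(mask_boundary(vox))
  d2 <- rep(Inf, prod(dims))
  for (b in bidx) {
    dd <- (xyz[, 1] - xyz[b, 1])^2 + (xyz[, 2] - xyz[b, 2])^2 +
      (xyz[, 3] - xyz[b, 3])^2
    d2 <- pmin(d2, dd)
  }
  d <- sqrt(d2)
  d[as.vector(vox)] <- 0
  array(d, dims)
}

#' Generate the synthetic thorax phantom
#'
#' Builds the structure set (LUNGS, GTV, CTV, PTV, PGTV) by margin expansion
#' — `CTV = GTV + ctv_margin`, `PTV = CTV + setup_margin`,
#' `PGTV = GTV + setup_margin` — and a dose grid equal to the prescription
#' inside the PTV with exponential falloff outside:
#' `D(x) = Rx * exp(-dist(x, PTV) * u(x) / falloff_mm)`, where `u` is a
#' per-voxel lognormal perturbation (median 1). Because `u > 0`, every PTV
#' voxel receives at least as much dose as any voxel outside the PTV, which
#' guarantees the definition-ordering invariant
#' `MLD(Lung-PTV) <= MLD(Lung-PGTV) <= MLD(Total Lung)` downstream, and the
#' `falloff_mm = Inf` limit yields an exactly uniform dose field.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed for the dose-noise draw (single RNG stream).
#' @return A list with `dose` (a [dose_grid()]) and `masks` (named list of
#'   [structure_mask()]s: LUNGS, GTV, CTV, PTV, PGTV).
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  shp <- config$shape; sp <- config$spacing

  lungs_vox <- ellipsoid_mask(shp, sp, config$lung_centers[[1]],
                              config$lung_semiaxes) |
    ellipsoid_mask(shp, sp, config$lung_centers[[2]], config$lung_semiaxes)
  xyz <- voxel_centers(shp, sp)
  gtv_vox <- array(sqrt((xyz[, 1] - config$gtv_center[1])^2 +
                        (xyz[, 2] - config$gtv_center[2])^2 +
                        (xyz[, 3] - config$gtv_center[3])^2) <=
                     config$gtv_radius, shp)
  if (!any(gtv_vox))
    stop("GTV contains no voxels: enlarge the radius or refine the grid",
         call. = FALSE)
  if (any(gtv_vox & !lungs_vox))
    stop("GTV is not strictly inside the lungs", call. = FALSE)

  lungs <- structure_mask("LUNGS", lungs_vox, sp)
  gtv <- structure_mask("GTV", gtv_vox, sp)
  ctv <- expand_margin(gtv, config$ctv_margin)
  ptv <- expand_margin(ctv, config$setup_margin)
  pgtv <- expand_margin(gtv, config$setup_margin)

  if (is.finite(config$falloff_mm)) {
    dist <- distance_to_mask(ptv$voxels, sp)
    set.seed(as.integer(seed))
    u <- if (config$dose_noise_sd > 0)
      array(exp(stats::rnorm(prod(shp), 0, config$dose_noise_sd)), shp)
    else 1
    dose_vals <- config$prescription_gy *
      exp(-(dist * u) / config$falloff_mm)
  } else {
    dose_vals <- array(config$prescription_gy, shp)
  }
  list(dose = dose_grid(dose_vals, sp),
       masks = list(LUNGS = lungs, GTV = gtv, CTV = structure_mask("CTV", ctv$voxels, sp),
                    PTV = structure_mask("PTV", ptv$voxels, sp),
                    PGTV = structure_mask("PGTV", pgtv$voxels, sp)))
}

#' Cohort simulation configuration
#'
#' Statistical configuration of the synthetic patient cohort. Defaults
#' emulate a 183-patient thoracic IMRT cohort with ~14% grade >= 2
#' pneumonitis (RP2): Lung-PTV MLD is drawn lognormal (median 10.3 Gy,
#' `sdlog` 0.22) truncated to \[6, 16\] Gy; Lung-PGTV and Total-Lung MLD sit
#' 1.7 and 2.3 Gy higher on average with small positive-increment jitter;
#' V5 and V20 are monotone noisy transforms of MLD with V20 <= V5 enforced;
#' and RP2 is Bernoulli with probability given by the Lyman curve
#' (`td50_true` = 17.5 Gy, `m_true` = 0.34) evaluated at the driving metric
#' (Lung-PTV MLD by default, configurable to study misspecification).
#'
#' @param n_patients Cohort size (>= 2), default 183.
#' @param td50_true,m_true True Lyman parameters of the outcome model.
#' @param mld_median,mld_sdlog Median (Gy) and log-sd of the Lung-PTV MLD
#'   distribution.
#' @param mld_range Truncation range (Gy) for Lung-PTV MLD.
#' @param d_pgtv,d_total Mean MLD offsets (Gy) of Lung-PGTV and Total Lung
#'   above Lung-PTV; both > 0 and `d_total > d_pgtv`.
#' @param jitter_sd SD (Gy) of the per-patient jitter on the offsets;
#'   increments are floored at 0.05 Gy so the definition ordering always
#'   holds.
#' @param v5_slope,v5_sd,v20_slope,v20_sd Slope (per Gy of MLD) and residual
#'   SD of the V5/V20 transforms.
#' @param rp2_driver Column driving the outcome model, default
#'   `"mld_lungptv"`.
#' @param seed Integer seed; one seed drives the single RNG stream for all
#'   draws (covariates first, then metrics, then outcomes).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 183L, td50_true = 17.5, m_true = 0.34,
                          mld_median = 10.3, mld_sdlog = 0.22,
                          mld_range = c(6, 16),
                          d_pgtv = 1.7, d_total = 2.3, jitter_sd = 0.2,
                          v5_slope = 4.7, v5_sd = 6,
                          v20_slope = 1.75, v20_sd = 2.5,
                          rp2_driver = "mld_lungptv", seed = 1L) {
  stopifnot(n_patients >= 2, td50_true > 0, m_true > 0,
            mld_median > 0, mld_sdlog > 0, length(mld_range) == 2L,
            mld_range[1] < mld_range[2],
            d_pgtv > 0, d_total > d_pgtv, jitter_sd >= 0,
            v5_slope > 0, v5_sd >= 0, v20_slope > 0, v20_sd >= 0)
  rp2_driver <- match.arg(rp2_driver,
                          c("mld_lungptv", "mld_lungpgtv", "mld_total"))
  structure(list(n_patients = as.integer(n_patients), td50_true = td50_true,
                 m_true = m_true, mld_median = mld_median,
                 mld_sdlog = mld_sdlog, mld_range = mld_range,
                 d_pgtv = d_pgtv, d_total = d_total, jitter_sd = jitter_sd,
                 v5_slope = v5_slope, v5_sd = v5_sd,
                 v20_slope = v20_slope, v20_sd = v20_sd,
                 rp2_driver = rp2_driver, seed = as.integer(seed)),
            class = "cohort_config")
}

# truncated lognormal by rejection; the acceptance region is wide so a few
# rounds always suffice
rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2L * (n - length(out)) + 10L, meanlog, sdlog)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulate a patient cohort
#'
#' Draws clinical covariates from the marginal frequencies typical of a
#' thoracic IMRT series (covariates are outcome-independent by default),
#' dose metrics under the three lung definitions with the configured
#' offsets, and the binary RP2 outcome from the true Lyman dose-response.
#' All per-patient constraints hold for every record: V20 <= V5 within a
#' definition and Lung-PTV <= Lung-PGTV <= Total Lung for each metric.
#' Metrics are rounded to 0.1 (1 decimal), mimicking reported precision and
#' creating realistic ties.
#'
#' @param config A [cohort_config()].
#' @return A data.frame of class `rp_cohort`, one row per patient, with the
#'   cohort CSV schema columns (`id`, `age`, `gender`, `smoking`,
#'   `pathology`, `stage`, `chemo`, `surgery`, `pgtv_volume_cm3`,
#'   `ptv_volume_cm3`, `pgtv_rx_gy`, `ptv_rx_gy`, `v5_lungptv`, ...,
#'   `mld_total`, `rp2`). The generating config is attached as attribute
#'   `"config"`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  set.seed(config$seed)

  age <- pmin(pmax(round(stats::rnorm(n, 62, 10)), 25), 88)
  gender <- sample(c("male", "female"), n, TRUE, prob = c(162, 21) / 183)
  smoking <- sample(c("never", "current", "former"), n, TRUE,
                    prob = c(42, 77, 64) / 183)
  pathology <- sample(c("squamous", "adenocarcinoma", "small_cell", "others"),
                      n, TRUE, prob = c(112, 30, 35, 6) / 183)
  stage <- sample(c("I/II", "III", "IV"), n, TRUE, prob = c(14, 115, 54) / 183)
  chemo <- stats::rbinom(n, 1, 158 / 183)
  surgery <- stats::rbinom(n, 1, 44 / 183)
  pgtv_volume <- round(stats::rlnorm(n, log(135.1), 0.8), 1)
  ptv_volume <- round(pgtv_volume * exp(stats::rnorm(n, log(543.6 / 135.1), 0.3)), 1)
  pgtv_rx <- sample(c(50, 54, 56, 60, 66, 70), n, TRUE,
                    prob = c(.35, .27, .10, .18, .06, .04))
  ptv_rx <- sample(c(45, 48, 50, 54), n, TRUE, prob = c(.18, .20, .50, .12))

  mld_ptv <- rlnorm_trunc(n, log(config$mld_median), config$mld_sdlog,
                          config$mld_range[1], config$mld_range[2])
  inc1 <- pmax(0.05, stats::rnorm(n, config$d_pgtv, config$jitter_sd))
  inc2 <- pmax(0.05, stats::rnorm(n, config$d_total - config$d_pgtv,
                                  config$jitter_sd))
  mld_pgtv <- mld_ptv + inc1
  mld_total <- mld_pgtv + inc2

  e5 <- stats::rnorm(n, 0, config$v5_sd)
  e20 <- stats::rnorm(n, 0, config$v20_sd)
  mk_v <- function(mldv) {
    v5 <- pmin(pmax(config$v5_slope * mldv + e5, 0), 100)
    v20 <- pmin(pmax(config$v20_slope * mldv + e20, 0), v5)
    list(v5 = v5, v20 = v20)
  }
  vp <- mk_v(mld_ptv); vg <- mk_v(mld_pgtv); vt <- mk_v(mld_total)

  cohort <- data.frame(
    id = sprintf("P%04d", seq_len(n)),
    age = age, gender = gender, smoking = smoking, pathology = pathology,
    stage = stage, chemo = chemo, surgery = surgery,
    pgtv_volume_cm3 = pgtv_volume, ptv_volume_cm3 = ptv_volume,
    pgtv_rx_gy = pgtv_rx, ptv_rx_gy = ptv_rx,
    v5_lungptv = round(vp$v5, 1), v20_lungptv = round(vp$v20, 1),
    mld_lungptv = round(mld_ptv, 1),
    v5_lungpgtv = round(vg$v5, 1), v20_lungpgtv = round(vg$v20, 1),
    mld_lungpgtv = round(mld_pgtv, 1),
    v5_total = round(vt$v5, 1), v20_total = round(vt$v20, 1),
    mld_total = round(mld_total, 1),
    stringsAsFactors = FALSE)

  pars <- lyman_params(config$td50_true, config$m_true)
  cohort$rp2 <- stats::rbinom(n, 1, ntcp_lyman(cohort[[config$rp2_driver]], pars))
  attr(cohort, "config") <- config
  class(cohort) <- c("rp_cohort", "data.frame")
  cohort
}

#' Cohort CSV schema
#'
#' Required column names of a cohort table, in order. This is both the
#' output schema of [simulate_cohort()]/[write_cohort_csv()] and the input
#' schema of [run_analysis()].
#' @return Character vector of column names.
#' @export
cohort_schema <- function() {
  c("id", "age", "gender", "smoking", "pathology", "stage", "chemo",
    "surgery", "pgtv_volume_cm3", "ptv_volume_cm3", "pgtv_rx_gy",
    "ptv_rx_gy", "v5_lungptv", "v20_lungptv", "mld_lungptv", "v5_lungpgtv",
    "v20_lungpgtv", "mld_lungpgtv", "v5_total", "v20_total", "mld_total",
    "rp2")
}

#' Write / read a cohort CSV
#'
#' @param cohort A cohort data.frame with the [cohort_schema()] columns.
#' @param path CSV path.
#' @return `path` (write) or the cohort data.frame (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(as.data.frame(cohort)[, cohort_schema()], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(cohort)
  class(cohort) <- c("rp_cohort", "data.frame")
  cohort
}

#' Validate a cohort table against the schema
#'
#' Checks column presence, outcome coding and per-row metric constraints,
#' reporting every violation with its row and column.
#'
#' @param cohort A data.frame.
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(cohort_schema(), names(cohort))
  if (length(missing_cols))
    stop("cohort table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- character(0)
  if (!all(cohort$rp2 %in% c(0, 1)))
    bad <- c(bad, paste0("rp2 not 0/1 at rows ",
                         paste(utils::head(which(!cohort$rp2 %in% c(0, 1)), 5),
                               collapse = ",")))
  num_cols <- grep("^(v5|v20|mld)_", cohort_schema(), value = TRUE)
  for (cc in num_cols) {
    v <- cohort[[cc]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0))
      bad <- c(bad, paste0(cc, " must be numeric, non-missing, >= 0"))
  }
  for (def in c("lungptv", "lungpgtv", "total")) {
    i <- which(cohort[[paste0("v20_", def)]] >
                 cohort[[paste0("v5_", def)]] + 1e-9)
    if (length(i))
      bad <- c(bad, paste0("v20_", def, " > v5_", def, " at rows ",
                           paste(utils::head(i, 5), collapse = ",")))
  }
  if (length(bad))
    stop("cohort schema violations:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  invisible(TRUE)
}
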