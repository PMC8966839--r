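# Phantom head-CT generator: skull ring, ventricles, unilateral hematoma,
# spatially correlated parenchyma noise, and ICP-coupled bilateral texture
# asymmetry (extra local smoothing in periventricular bands on the
# hemorrhagic side).

.ict_cache <- new.env(parent = emptyenv())

# row-normalized banded Gaussian smoothing matrix (cached)
.gauss_smooth_matrix <- function(n, sigma) {
  key <- sprintf("S_%d_%.6g", n, sigma)
  if (!is.null(.ict_cache[[key]])) return(.ict_cache[[key]])
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  s <- exp(-0.5 * (d / sigma)^2)
  s[d > 4 * sigma] <- 0
  s <- s / rowSums(s)
  .ict_cache[[key]] <- s
  s
}

.smooth2d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  sr <- .gauss_smooth_matrix(nrow(x), sigma)
  sc <- .gauss_smooth_matrix(ncol(x), sigma)
  sr %*% x %*% t(sc)
}

.ellipse_mask <- function(nr, nc, cr, cc, sr, sc) {
  if (sr <= 0 || sc <= 0) return(matrix(FALSE, nr, nc))
  outer(((seq_len(nr) - cr) / sr)^2, ((seq_len(nc) - cc) / sc)^2, "+") <= 1
}

#' Phantom generator parameters
#'
#' Defaults emulate a unilateral supratentorial (basal-ganglia-type)
#' hemorrhage cohort: 256x256 axial grids at 0.5 mm spacing, 12 slices from
#' 0 to 110 mm above the base plane, parenchyma around 30 HU with spatially
#' correlated noise, ventricles at 8 HU, hematoma at 60-80 HU, skull at
#' 1000 HU. Midline shift grows at `midline_shift_gain_mm_per_mmhg` per mmHg
#' above 10 (default 0.4, giving ~6 mm at ICP 25); region texture asymmetry
#' (extra smoothing on the hemorrhagic side) grows with
#' `region_asymmetry_gain[region] * max(0, icp - 20)`.
#'
#' @param grid_size Square grid side in pixels.
#' @param slice_heights_mm Ascending slice heights above the base plane.
#' @param pixel_spacing_mm In-plane pixel spacing.
#' @param slice_thickness_mm Through-plane extent per slice.
#' @param parenchyma_mean_hu,parenchyma_noise_sd,noise_correlation_length_px
#'   Parenchyma texture model.
#' @param ventricle_hu,skull_hu Tissue attenuations.
#' @param hematoma_hu_range Length-2 (low, high) HU of hematoma voxels.
#' @param hematoma_volume_ml Target hematoma volume; 0 disables the hematoma.
#' @param hemorrhagic_side `"left"` or `"right"`.
#' @param icp_mmhg Latent intracranial pressure.
#' @param region_asymmetry_gain Named nonnegative vector over AH/TL/PH.
#' @param asym_sigma_px_per_unit Blur sigma (px) added per unit of
#'   `gain * (icp - 20)`.
#' @param midline_shift_gain_mm_per_mmhg Shift per mmHg above 10.
#' @param ventricle_compression_per_mmhg Fractional shrinkage of the
#'   hemorrhagic-side ventricle per mmHg above 10 (at most 50% total).
#' @param mirror_noise If `TRUE`, the noise field is generated mirror-
#'   symmetric about the midline column (symmetry switch for tests).
#' @param seed Integer seed; generation is deterministic given the params.
#' @return A validated `phantom_params` list.
#' @export
phantom_params <- function(grid_size = 256L,
                           slice_heights_mm = seq(0, 110, by = 10),
                           pixel_spacing_mm = 0.5,
                           slice_thickness_mm = 10,
                           parenchyma_mean_hu = 30,
                           parenchyma_noise_sd = 4,
                           noise_correlation_length_px = 1.5,
                           ventricle_hu = 8,
                           skull_hu = 1000,
                           hematoma_hu_range = c(60, 80),
                           hematoma_volume_ml = 52,
                           hemorrhagic_side = "left",
                           icp_mmhg = 25,
                           region_asymmetry_gain = c(AH = 0.3, TL = 0.3, PH = 1),
                           asym_sigma_px_per_unit = 0.12,
                           midline_shift_gain_mm_per_mmhg = 0.4,
                           ventricle_compression_per_mmhg = 0.015,
                           mirror_noise = FALSE,
                           seed = 1L) {
  p <- list(grid_size = as.integer(grid_size),
            slice_heights_mm = as.numeric(slice_heights_mm),
            pixel_spacing_mm = pixel_spacing_mm,
            slice_thickness_mm = slice_thickness_mm,
            parenchyma_mean_hu = parenchyma_mean_hu,
            parenchyma_noise_sd = parenchyma_noise_sd,
            noise_correlation_length_px = noise_correlation_length_px,
            ventricle_hu = ventricle_hu, skull_hu = skull_hu,
            hematoma_hu_range = hematoma_hu_range,
            hematoma_volume_ml = hematoma_volume_ml,
            hemorrhagic_side = match.arg(hemorrhagic_side, c("left", "right")),
            icp_mmhg = icp_mmhg,
            region_asymmetry_gain = region_asymmetry_gain,
            asym_sigma_px_per_unit = asym_sigma_px_per_unit,
            midline_shift_gain_mm_per_mmhg = midline_shift_gain_mm_per_mmhg,
            ventricle_compression_per_mmhg = ventricle_compression_per_mmhg,
            mirror_noise = isTRUE(mirror_noise),
            seed = as.integer(seed))
  stopifnot(p$grid_size >= 128,
            all(diff(p$slice_heights_mm) > 0),
            p$pixel_spacing_mm > 0, p$slice_thickness_mm > 0,
            p$parenchyma_noise_sd > 0, p$noise_correlation_length_px > 0,
            length(p$hematoma_hu_range) == 2,
            p$hematoma_hu_range[1] < p$hematoma_hu_range[2],
            p$hematoma_volume_ml >= 0, p$icp_mmhg > 0,
            all(c("AH", "TL", "PH") %in% names(p$region_asymmetry_gain)),
            all(p$region_asymmetry_gain >= 0),
            p$midline_shift_gain_mm_per_mmhg >= 0,
            p$ventricle_compression_per_mmhg >= 0)
  if (!(0 <= p$ventricle_hu && p$ventricle_hu < p$parenchyma_mean_hu &&
        p$parenchyma_mean_hu < p$hematoma_hu_range[1]))
    stop("require 0 <= ventricle_hu < parenchyma_mean_hu < hematoma low HU")
  class(p) <- "phantom_params"
  p
}

# fixed in-plane geometry (units: pixels on the 256 grid, scaled by
# grid_size/256 otherwise); midline at integer column grid_size/2
.phantom_geometry <- function(p) {
  g <- p$grid_size / 256
  list(
    mid = as.integer(p$grid_size / 2),
    center_row = 128 * g,
    brain_semi = c(105, 85) * g,
    skull_outer = c(112, 92) * g,
    ventricle_z = c(40, 80),
    lobes = list( # per-side ventricle lobes: center row, |dcol|, semi r, semi c
      anterior_horn  = c(98, 13, 13, 6) * g,
      body           = c(128, 10, 28, 4) * g,
      posterior_horn = c(158, 17, 12, 7) * g
    ),
    hematoma = list(center_row = 128 * g, dcol = 31 * g,
                    semi = c(36, 22) * g, z_center = 55, z_half_max = 70),
    bands = list( # rows, |dcol| range of the periventricular texture bands
      AH = list(rows = c(58, 92) * g,  dcol = c(2, 40) * g),
      TL = list(rows = c(112, 145) * g, dcol = c(52, 84) * g),
      PH = list(rows = c(170, 204) * g, dcol = c(2, 44) * g)
    )
  )
}

#' Default symmetric ROI offsets matching the phantom geometry
#'
#' Offsets are `(row, dcol)`: the hemorrhagic-side patch origin is at
#' `(row, midline + dcol)`; see [place_rois()].
#'
#' @param grid_size Phantom grid size (offsets scale with it).
#' @return Named list over AH/TL/PH of `c(row, dcol)`.
#' @export
phantom_roi_offsets <- function(grid_size = 256L) {
  g <- grid_size / 256
  list(AH = c(row = 63, dcol = 8) * g,
       TL = c(row = 119, dcol = 60) * g,
       PH = c(row = 177, dcol = 8) * g)
}

# correlated, sd-calibrated noise field; optionally mirror-symmetric
.noise_field <- function(nr, nc, sd, corr_len, mid, mirror) {
  x <- matrix(stats::rnorm(nr * nc), nr, nc)
  x <- .smooth2d(x, corr_len)
  x <- x * (sd / stats::sd(as.vector(x)))
  if (mirror) {
    k <- seq_len(min(mid - 1, nc - mid))
    x[, mid - k] <- x[, mid + k]
  }
  x
}

#' Generate one phantom patient
#'
#' Builds the full CT volume plus ground truth. The hemorrhagic side carries
#' an elliptical hematoma; the midline (septum and ventricles) is displaced
#' toward the contralateral side by `gain * max(0, icp - 10)` mm; the
#' hemorrhagic ventricle is compressed with ICP; and within the three
#' periventricular bands on the hemorrhagic side the parenchyma noise is
#' smoothed with strength `region_asymmetry_gain[region] * max(0, icp - 20)`,
#' which is the texture signal the downstream models recover. HU values are
#' rounded to integers, as on a real scanner.
#'
#' @param params A `phantom_params`.
#' @return List with `volume` (`ct_volume`) and `truth` (ground-truth list:
#'   patient_id, icp_mmhg, label_hypertension, per-slice hematoma/ventricle
#'   masks, hematoma_volume_ml, midline_shift_mm, hemorrhagic_side,
#'   midline_col, septum_point, midline landmarks).
#' @export
generate_patient <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  geo <- .phantom_geometry(p)
  n <- p$grid_size
  sgn <- if (p$hemorrhagic_side == "left") -1 else 1
  sp <- p$pixel_spacing_mm

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(p$seed)

  # clamp to a physiologic ceiling so extreme draws keep a valid geometry
  shift_mm <- min(15, p$midline_shift_gain_mm_per_mmhg * max(0, p$icp_mmhg - 10))
  shift_px <- shift_mm / sp
  compress <- 1 - min(0.5, p$ventricle_compression_per_mmhg *
                        max(0, p$icp_mmhg - 10))

  # hematoma ellipsoid: fixed in-plane axes, z half-length from target volume
  hem <- geo$hematoma
  if (p$hematoma_volume_ml > 0) {
    denom <- (4 / 3) * pi * (hem$semi[1] * sp) * (hem$semi[2] * sp)
    z_half <- min(hem$z_half_max, p$hematoma_volume_ml * 1000 / denom)
    if (hem$dcol + hem$semi[2] + 4 > geo$brain_semi[2])
      stop("hematoma does not fit inside the hemicranium")
  } else z_half <- 0

  brain <- .ellipse_mask(n, n, geo$center_row, geo$mid,
                         geo$brain_semi[1], geo$brain_semi[2])
  skull <- .ellipse_mask(n, n, geo$center_row, geo$mid,
                         geo$skull_outer[1], geo$skull_outer[2]) & !brain

  gain <- p$region_asymmetry_gain
  asym_sig <- vapply(c("AH", "TL", "PH"), function(rg)
    p$asym_sigma_px_per_unit * gain[[rg]] * max(0, p$icp_mmhg - 20),
    numeric(1))

  # in-plane ventricle shape is constant over the ventricle z-band
  vm_base <- matrix(FALSE, n, n)
  for (lb in geo$lobes) {
    for (side in c(-1, 1)) {
      f <- if (side == sgn) compress else 1
      vm_base <- vm_base | .ellipse_mask(n, n, lb[1],
                                         geo$mid + side * lb[2] - sgn * shift_px,
                                         lb[3] * f, lb[4] * f)
    }
  }

  slices <- vector("list", length(p$slice_heights_mm))
  hmask <- vmask <- vector("list", length(slices))
  for (k in seq_along(p$slice_heights_mm)) {
    z <- p$slice_heights_mm[k]
    noise <- .noise_field(n, n, p$parenchyma_noise_sd,
                          p$noise_correlation_length_px, geo$mid,
                          p$mirror_noise)
    # hemorrhagic-side periventricular smoothing (the texture asymmetry)
    for (rg in c("AH", "TL", "PH")) {
      if (asym_sig[[rg]] <= 0) next
      b <- geo$bands[[rg]]
      rows <- round(b$rows[1]):round(b$rows[2])
      cols <- sort(geo$mid + sgn * (round(b$dcol[1]):round(b$dcol[2])))
      pad <- 8
      rpad <- max(1, min(rows) - pad):min(n, max(rows) + pad)
      cpad <- max(1, min(cols) - pad):min(n, max(cols) + pad)
      sm <- .smooth2d(noise[rpad, cpad], asym_sig[[rg]])
      ri <- match(rows, rpad); ci <- match(cols, cpad)
      noise[rows, cols] <- sm[ri, ci]
    }

    img <- matrix(-1000, n, n)
    img[skull] <- p$skull_hu
    img[brain] <- p$parenchyma_mean_hu + noise[brain]

    # ventricles, displaced toward the contralateral side, hemorrhagic side
    # compressed
    vm <- if (z >= geo$ventricle_z[1] && z <= geo$ventricle_z[2])
      vm_base else matrix(FALSE, n, n)

    # hematoma cross-section at this height
    hm <- matrix(FALSE, n, n)
    if (z_half > 0) {
      dz <- (z - hem$z_center) / z_half
      if (abs(dz) < 1) {
        sc <- sqrt(1 - dz^2)
        hm <- .ellipse_mask(n, n, hem$center_row, geo$mid + sgn * hem$dcol,
                            hem$semi[1] * sc, hem$semi[2] * sc)
      }
    }
    vm <- vm & brain & !hm
    hm <- hm & brain
    img[vm] <- p$ventricle_hu
    if (any(hm)) img[hm] <- stats::runif(sum(hm), p$hematoma_hu_range[1] + 0.5,
                                         p$hematoma_hu_range[2] - 0.5)
    img <- round(img)
    slices[[k]] <- ct_slice(img, sp, z, sprintf("phantom%06d", p$seed))
    hmask[[k]] <- hm
    vmask[[k]] <- vm
  }

  voxel_ml <- sp * sp * p$slice_thickness_mm / 1000
  truth <- list(
    patient_id = sprintf("phantom%06d", p$seed),
    icp_mmhg = p$icp_mmhg,
    label_hypertension = p$icp_mmhg >= 20,
    hematoma_mask = hmask,
    ventricle_mask = vmask,
    hematoma_volume_ml = sum(vapply(hmask, sum, numeric(1))) * voxel_ml,
    midline_shift_mm = shift_mm,
    hemorrhagic_side = p$hemorrhagic_side,
    midline_col = geo$mid,
    septum_point = c(row = geo$lobes$anterior_horn[1],
                     col = geo$mid - sgn * shift_px),
    anterior_point = c(row = geo$center_row - geo$brain_semi[1] + 2,
                       col = geo$mid),
    posterior_point = c(row = geo$center_row + geo$brain_semi[1] - 2,
                        col = geo$mid)
  )
  list(volume = ct_volume(slices, p$slice_thickness_mm), truth = truth)
}

.derive_seed <- function(seed, i, salt = 0L) {
  as.integer((as.double(seed %% 100003L) * 20011 + i * 7919 +
                salt * 104729) %% 2147483629) + 1L
}

#' Generate a phantom cohort
#'
#' Exactly `round(n * prevalence)` patients are hypertensive (ICP drawn
#' Uniform(20, 40)); the rest are normotensive (Uniform(8, 19)). Hematoma
#' volume is drawn around `20 + 1.3 * ICP` mL when `icp_volume_coupling = 1`
#' (about the study regime: ~52 mL at ICP 25), or around a fixed 52 mL mean
#' when 0. Hemorrhagic side is randomized per patient; per-patient seeds are
#' derived deterministically from the cohort seed.
#'
#' @param n Cohort size (>= 2).
#' @param prevalence Fraction with ICP >= 20, in (0, 1).
#' @param base_params `phantom_params` supplying everything except ICP,
#'   volume, side, and seed.
#' @param seed Cohort seed.
#' @param icp_volume_coupling 1 (default) couples hematoma volume to ICP; 0
#'   decouples it (null cohorts).
#' @return List of per-patient lists as from [generate_patient()].
#' @export
generate_cohort <- function(n, prevalence = 0.68,
                            base_params = phantom_params(), seed = 1L,
                            icp_volume_coupling = 1) {
  stopifnot(n >= 2, prevalence > 0, prevalence < 1)
  n_pos <- round(n * prevalence)
  if (n_pos < 1) stop("n * prevalence < 1: no hypertensive patients possible")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  labels <- sample(rep(c(TRUE, FALSE), c(n_pos, n - n_pos)))
  icp <- ifelse(labels, stats::runif(n, 20, 40), stats::runif(n, 8, 19))
  vol_mean <- if (icp_volume_coupling > 0) 32 + 0.8 * icp else rep(52, n)
  vol <- pmin(90, pmax(15, stats::rnorm(n, vol_mean, 15)))
  side <- sample(c("left", "right"), n, replace = TRUE)
  # anatomical variability: per-patient dispersion of the shift response
  shift_jit <- exp(stats::rnorm(n, 0, 0.4))
  lapply(seq_len(n), function(i) {
    pp <- base_params
    pp$icp_mmhg <- icp[i]
    pp$hematoma_volume_ml <- vol[i]
    pp$hemorrhagic_side <- side[i]
    pp$midline_shift_gain_mm_per_mmhg <-
      base_params$midline_shift_gain_mm_per_mmhg * shift_jit[i]
    pp$seed <- .derive_seed(seed, i)
    generate_patient(pp)
  })
}
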