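# Morphological features: hematoma volume by HU thresholding, midline shift
# as septum-to-midline perpendicular distance, and the ventriculocranial
# ratio (VCR).

# largest 6-connected component of a per-slice list of logical masks,
# by breadth-first frontier expansion over voxel indices
.largest_component_3d <- function(masks) {
  nr <- nrow(masks[[1]]); nc <- ncol(masks[[1]]); ns <- length(masks)
  occ <- array(unlist(masks), dim = c(nr, nc, ns))
  lab <- array(0L, dim = dim(occ))
  nxt <- 1L
  idx_all <- which(occ)
  strides <- c(1L, nr, nr * nc)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    frontier <- start
    lab[start] <- nxt
    while (length(frontier)) {
      coords <- arrayInd(frontier, dim(occ))
      nb <- integer(0)
      for (ax in 1:3) for (dd in c(-1L, 1L)) {
        ok <- coords[, ax] + dd >= 1L & coords[, ax] + dd <= dim(occ)[ax]
        if (!any(ok)) next
        nb <- c(nb, frontier[ok] + dd * strides[ax])
      }
      nb <- unique(nb[occ[nb] & lab[nb] == 0L])
      lab[nb] <- nxt
      frontier <- nb
    }
    nxt <- nxt + 1L
  }
  if (nxt == 1L) return(occ & FALSE)
  sizes <- tabulate(lab[lab > 0L], nbins = nxt - 1L)
  lab == which.max(sizes)
}

#' Hematoma volume by HU-range thresholding
#'
#' Counts voxels whose HU lies in the closed range and multiplies by the
#' voxel volume. Without a seed mask the count is restricted to the largest
#' 6-connected component, which suppresses isolated above-threshold noise
#' voxels; with a seed mask, to voxels inside it.
#'
#' @param volume A `ct_volume`.
#' @param hu_range Closed (low, high) HU range; default `c(50, 90)` for
#'   acute blood.
#' @param seed_mask Optional per-slice list of logical matrices.
#' @return Volume in mL (0, with a warning, when nothing is in range).
#' @export
hematoma_volume <- function(volume, hu_range = c(50, 90), seed_mask = NULL) {
  stopifnot(inherits(volume, "ct_volume"), length(hu_range) == 2,
            hu_range[1] < hu_range[2])
  inr <- lapply(volume$slices, function(s)
    s$pixels >= hu_range[1] & s$pixels <= hu_range[2])
  if (!is.null(seed_mask))
    inr <- Map(function(a, b) a & b, inr, seed_mask)
  n_in <- sum(vapply(inr, sum, numeric(1)))
  if (n_in == 0) {
    warning("no voxels in HU range; hematoma volume reported as 0")
    return(0)
  }
  if (is.null(seed_mask)) {
    comp <- .largest_component_3d(inr)
    n_in <- sum(comp)
  }
  sp <- volume$slices[[1]]$pixel_spacing_mm
  n_in * sp[1] * sp[2] * volume$slice_thickness_mm / 1000
}

#' Midline shift
#'
#' Perpendicular distance, in mm, from the septum pellucidum point to the
#' cranial midline defined by two inner-skull landmarks.
#'
#' @param slice A `ct_slice` (supplies pixel spacing).
#' @param septum_point,anterior_point,posterior_point `(row, col)` pixel
#'   coordinates; the two landmarks must differ.
#' @return Shift in mm.
#' @export
midline_shift <- function(slice, septum_point, anterior_point,
                          posterior_point) {
  stopifnot(inherits(slice, "ct_slice"))
  sp <- slice$pixel_spacing_mm
  a <- c(anterior_point[1] * sp[1], anterior_point[2] * sp[2])
  b <- c(posterior_point[1] * sp[1], posterior_point[2] * sp[2])
  s <- c(septum_point[1] * sp[1], septum_point[2] * sp[2])
  v <- b - a
  if (sqrt(sum(v^2)) < 1e-9) stop("midline landmarks coincide")
  unname(abs(v[1] * (s[2] - a[2]) - v[2] * (s[1] - a[1])) / sqrt(sum(v^2)))
}

#' Ventriculocranial ratio
#'
#' On the measurement slice (about 50 mm above the reference plane), finds
#' the widest row of the ventricle mask within the anterior band and divides
#' the ventricle's horizontal extent there by the inner cranial width on the
#' same row.
#'
#' @param slice A `ct_slice`.
#' @param ventricle_mask Logical matrix on the slice grid.
#' @param cranial_mask Logical matrix marking the inner cranial cavity.
#' @param anterior_band Optional `(row_min, row_max)` restricting the search
#'   to the anterior-horn band; default the anterior half of the mask.
#' @return VCR in `[0, 1]`.
#' @export
ventriculocranial_ratio <- function(slice, ventricle_mask, cranial_mask,
                                    anterior_band = NULL) {
  stopifnot(inherits(slice, "ct_slice"))
  if (!any(ventricle_mask)) stop("ventricle mask is empty on this slice")
  if (!any(cranial_mask)) stop("cranial mask is empty on this slice")
  if (!all(dim(ventricle_mask) == dim(slice$pixels)) ||
      !all(dim(cranial_mask) == dim(slice$pixels)))
    stop("mask shape does not match the slice grid")
  rows_v <- which(rowSums(ventricle_mask) > 0)
  if (is.null(anterior_band)) {
    mid_row <- stats::median(rows_v)
    band <- rows_v[rows_v <= mid_row]
  } else {
    band <- rows_v[rows_v >= anterior_band[1] & rows_v <= anterior_band[2]]
  }
  if (length(band) == 0) stop("no ventricle rows inside the anterior band")
  width_at <- function(mask, r) {
    cc <- which(mask[r, ])
    if (length(cc) == 0) 0L else max(cc) - min(cc) + 1L
  }
  vw <- vapply(band, width_at, integer(1), mask = ventricle_mask)
  r_star <- band[which.max(vw)]
  cw <- width_at(cranial_mask, r_star)
  if (cw == 0) stop("cranial mask empty on the measurement row")
  min(1, max(vw) / cw)
}

#' All three morphological features for a phantom patient
#'
#' @param patient List from [generate_patient()].
#' @param hu_range HU threshold range for the hematoma.
#' @param vcr_height_mm Height of the VCR measurement slice.
#' @return Named numeric vector: `hematoma_volume_ml`, `midline_shift_mm`,
#'   `vcr`.
#' @export
morph_features <- function(patient, hu_range = c(50, 90),
                           vcr_height_mm = 50) {
  vol <- patient$volume; truth <- patient$truth
  hv <- hematoma_volume(vol, hu_range, seed_mask = truth$hematoma_mask)
  sl60 <- select_analysis_slice(vol, 60)
  ms <- midline_shift(sl60, truth$septum_point, truth$anterior_point,
                      truth$posterior_point)
  slv <- select_analysis_slice(vol, vcr_height_mm)
  k <- which(slice_heights(vol) == slv$slice_height_mm)[1]
  cranial <- slv$pixels > -500 & slv$pixels < 500  # inner cavity: not air/bone
  vcr <- ventriculocranial_ratio(slv, truth$ventricle_mask[[k]], cranial)
  c(hematoma_volume_ml = hv, midline_shift_mm = ms, vcr = vcr)
}
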