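# Analysis-slice selection and placement of the six bilateral symmetric
# 20x20 ROIs about the midline column, with HU-window / lesion-overlap
# validation and mirror-preserving repositioning.

ROI_SIZE <- 20L

#' Select the texture-analysis slice
#'
#' Returns the slice whose height is nearest `target_height_mm` (the level
#' of the upper third ventricle, about 60 mm above the reference plane);
#' ties break toward the lower slice.
#'
#' @param volume A `ct_volume`.
#' @param target_height_mm Target height, default 60.
#' @return A `ct_slice`.
#' @export
select_analysis_slice <- function(volume, target_height_mm = 60) {
  stopifnot(inherits(volume, "ct_volume"), length(volume$slices) > 0)
  h <- slice_heights(volume)
  d <- abs(h - target_height_mm)
  volume$slices[[which(d == min(d))[1]]]  # heights ascending: first = lower
}

.roi_patch <- function(slice, origin, region, side) {
  rows <- origin[1]:(origin[1] + ROI_SIZE - 1L)
  cols <- origin[2]:(origin[2] + ROI_SIZE - 1L)
  if (min(rows) < 1 || min(cols) < 1 || max(rows) > nrow(slice$pixels) ||
      max(cols) > ncol(slice$pixels))
    stop(sprintf("ROI %s out of bounds at origin (%d, %d)", region,
                 origin[1], origin[2]))
  structure(list(pixels = slice$pixels[rows, cols],
                 region = region, side = side,
                 origin = c(row = as.integer(origin[1]),
                            col = as.integer(origin[2]))),
            class = "roi_patch")
}

# mirror of origin column about integer midline m for a ROI_SIZE-wide patch:
# pixel column x reflects to 2m - x, so the mirrored origin is
# 2m - (c + ROI_SIZE - 1)
.mirror_origin_col <- function(col, midline_col)
  2L * as.integer(midline_col) - (as.integer(col) + ROI_SIZE - 1L)

#' Place the six bilateral symmetric ROIs
#'
#' For each region (AH, TL, PH) one 20x20 patch is placed with origin
#' `(row, midline_col + dcol)` and its mirror image about `midline_col` on
#' the opposite side; patches are tagged hemorrhagic/contralateral according
#' to `hemorrhagic_side` (left = columns below the midline).
#'
#' @param slice A `ct_slice`.
#' @param midline_col Integer midline column used for reflection.
#' @param region_offsets Named list over AH/TL/PH of `c(row, dcol)` offsets
#'   (see [phantom_roi_offsets()]).
#' @param hemorrhagic_side `"left"` or `"right"`.
#' @return List of 6 `roi_patch` objects (two per region).
#' @export
place_rois <- function(slice, midline_col,
                       region_offsets = phantom_roi_offsets(),
                       hemorrhagic_side = "left") {
  stopifnot(inherits(slice, "ct_slice"),
            all(c("AH", "TL", "PH") %in% names(region_offsets)))
  hemorrhagic_side <- match.arg(hemorrhagic_side, c("left", "right"))
  m <- as.integer(midline_col)
  out <- list()
  for (rg in c("AH", "TL", "PH")) {
    off <- region_offsets[[rg]]
    row <- as.integer(round(off[[1]])); dcol <- as.integer(round(off[[2]]))
    col_right <- m + dcol
    col_left <- .mirror_origin_col(col_right, m)
    side_right <- if (hemorrhagic_side == "right") "hemorrhagic" else "contralateral"
    side_left <- if (hemorrhagic_side == "left") "hemorrhagic" else "contralateral"
    out[[length(out) + 1]] <- .roi_patch(slice, c(row, col_left), rg, side_left)
    out[[length(out) + 1]] <- .roi_patch(slice, c(row, col_right), rg, side_right)
  }
  out
}

#' Validate an ROI against the HU window and lesion masks
#'
#' A patch is valid iff every pixel lies inside the closed HU window and the
#' patch overlaps neither the hematoma nor the ventricle mask.
#'
#' @param patch An `roi_patch`.
#' @param hu_window Closed HU window, default `c(0, 50)`.
#' @param hematoma_mask,ventricle_mask Logical matrices on the slice grid
#'   (or `NULL` to skip that check).
#' @param slice_dim Dimensions of the slice grid (taken from the masks when
#'   given).
#' @return List with `valid` (logical) and `violations` (data.frame of rule,
#'   pixel count).
#' @export
validate_roi <- function(patch, hu_window = c(0, 50), hematoma_mask = NULL,
                         ventricle_mask = NULL, slice_dim = NULL) {
  stopifnot(inherits(patch, "roi_patch"))
  rows <- patch$origin[1]:(patch$origin[1] + ROI_SIZE - 1L)
  cols <- patch$origin[2]:(patch$origin[2] + ROI_SIZE - 1L)
  viol <- data.frame(rule = character(0), count = integer(0))
  n_out <- sum(patch$pixels < hu_window[1] | patch$pixels > hu_window[2])
  if (n_out > 0) viol <- rbind(viol, data.frame(rule = "HU window", count = n_out))
  chk_mask <- function(mask, nm) {
    if (is.null(mask)) return(NULL)
    if (!is.null(slice_dim) && !all(dim(mask) == slice_dim))
      stop("mask shape does not match the slice grid")
    if (max(rows) > nrow(mask) || max(cols) > ncol(mask))
      stop("mask shape does not match the slice grid")
    k <- sum(mask[rows, cols])
    if (k > 0) data.frame(rule = nm, count = k) else NULL
  }
  viol <- rbind(viol, chk_mask(hematoma_mask, "hematoma overlap"),
                chk_mask(ventricle_mask, "ventricle overlap"))
  list(valid = nrow(viol) == 0, violations = viol)
}

#' Reposition an invalid ROI to the nearest valid placement
#'
#' Searches all integer displacements within `search_radius_px` (Euclidean
#' distance of origins, ties broken toward the smaller resulting row, then
#' the smaller column) and returns the nearest valid placement. The same displacement, with its column component
#' mirrored, keeps the paired patch symmetric: apply the returned
#' `displacement` to the mirror patch with `dcol` negated.
#'
#' @param patch An `roi_patch`.
#' @param slice The `ct_slice` it came from.
#' @param hu_window,hematoma_mask,ventricle_mask As [validate_roi()].
#' @param search_radius_px Nonnegative search radius.
#' @return The repositioned `roi_patch` (unchanged if already valid), with a
#'   `displacement` attribute `c(drow, dcol)`.
#' @export
auto_reposition <- function(patch, slice, hu_window = c(0, 50),
                            hematoma_mask = NULL, ventricle_mask = NULL,
                            search_radius_px = 10L) {
  stopifnot(search_radius_px >= 0)
  ok <- function(p) validate_roi(p, hu_window, hematoma_mask, ventricle_mask)$valid
  if (ok(patch)) {
    attr(patch, "displacement") <- c(drow = 0L, dcol = 0L)
    return(patch)
  }
  r <- as.integer(search_radius_px)
  cand <- expand.grid(drow = -r:r, dcol = -r:r)
  cand$d2 <- cand$drow^2 + cand$dcol^2
  cand <- cand[cand$d2 <= r^2 & cand$d2 > 0, ]
  cand <- cand[order(cand$d2, cand$drow, cand$dcol), ]
  for (k in seq_len(nrow(cand))) {
    orig <- patch$origin + c(cand$drow[k], cand$dcol[k])
    if (orig[1] < 1 || orig[2] < 1 ||
        orig[1] + ROI_SIZE - 1L > nrow(slice$pixels) ||
        orig[2] + ROI_SIZE - 1L > ncol(slice$pixels)) next
    p2 <- .roi_patch(slice, orig, patch$region, patch$side)
    if (ok(p2)) {
      attr(p2, "displacement") <- c(drow = cand$drow[k], dcol = cand$dcol[k])
      return(p2)
    }
  }
  stop(sprintf("no valid placement for ROI %s within radius %d",
               patch$region, r))
}

#' Extract validated, mirror-symmetric ROIs from a phantom patient
#'
#' Convenience wrapper: selects the analysis slice, places the six ROIs with
#' the phantom's default offsets about the anatomical midline, validates
#' each against the ground-truth masks, and repositions mirror pairs
#' together when needed.
#'
#' @param patient List from [generate_patient()].
#' @param target_height_mm Analysis-slice height.
#' @param hu_window HU validity window.
#' @param search_radius_px Repositioning radius.
#' @return List of 6 valid `roi_patch` objects.
#' @export
extract_patient_rois <- function(patient, target_height_mm = 60,
                                 hu_window = c(0, 50),
                                 search_radius_px = 12L) {
  vol <- patient$volume; truth <- patient$truth
  sl <- select_analysis_slice(vol, target_height_mm)
  k <- which(slice_heights(vol) == sl$slice_height_mm)[1]
  hm <- truth$hematoma_mask[[k]]; vm <- truth$ventricle_mask[[k]]
  patches <- place_rois(sl, truth$midline_col,
                        phantom_roi_offsets(nrow(sl$pixels)),
                        truth$hemorrhagic_side)
  lapply(patches, function(p) {
    v <- validate_roi(p, hu_window, hm, vm)
    if (v$valid) p else
      auto_reposition(p, sl, hu_window, hm, vm, search_radius_px)
  })
}
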