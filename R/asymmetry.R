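# The bilateral variation-rate statistic: per feature and region,
# R = |(F_hem - F_contra) / F_hem|, then cohort min-max standardization to
# R_new in [0, 1].

VR_EPS <- 1e-12

#' Variation rate between paired feature values
#'
#' `R = |(f_hem - f_contra) / f_hem|`. When both values are numerically zero
#' the asymmetry is taken as 0; when only the hemorrhagic value is zero the
#' ratio is undefined and `NA` is returned (flagged for imputation). R is
#' not clipped and may exceed 1.
#'
#' @param f_hem Feature value on the hemorrhagic side.
#' @param f_contra Feature value on the contralateral side.
#' @return Nonnegative scalar, or `NA` when undefined.
#' @export
variation_rate <- function(f_hem, f_contra) {
  if (!is.finite(f_hem) || !is.finite(f_contra))
    stop("variation_rate requires finite inputs")
  if (abs(f_hem) > VR_EPS) return(abs((f_hem - f_contra) / f_hem))
  if (abs(f_contra) <= VR_EPS) return(0)
  NA_real_
}

#' Build the per-patient, per-region variation-rate table
#'
#' Takes a feature table (one row per patient x region x side, feature
#' columns as from [extract_features()]) and collapses the two sides into
#' one variation rate per feature.
#'
#' @param features data.frame with columns `patient_id`, `region`, `side`
#'   plus the 40 feature columns.
#' @return data.frame with columns `patient_id`, `region`, the 40 feature
#'   columns holding raw R (NA where undefined), and an attribute
#'   `"imputed"`: logical matrix marking undefined cells.
#' @export
variation_rate_table <- function(features) {
  fn <- texture_feature_registry()$name
  stopifnot(all(c("patient_id", "region", "side") %in% names(features)),
            all(fn %in% names(features)))
  key <- paste(features$patient_id, features$region, sep = "\r")
  groups <- split(seq_len(nrow(features)), key)
  keys <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
  fm <- as.matrix(features[, fn])
  rows <- lapply(groups, function(ix) {
    hem <- ix[features$side[ix] == "hemorrhagic"]
    con <- ix[features$side[ix] == "contralateral"]
    if (length(hem) != 1 || length(con) != 1)
      stop(sprintf("need exactly one patch per side for %s/%s",
                   features$patient_id[ix[1]], features$region[ix[1]]))
    vapply(seq_along(fn), function(f)
      variation_rate(fm[hem, f], fm[con, f]), numeric(1))
  })
  r <- as.data.frame(do.call(rbind, rows))
  names(r) <- fn
  out <- cbind(data.frame(patient_id = keys[, 1], region = keys[, 2],
                          stringsAsFactors = FALSE), r)
  rownames(out) <- NULL
  attr(out, "imputed") <- is.na(as.matrix(r))
  out
}

#' Min-max standardize variation rates within region groups
#'
#' Per feature column within each region, maps R to
#' `R_new = (R - Rmin)/(Rmax - Rmin)`. Undefined cells are imputed with the
#' column median first; degenerate columns (Rmax = Rmin) map to 0. With
#' `fit`, the min/max (and medians) of a previously fitted table are applied
#' instead and results are clipped to `[0, 1]` — use this to standardize a
#' test split with training-split statistics.
#'
#' @param vr Table from [variation_rate_table()].
#' @param fit Optional fit object (attribute `"vr_fit"` of a previous call).
#' @return Standardized table (same shape); attributes `"imputed"` and
#'   `"vr_fit"` (per region/feature min, max, median).
#' @export
standardize_variation_rates <- function(vr, fit = NULL) {
  fn <- texture_feature_registry()$name
  regions <- unique(vr$region)
  if (is.null(fit) && length(unique(vr$patient_id)) < 2)
    stop("min-max standardization needs at least 2 patients")
  out <- vr
  newfit <- list()
  for (rg in regions) {
    sel <- vr$region == rg
    for (f in fn) {
      x <- vr[[f]][sel]
      if (is.null(fit)) {
        med <- stats::median(x, na.rm = TRUE)
        x[is.na(x)] <- med
        lo <- min(x); hi <- max(x)
        newfit[[rg]][[f]] <- c(lo = lo, hi = hi, med = med)
      } else {
        st <- fit[[rg]][[f]]
        med <- st[["med"]]; lo <- st[["lo"]]; hi <- st[["hi"]]
        x[is.na(x)] <- med
      }
      y <- if (hi - lo > VR_EPS) (x - lo) / (hi - lo) else rep(0, length(x))
      if (!is.null(fit)) y <- pmin(1, pmax(0, y))
      out[[f]][sel] <- y
    }
  }
  attr(out, "imputed") <- attr(vr, "imputed")
  attr(out, "vr_fit") <- if (is.null(fit)) newfit else fit
  out
}

#' Per-patient feature table from a phantom cohort
#'
#' Extracts the six validated ROIs per patient from the analysis slice and
#' computes the 40 texture features per ROI.
#'
#' @param cohort List from [generate_cohort()].
#' @param bin_width_hu,window Texture discretization settings.
#' @return data.frame: `patient_id`, `region`, `side`, 40 feature columns.
#' @export
cohort_feature_table <- function(cohort, bin_width_hu = 5, window = c(0, 50)) {
  meta <- list(); vals <- list()
  for (pt in cohort) {
    patches <- extract_patient_rois(pt, hu_window = window)
    for (p in patches) {
      meta[[length(meta) + 1]] <- c(pt$truth$patient_id, p$region, p$side)
      vals[[length(vals) + 1]] <- extract_features(
        p, bin_width_hu = bin_width_hu, window = window)
    }
  }
  mm <- do.call(rbind, meta)
  out <- cbind(data.frame(patient_id = mm[, 1], region = mm[, 2],
                          side = mm[, 3], stringsAsFactors = FALSE),
               as.data.frame(do.call(rbind, vals)))
  rownames(out) <- NULL
  out
}
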