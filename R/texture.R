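# Canonical four in-plane directions at unit distance: 0, 45, 90, 135 degrees,
# as (row, col) offsets with rows increasing downwards.
canonical_directions <- function() {
  list(deg0 = c(0L, 1L), deg45 = c(-1L, 1L), deg90 = c(-1L, 0L),
       deg135 = c(-1L, -1L))
}

#' Texture feature registry
#'
#' The 40 second-order texture features computed by the package: 24 from the
#' gray-level co-occurrence matrix (GLCM) and 16 from the gray-level
#' run-length matrix (GLRLM). Canonical names are snake_case with a matrix
#' prefix; `display` gives the conventional human-readable name used in the
#' radiomics literature.
#'
#' @return A data.frame with columns `name` (canonical), `matrix`
#'   (`"glcm"`/`"glrlm"`), and `display`.
#' @export
texture_feature_registry <- function() {
  glcm <- c(
    glcm_autocorrelation        = "Autocorrelation",
    glcm_cluster_prominence     = "Cluster prominence",
    glcm_cluster_shade          = "Cluster shade",
    glcm_cluster_tendency       = "Cluster tendency",
    glcm_contrast               = "Contrast",
    glcm_correlation            = "Correlation",
    glcm_difference_average     = "Difference average",
    glcm_difference_entropy     = "Difference entropy",
    glcm_difference_variance    = "Difference variance",
    glcm_id                     = "Id",
    glcm_idm                    = "Idm",
    glcm_idmn                   = "Idmn",
    glcm_idn                    = "Idn",
    glcm_imc1                   = "Imc1",
    glcm_imc2                   = "Imc2",
    glcm_inverse_variance       = "Inverse variance",
    glcm_joint_average          = "Joint average",
    glcm_joint_energy           = "Joint energy",
    glcm_joint_entropy          = "Joint entropy",
    glcm_mcc                    = "MCC",
    glcm_maximum_probability    = "Maximum probability",
    glcm_sum_average            = "Sum average",
    glcm_sum_entropy            = "Sum entropy",
    glcm_sum_squares            = "Sum squares"
  )
  glrlm <- c(
    glrlm_gray_level_nonuniformity            = "Gray level nonuniformity",
    glrlm_gray_level_nonuniformity_normalized = "Gray level nonuniformity normalized",
    glrlm_gray_level_variance                 = "Gray level variance",
    glrlm_high_gray_level_run_emphasis        = "High gray level run emphasis",
    glrlm_long_run_emphasis                   = "Long run emphasis",
    glrlm_long_run_high_gray_level_emphasis   = "Long run high gray level emphasis",
    glrlm_long_run_low_gray_level_emphasis    = "Long run low gray level emphasis",
    glrlm_low_gray_level_run_emphasis         = "Low gray level run emphasis",
    glrlm_run_entropy                         = "Run entropy",
    glrlm_run_length_nonuniformity            = "Run length nonuniformity",
    glrlm_run_length_nonuniformity_normalized = "Run length nonuniformity normalized",
    glrlm_run_percentage                      = "Run percentage",
    glrlm_run_variance                        = "Run variance",
    glrlm_short_run_emphasis                  = "Short run emphasis",
    glrlm_short_run_high_gray_level_emphasis  = "Short run high gray level emphasis",
    glrlm_short_run_low_gray_level_emphasis   = "Short run low gray level emphasis"
  )
  data.frame(
    name = c(names(glcm), names(glrlm)),
    matrix = rep(c("glcm", "glrlm"), c(length(glcm), length(glrlm))),
    display = unname(c(glcm, glrlm)),
    stringsAsFactors = FALSE
  )
}

#' Discretize an HU patch into gray levels
#'
#' Fixed-bin-width discretization over a closed HU window. Level
#' `floor((hu - low)/bin_width) + 1`, with values equal to the upper window
#' edge assigned to the top bin, so levels run 1..Ng with
#' `Ng = ceiling((high - low)/bin_width)`.
#'
#' @param pixels Numeric matrix of HU values, all inside `window` (inclusive).
#' @param bin_width_hu Positive bin width in HU (default 5).
#' @param window Closed HU window, default `c(0, 50)`.
#' @return A `quantized_patch`: list with `levels` (integer matrix), `ng`,
#'   `bin_width_hu`.
#' @export
quantize_patch <- function(pixels, bin_width_hu = 5, window = c(0, 50)) {
  stopifnot(is.matrix(pixels), bin_width_hu > 0, length(window) == 2,
            window[1] < window[2])
  if (any(!is.finite(pixels))) stop("non-finite HU values in patch")
  if (any(pixels < window[1]) || any(pixels > window[2]))
    stop(sprintf("pixel outside HU window [%g, %g]; validate the ROI first",
                 window[1], window[2]))
  ng <- as.integer(ceiling((window[2] - window[1]) / bin_width_hu))
  lev <- floor((pixels - window[1]) / bin_width_hu) + 1
  lev <- pmin(lev, ng)
  structure(list(levels = matrix(as.integer(lev), nrow(pixels)),
                 ng = ng, bin_width_hu = bin_width_hu),
            class = "quantized_patch")
}

# ordered pixel pairs at offset (dr, dc): returns two integer vectors (from, to)
.pairs_at_offset <- function(levels, dr, dc) {
  nr <- nrow(levels); nc <- ncol(levels)
  r0 <- max(1, 1 - dr):min(nr, nr - dr)
  c0 <- max(1, 1 - dc):min(nc, nc - dc)
  if (length(r0) == 0 || length(c0) == 0 ||
      min(r0) > max(r0) || min(c0) > max(c0)) return(NULL)
  a <- levels[r0, c0, drop = FALSE]
  b <- levels[r0 + dr, c0 + dc, drop = FALSE]
  list(from = as.vector(a), to = as.vector(b))
}

#' Gray-level co-occurrence matrix
#'
#' For each direction, counts ordered level pairs at the given pixel
#' distance, symmetrizes by adding the transpose, and normalizes to a
#' probability matrix; the stored matrix is the average of the per-direction
#' normalized matrices.
#'
#' @param q A `quantized_patch`.
#' @param distance_px Integer pixel distance (default 1).
#' @param directions List of (row, col) offsets; default the four canonical
#'   in-plane directions.
#' @return A `glcm`: list with `p` (Ng x Ng probability matrix), `ng`,
#'   `directions`, `distance_px`.
#' @export
compute_glcm <- function(q, distance_px = 1L,
                         directions = canonical_directions()) {
  stopifnot(inherits(q, "quantized_patch"), distance_px >= 1)
  ng <- q$ng
  mats <- list()
  for (d in directions) {
    pr <- .pairs_at_offset(q$levels, d[1] * distance_px, d[2] * distance_px)
    if (is.null(pr) || length(pr$from) == 0) next
    counts <- tabulate(pr$from + ng * (pr$to - 1L), nbins = ng * ng)
    cmat <- matrix(counts, ng, ng)
    cmat <- cmat + t(cmat)
    mats[[length(mats) + 1]] <- cmat / sum(cmat)
  }
  if (length(mats) == 0)
    stop("patch too small: no pixel pairs in any direction")
  p <- Reduce(`+`, mats) / length(mats)
  structure(list(p = p, ng = ng, directions = directions,
                 distance_px = as.integer(distance_px)),
            class = "glcm")
}

.log2z <- function(x) ifelse(x > 0, log2(x), 0)

#' GLCM texture features
#'
#' Computes the 24 co-occurrence features on a direction-averaged symmetric
#' GLCM. Conventions: logs base 2 with 0*log(0) = 0; Correlation is 0 when
#' the marginal variance vanishes; Imc1/Imc2 are 0 for a degenerate joint
#' entropy; MCC is 1 when only one gray level is present.
#'
#' @param g A `glcm`.
#' @return Named numeric vector of 24 features (canonical `glcm_*` names).
#' @export
glcm_features <- function(g) {
  stopifnot(inherits(g, "glcm"))
  p <- g$p
  ng <- g$ng
  i <- matrix(seq_len(ng), ng, ng)        # row level
  j <- t(i)                               # col level
  px <- rowSums(p)                        # == colSums(p) by symmetry
  py <- colSums(p)
  mu <- sum(i * p)                        # joint average (row-marginal mean)
  sigma2 <- sum((i - mu)^2 * p)

  # difference |i-j| and sum i+j distributions
  dk <- 0:(ng - 1)
  pdiff <- vapply(dk, function(k) sum(p[abs(i - j) == k]), numeric(1))
  sk <- 2:(2 * ng)
  psum <- vapply(sk, function(k) sum(p[(i + j) == k]), numeric(1))

  da <- sum(dk * pdiff)
  sa <- sum(sk * psum)

  hx <- -sum(px * .log2z(px))
  hy <- -sum(py * .log2z(py))
  hxy <- -sum(p * .log2z(p))
  pxpy <- outer(px, py)
  hxy1 <- -sum(p * .log2z(pxpy))
  hxy2 <- -sum(pxpy * .log2z(pxpy))

  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- if (hxy > 0 || hxy2 > hxy) sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))) else 0

  corr <- if (sigma2 > 1e-14) (sum(i * j * p) - mu^2) / sigma2 else 0

  # MCC: second-largest eigenvalue of Q over levels with nonzero marginal
  nz <- which(px > 0)
  mcc <- if (length(nz) <= 1) 1 else {
    psub <- p[nz, nz, drop = FALSE]
    pxs <- px[nz]
    # Q[a,b] = sum_k p[a,k] p[b,k] / (px[a] py[k]); py == px by symmetry
    qm <- matrix(0, length(nz), length(nz))
    for (k in seq_along(nz)) {
      qm <- qm + outer(psub[, k] / pxs, psub[, k] / pxs[k])
    }
    ev <- sort(Re(eigen(qm, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, ev[2]))
  }

  offdiag <- abs(i - j) > 0
  c(
    glcm_autocorrelation     = sum(i * j * p),
    glcm_cluster_prominence  = sum((i + j - 2 * mu)^4 * p),
    glcm_cluster_shade       = sum((i + j - 2 * mu)^3 * p),
    glcm_cluster_tendency    = sum((i + j - 2 * mu)^2 * p),
    glcm_contrast            = sum((i - j)^2 * p),
    glcm_correlation         = corr,
    glcm_difference_average  = da,
    glcm_difference_entropy  = -sum(pdiff * .log2z(pdiff)),
    glcm_difference_variance = sum((dk - da)^2 * pdiff),
    glcm_id                  = sum(p / (1 + abs(i - j))),
    glcm_idm                 = sum(p / (1 + (i - j)^2)),
    glcm_idmn                = sum(p / (1 + (i - j)^2 / ng^2)),
    glcm_idn                 = sum(p / (1 + abs(i - j) / ng)),
    glcm_imc1                = imc1,
    glcm_imc2                = imc2,
    glcm_inverse_variance    = sum(p[offdiag] / (i - j)[offdiag]^2),
    glcm_joint_average       = mu,
    glcm_joint_energy        = sum(p^2),
    glcm_joint_entropy       = hxy,
    glcm_mcc                 = mcc,
    glcm_maximum_probability = max(p),
    glcm_sum_average         = sa,
    glcm_sum_entropy         = -sum(psum * .log2z(psum)),
    glcm_sum_squares         = sigma2
  )
}

# maximal runs along one direction; returns data.frame(level, length)
.runs_in_direction <- function(levels, dr, dc) {
  nr <- nrow(levels); nc <- ncol(levels)
  lines <- if (dr == 0 && dc == 1) {
    split(as.vector(t(levels)), rep(seq_len(nr), each = nc))     # rows, l->r
  } else if (dr == -1 && dc == 0) {
    split(as.vector(levels), rep(seq_len(nc), each = nr))        # cols
  } else if (dr == -1 && dc == 1) {
    ix <- row(levels) + col(levels)                              # anti-diag
    split(as.vector(levels), as.vector(ix))
  } else if (dr == -1 && dc == -1) {
    ix <- row(levels) - col(levels)                              # main diag
    split(as.vector(levels), as.vector(ix))
  } else stop("unsupported direction")
  lv <- integer(0); ln <- integer(0)
  for (x in lines) {
    r <- rle(x)
    lv <- c(lv, r$values)
    ln <- c(ln, r$lengths)
  }
  data.frame(level = lv, length = ln)
}

#' Gray-level run-length matrices
#'
#' Decomposes every maximal collinear run of equal gray levels per direction.
#' Run counts are kept per direction; features are computed per direction and
#' averaged by [glrlm_features()].
#'
#' @param q A `quantized_patch`.
#' @param directions List of (row, col) offsets; default the four canonical
#'   in-plane directions.
#' @return A `glrlm`: list with `r` (list of Ng x Lmax count matrices, one
#'   per direction), `nr` (runs per direction), `np` (pixels), `ng`.
#' @export
compute_glrlm <- function(q, directions = canonical_directions()) {
  stopifnot(inherits(q, "quantized_patch"))
  np <- length(q$levels)
  if (np == 0) stop("empty patch")
  lmax <- max(dim(q$levels))
  rl <- list(); nr <- numeric(0)
  for (nm in names(directions)) {
    d <- directions[[nm]]
    runs <- .runs_in_direction(q$levels, d[1], d[2])
    m <- matrix(tabulate(runs$level + q$ng * (runs$length - 1L),
                         nbins = q$ng * lmax), q$ng, lmax)
    rl[[nm]] <- m
    nr[nm] <- nrow(runs)
  }
  structure(list(r = rl, nr = nr, np = np, ng = q$ng), class = "glrlm")
}

.glrlm_features_one <- function(m, np) {
  nrn <- sum(m)
  ng <- nrow(m); lmax <- ncol(m)
  i <- matrix(seq_len(ng), ng, lmax)
  j <- matrix(seq_len(lmax), ng, lmax, byrow = TRUE)
  ri <- rowSums(m)  # runs per gray level
  rj <- colSums(m)  # runs per length
  p <- m / nrn
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  c(
    glrlm_gray_level_nonuniformity            = sum(ri^2) / nrn,
    glrlm_gray_level_nonuniformity_normalized = sum(ri^2) / nrn^2,
    glrlm_gray_level_variance                 = sum((i - mu_i)^2 * p),
    glrlm_high_gray_level_run_emphasis        = sum(m * i^2) / nrn,
    glrlm_long_run_emphasis                   = sum(m * j^2) / nrn,
    glrlm_long_run_high_gray_level_emphasis   = sum(m * i^2 * j^2) / nrn,
    glrlm_long_run_low_gray_level_emphasis    = sum(m * j^2 / i^2) / nrn,
    glrlm_low_gray_level_run_emphasis         = sum(m / i^2) / nrn,
    glrlm_run_entropy                         = -sum(p * .log2z(p)),
    glrlm_run_length_nonuniformity            = sum(rj^2) / nrn,
    glrlm_run_length_nonuniformity_normalized = sum(rj^2) / nrn^2,
    glrlm_run_percentage                      = nrn / np,
    glrlm_run_variance                        = sum((j - mu_j)^2 * p),
    glrlm_short_run_emphasis                  = sum(m / j^2) / nrn,
    glrlm_short_run_high_gray_level_emphasis  = sum(m * i^2 / j^2) / nrn,
    glrlm_short_run_low_gray_level_emphasis   = sum(m / (i^2 * j^2)) / nrn
  )
}

#' GLRLM texture features
#'
#' The 16 run-length features, computed per direction and averaged across
#' directions. Run percentage is runs/pixels per direction; run entropy uses
#' log base 2 with 0*log(0) = 0.
#'
#' @param m A `glrlm`.
#' @return Named numeric vector of 16 features (canonical `glrlm_*` names).
#' @export
glrlm_features <- function(m) {
  stopifnot(inherits(m, "glrlm"))
  if (any(m$nr < 1)) stop("no runs in some direction (empty patch?)")
  per_dir <- lapply(m$r, .glrlm_features_one, np = m$np)
  Reduce(`+`, per_dir) / length(per_dir)
}

#' Extract the 40 texture features from an ROI patch
#'
#' Quantizes the patch and computes all 24 GLCM + 16 GLRLM features with the
#' package's default conventions (distance 1, four directions, symmetric
#' direction-averaged GLCM).
#'
#' @param patch An `roi_patch` (see [place_rois()]) or a bare HU matrix.
#' @param bin_width_hu Discretization bin width in HU.
#' @param window HU window used for validation and discretization.
#' @param distance_px GLCM pixel distance.
#' @return Named numeric vector of 40 features in registry order.
#' @export
extract_features <- function(patch, bin_width_hu = 5, window = c(0, 50),
                             distance_px = 1L) {
  px <- if (inherits(patch, "roi_patch")) patch$pixels else patch
  q <- quantize_patch(px, bin_width_hu = bin_width_hu, window = window)
  v <- c(glcm_features(compute_glcm(q, distance_px = distance_px)),
         glrlm_features(compute_glrlm(q)))
  v[texture_feature_registry()$name]
}
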