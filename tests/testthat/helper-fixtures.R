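# Small constructors for hand-built volumes and patches used across tests.

make_slice <- function(pixels, height = 0, spacing = 1, id = "t") {
  ct_slice(pixels, spacing, height, id)
}

make_volume <- function(mats, heights = seq_along(mats) - 1, spacing = 1,
                        thickness = 1, id = "t") {
  ct_volume(lapply(seq_along(mats), function(k)
    ct_slice(mats[[k]], spacing, heights[k], id)), thickness)
}

flat_volume <- function(value = 25, n = 40, n_slices = 3, ...) {
  make_volume(replicate(n_slices, matrix(value, n, n), simplify = FALSE), ...)
}

make_patch <- function(pixels, region = "AH", side = "hemorrhagic",
                       origin = c(1L, 1L)) {
  structure(list(pixels = pixels, region = region, side = side,
                 origin = c(row = as.integer(origin[1]),
                            col = as.integer(origin[2]))),
            class = "roi_patch")
}

random_hu_patch <- function(seed, n = 20, lo = 0, hi = 50) {
  set.seed(seed)
  matrix(sample(lo:hi, n * n, replace = TRUE), n, n)
}

quick_phantom <- function(icp = 25, seed = 1, ...) {
  generate_patient(phantom_params(icp_mmhg = icp, seed = seed,
                                  slice_heights_mm = c(50, 60), ...))
}
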