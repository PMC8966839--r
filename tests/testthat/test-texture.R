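# GLCM/GLRLM construction and the 40 features, checked against independent
# brute-force enumeration oracles and closed forms.

test_that("quantization maps HU to levels with inclusive boundary rules", {
  q <- quantize_patch(matrix(25, 4, 4), bin_width_hu = 5)
  expect_equal(unique(as.vector(q$levels)), 6L)  # floor(25/5)+1
  expect_equal(q$ng, 10L)

  edges <- quantize_patch(matrix(c(0, 50, 49.999, 5), 2, 2), bin_width_hu = 5)
  expect_equal(edges$levels[1, 1], 1L)   # lower edge -> first bin
  expect_equal(edges$levels[2, 1], 10L)  # upper edge -> top-bin cap
  expect_equal(edges$levels[1, 2], 10L)
  expect_equal(edges$levels[2, 2], 2L)

  one <- quantize_patch(matrix(c(0, 17, 33, 50), 2, 2), bin_width_hu = 50)
  expect_true(all(one$levels == 1L))

  expect_error(quantize_patch(matrix(51, 2, 2)), "window")
  expect_error(quantize_patch(matrix(-1, 2, 2)), "window")
})

test_that("GLCM of the 2x2 two-level grid matches hand enumeration", {
  q <- quantize_patch(matrix(c(1, 1, 2, 2) * 5 - 3, 2, 2), bin_width_hu = 5)
  # levels [[1,2],[1,2]]: only horizontal pairs (1,2) twice
  g <- compute_glcm(q, directions = list(c(0L, 1L)))
  expect_equal(g$p[1, 2], 0.5)
  expect_equal(g$p[2, 1], 0.5)
  expect_equal(sum(g$p), 1)
  f <- glcm_features(g)
  expect_equal(unname(f["glcm_contrast"]), 1.0)
  expect_equal(unname(f["glcm_joint_energy"]), 0.5)
})

test_that("constant patch yields the degenerate GLCM closed forms", {
  f <- glcm_features(compute_glcm(quantize_patch(matrix(25, 6, 6))))
  expect_equal(unname(f["glcm_joint_energy"]), 1)
  expect_equal(unname(f["glcm_maximum_probability"]), 1)
  expect_equal(unname(f["glcm_contrast"]), 0)
  expect_equal(unname(f["glcm_cluster_shade"]), 0)
  expect_equal(unname(f["glcm_idm"]), 1)
  expect_equal(unname(f["glcm_correlation"]), 0)  # zero marginal variance
  expect_equal(unname(f["glcm_imc1"]), 0)
  expect_equal(unname(f["glcm_imc2"]), 0)
  expect_equal(unname(f["glcm_mcc"]), 1)          # single gray level
})

test_that("GLCM equals the pair-enumeration oracle on random patches", {
  for (seed in 1:20) {
    set.seed(seed)
    m <- matrix(sample(0:50, 64, replace = TRUE), 8, 8)
    q <- quantize_patch(m)
    g <- compute_glcm(q)
    expect_lt(max(abs(g$p - oracle_glcm(q$levels, q$ng))), 1e-12)
    expect_equal(sum(g$p), 1, tolerance = 1e-12)
    expect_equal(g$p, t(g$p))
  }
})

test_that("all 24 GLCM features match the direct-summation oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    m <- matrix(sample(0:50, 64, replace = TRUE), 8, 8)
    q <- quantize_patch(m)
    g <- compute_glcm(q)
    got <- glcm_features(g)
    want <- oracle_glcm_features(g$p)
    expect_equal(got[names(want)], want, tolerance = 1e-9)
  }
})

test_that("GLRLM run decomposition matches the scan-line oracle", {
  # 4x4 constant patch, 0 degrees: four runs of length 4
  q <- quantize_patch(matrix(25, 4, 4))
  m <- compute_glrlm(q, directions = list(deg0 = c(0L, 1L)))
  expect_equal(m$r$deg0[6, 4], 4)
  expect_equal(sum(m$r$deg0), 4)
  expect_equal(unname(m$nr["deg0"]), 4)

  # alternating rows 1,2,1,2...: every horizontal run has length 1
  alt <- matrix(rep(c(2, 7), 10), 4, 20, byrow = TRUE)
  qa <- quantize_patch(alt)
  ma <- compute_glrlm(qa, directions = list(deg0 = c(0L, 1L)))
  expect_equal(sum(ma$r$deg0[, 1]), length(alt))
  expect_equal(unname(ma$nr["deg0"]), length(alt))

  for (seed in 1:10) {
    set.seed(seed)
    m8 <- matrix(sample(0:50, 64, replace = TRUE), 8, 8)
    q8 <- quantize_patch(m8)
    got <- compute_glrlm(q8)
    for (k in seq_along(oracle_dirs)) {
      want <- oracle_glrlm(q8$levels, oracle_dirs[[k]], q8$ng)
      expect_equal(unname(got$r[[k]]), unname(want))
    }
  }
})

test_that("GLRLM pixel conservation holds per direction", {
  for (seed in 1:10) {
    set.seed(seed)
    q <- quantize_patch(matrix(sample(0:50, 100, replace = TRUE), 10, 10))
    m <- compute_glrlm(q)
    for (r in m$r) {
      j <- matrix(seq_len(ncol(r)), nrow(r), ncol(r), byrow = TRUE)
      expect_equal(sum(j * r), m$np)
    }
  }
})

test_that("GLRLM closed forms for constant and alternating patches", {
  q <- quantize_patch(matrix(25, 4, 4))
  m <- compute_glrlm(q, directions = list(deg0 = c(0L, 1L)))
  f <- glrlm_features(m)
  expect_equal(unname(f["glrlm_short_run_emphasis"]), 0.0625)
  expect_equal(unname(f["glrlm_long_run_emphasis"]), 16)
  expect_equal(unname(f["glrlm_run_percentage"]), 0.25)

  alt <- matrix(rep(c(2, 7), 10), 4, 20, byrow = TRUE)
  fa <- glrlm_features(compute_glrlm(quantize_patch(alt),
                                     directions = list(deg0 = c(0L, 1L))))
  expect_equal(unname(fa["glrlm_short_run_emphasis"]), 1)
  expect_equal(unname(fa["glrlm_run_percentage"]), 1)
})

test_that("all 16 GLRLM features match the direct-summation oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    m <- matrix(sample(0:50, 64, replace = TRUE), 8, 8)
    q <- quantize_patch(m)
    got <- glrlm_features(compute_glrlm(q))
    want <- oracle_glrlm_features(q$levels, q$ng)
    expect_equal(got[names(want)], want, tolerance = 1e-9)
  }
})

test_that("extract_features returns the full named 40-feature vector", {
  v <- extract_features(random_hu_patch(1))
  expect_length(v, 40)
  expect_true(all(is.finite(v)))
  expect_equal(sum(startsWith(names(v), "glcm_")), 24)
  expect_equal(sum(startsWith(names(v), "glrlm_")), 16)
  expect_identical(names(v), texture_feature_registry()$name)
  # determinism
  expect_identical(v, extract_features(random_hu_patch(1)))
})

test_that("features are invariant under left-right mirroring of the patch", {
  for (seed in 1:5) {
    m <- random_hu_patch(seed)
    v1 <- extract_features(m)
    v2 <- extract_features(m[, ncol(m):1])
    expect_equal(v1, v2, tolerance = 1e-12)
  }
})

test_that("registry covers the display names used in clinical reporting", {
  reg <- texture_feature_registry()
  expect_equal(nrow(reg), 40)
  expect_equal(sum(reg$matrix == "glcm"), 24)
  expect_equal(sum(reg$matrix == "glrlm"), 16)
  named_in_study <- c(
    "Autocorrelation", "Cluster shade", "Idm", "Joint average",
    "Joint energy", "Maximum probability", "Sum average",
    "Gray level variance", "High gray level run emphasis",
    "Run length nonuniformity", "Short run emphasis",
    "Short run low gray level emphasis", "Cluster prominence", "Id",
    "Gray level nonuniformity", "Long run high gray level emphasis",
    "Run percentage", "Correlation", "Imc1", "Imc2", "MCC", "Sum squares",
    "Long run emphasis", "Run entropy",
    "Run length nonuniformity normalized")
  expect_true(all(named_in_study %in% reg$display))
})
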