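# Independent brute-force oracles: naive scalar loops over pixel pairs,
# runs and score pairs. Deliberately written without reusing any package
# internals so they can certify the vectorized implementations.

oracle_dirs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))

oracle_glcm <- function(levels, ng, directions = oracle_dirs, distance = 1) {
  nr <- nrow(levels); nc <- ncol(levels)
  mats <- list()
  for (d in directions) {
    cmat <- matrix(0, ng, ng)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      r2 <- r + d[1] * distance; c2 <- c + d[2] * distance
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        a <- levels[r, c]; b <- levels[r2, c2]
        cmat[a, b] <- cmat[a, b] + 1
        cmat[b, a] <- cmat[b, a] + 1  # symmetric by construction
      }
    }
    if (sum(cmat) > 0) mats[[length(mats) + 1]] <- cmat / sum(cmat)
  }
  Reduce(`+`, mats) / length(mats)
}

oracle_glcm_features <- function(p) {
  ng <- nrow(p)
  lg2 <- function(x) if (x > 0) log2(x) else 0
  px <- rowSums(p); py <- colSums(p)
  mu <- 0
  for (i in 1:ng) for (j in 1:ng) mu <- mu + i * p[i, j]
  s2 <- 0
  for (i in 1:ng) for (j in 1:ng) s2 <- s2 + (i - mu)^2 * p[i, j]
  acc <- function(f) {
    tot <- 0
    for (i in 1:ng) for (j in 1:ng) tot <- tot + f(i, j, p[i, j])
    tot
  }
  pd <- numeric(ng); ps <- numeric(2 * ng - 1)
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + p[i, j]
  }
  da <- sum((0:(ng - 1)) * pd)
  sa <- sum((2:(2 * ng)) * ps)
  hx <- -sum(sapply(px, function(v) v * lg2(v)))
  hy <- -sum(sapply(py, function(v) v * lg2(v)))
  hxy <- -acc(function(i, j, v) v * lg2(v))
  hxy1 <- -acc(function(i, j, v) v * lg2(px[i] * py[j]))
  hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng)
    hxy2 <- hxy2 - px[i] * py[j] * lg2(px[i] * py[j])
  nz <- which(px > 0)
  mcc <- if (length(nz) <= 1) 1 else {
    q <- matrix(0, length(nz), length(nz))
    for (a in seq_along(nz)) for (b in seq_along(nz)) {
      tot <- 0
      for (k in seq_along(nz))
        tot <- tot + p[nz[a], nz[k]] * p[nz[b], nz[k]] / (px[nz[a]] * py[nz[k]])
      q[a, b] <- tot
    }
    ev <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, ev[2]))
  }
  c(
    glcm_autocorrelation     = acc(function(i, j, v) i * j * v),
    glcm_cluster_prominence  = acc(function(i, j, v) (i + j - 2 * mu)^4 * v),
    glcm_cluster_shade       = acc(function(i, j, v) (i + j - 2 * mu)^3 * v),
    glcm_cluster_tendency    = acc(function(i, j, v) (i + j - 2 * mu)^2 * v),
    glcm_contrast            = acc(function(i, j, v) (i - j)^2 * v),
    glcm_correlation         = if (s2 > 1e-14)
      (acc(function(i, j, v) i * j * v) - mu^2) / s2 else 0,
    glcm_difference_average  = da,
    glcm_difference_entropy  = -sum(sapply(pd, function(v) v * lg2(v))),
    glcm_difference_variance = sum(((0:(ng - 1)) - da)^2 * pd),
    glcm_id                  = acc(function(i, j, v) v / (1 + abs(i - j))),
    glcm_idm                 = acc(function(i, j, v) v / (1 + (i - j)^2)),
    glcm_idmn                = acc(function(i, j, v) v / (1 + (i - j)^2 / ng^2)),
    glcm_idn                 = acc(function(i, j, v) v / (1 + abs(i - j) / ng)),
    glcm_imc1                = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    glcm_imc2                = if (hxy > 0 || hxy2 > hxy)
      sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))) else 0,
    glcm_inverse_variance    = acc(function(i, j, v)
      if (i != j) v / (i - j)^2 else 0),
    glcm_joint_average       = mu,
    glcm_joint_energy        = acc(function(i, j, v) v^2),
    glcm_joint_entropy       = hxy,
    glcm_mcc                 = mcc,
    glcm_maximum_probability = max(p),
    glcm_sum_average         = sa,
    glcm_sum_entropy         = -sum(sapply(ps, function(v) v * lg2(v))),
    glcm_sum_squares         = s2
  )
}

# scan one line with an explicit run loop
oracle_line_runs <- function(x) {
  runs <- list()
  k <- 1
  while (k <= length(x)) {
    j <- k
    while (j < length(x) && x[j + 1] == x[k]) j <- j + 1
    runs[[length(runs) + 1]] <- c(level = x[k], len = j - k + 1)
    k <- j + 1
  }
  do.call(rbind, runs)
}

oracle_glrlm <- function(levels, dir, ng) {
  nr <- nrow(levels); nc <- ncol(levels)
  lines <- list()
  if (all(dir == c(0, 1))) {
    for (r in 1:nr) lines[[r]] <- levels[r, ]
  } else if (all(dir == c(-1, 0))) {
    for (c in 1:nc) lines[[c]] <- levels[, c]
  } else if (all(dir == c(-1, 1))) {
    for (s in 2:(nr + nc)) {
      cells <- c()
      for (r in nr:1) {
        c <- s - r
        if (c >= 1 && c <= nc) cells <- c(cells, levels[r, c])
      }
      if (length(cells)) lines[[length(lines) + 1]] <- cells
    }
  } else if (all(dir == c(-1, -1))) {
    for (s in (1 - nc):(nr - 1)) {
      cells <- c()
      for (r in nr:1) {
        c <- r - s
        if (c >= 1 && c <= nc) cells <- c(cells, levels[r, c])
      }
      if (length(cells)) lines[[length(lines) + 1]] <- cells
    }
  } else stop("unsupported direction")
  m <- matrix(0, ng, max(nr, nc))
  for (ln in lines) {
    runs <- oracle_line_runs(ln)
    for (k in seq_len(nrow(runs)))
      m[runs[k, 1], runs[k, 2]] <- m[runs[k, 1], runs[k, 2]] + 1
  }
  m
}

oracle_glrlm_features_one <- function(m, np) {
  nrn <- sum(m)
  ng <- nrow(m); lm <- ncol(m)
  lg2 <- function(x) if (x > 0) log2(x) else 0
  out <- c(glrlm_gray_level_nonuniformity = 0,
           glrlm_gray_level_nonuniformity_normalized = 0,
           glrlm_gray_level_variance = 0,
           glrlm_high_gray_level_run_emphasis = 0,
           glrlm_long_run_emphasis = 0,
           glrlm_long_run_high_gray_level_emphasis = 0,
           glrlm_long_run_low_gray_level_emphasis = 0,
           glrlm_low_gray_level_run_emphasis = 0,
           glrlm_run_entropy = 0,
           glrlm_run_length_nonuniformity = 0,
           glrlm_run_length_nonuniformity_normalized = 0,
           glrlm_run_percentage = nrn / np,
           glrlm_run_variance = 0,
           glrlm_short_run_emphasis = 0,
           glrlm_short_run_high_gray_level_emphasis = 0,
           glrlm_short_run_low_gray_level_emphasis = 0)
  mu_i <- 0; mu_j <- 0
  for (i in 1:ng) for (j in 1:lm) {
    mu_i <- mu_i + i * m[i, j] / nrn
    mu_j <- mu_j + j * m[i, j] / nrn
  }
  for (i in 1:ng) {
    ri <- sum(m[i, ])
    out["glrlm_gray_level_nonuniformity"] <-
      out["glrlm_gray_level_nonuniformity"] + ri^2 / nrn
  }
  for (j in 1:lm) {
    rj <- sum(m[, j])
    out["glrlm_run_length_nonuniformity"] <-
      out["glrlm_run_length_nonuniformity"] + rj^2 / nrn
  }
  out["glrlm_gray_level_nonuniformity_normalized"] <-
    out["glrlm_gray_level_nonuniformity"] / nrn
  out["glrlm_run_length_nonuniformity_normalized"] <-
    out["glrlm_run_length_nonuniformity"] / nrn
  for (i in 1:ng) for (j in 1:lm) {
    v <- m[i, j]
    if (v == 0) next
    pr <- v / nrn
    out["glrlm_gray_level_variance"] <-
      out["glrlm_gray_level_variance"] + (i - mu_i)^2 * pr
    out["glrlm_run_variance"] <-
      out["glrlm_run_variance"] + (j - mu_j)^2 * pr
    out["glrlm_high_gray_level_run_emphasis"] <-
      out["glrlm_high_gray_level_run_emphasis"] + v * i^2 / nrn
    out["glrlm_low_gray_level_run_emphasis"] <-
      out["glrlm_low_gray_level_run_emphasis"] + v / i^2 / nrn
    out["glrlm_long_run_emphasis"] <-
      out["glrlm_long_run_emphasis"] + v * j^2 / nrn
    out["glrlm_short_run_emphasis"] <-
      out["glrlm_short_run_emphasis"] + v / j^2 / nrn
    out["glrlm_long_run_high_gray_level_emphasis"] <-
      out["glrlm_long_run_high_gray_level_emphasis"] + v * i^2 * j^2 / nrn
    out["glrlm_long_run_low_gray_level_emphasis"] <-
      out["glrlm_long_run_low_gray_level_emphasis"] + v * j^2 / i^2 / nrn
    out["glrlm_short_run_high_gray_level_emphasis"] <-
      out["glrlm_short_run_high_gray_level_emphasis"] + v * i^2 / j^2 / nrn
    out["glrlm_short_run_low_gray_level_emphasis"] <-
      out["glrlm_short_run_low_gray_level_emphasis"] + v / (i^2 * j^2) / nrn
    out["glrlm_run_entropy"] <- out["glrlm_run_entropy"] - pr * lg2(pr)
  }
  out
}

oracle_glrlm_features <- function(levels, ng) {
  per <- lapply(oracle_dirs, function(d)
    oracle_glrlm_features_one(oracle_glrlm(levels, d, ng), length(levels)))
  Reduce(`+`, per) / length(per)
}

# rank-based AUC: concordant pairs + half credit for ties
oracle_auc <- function(prob, pos) {
  ppos <- prob[pos]; pneg <- prob[!pos]
  tot <- 0
  for (a in ppos) for (b in pneg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(ppos) * length(pneg))
}
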