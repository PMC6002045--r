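# Independent oracles and small fixture builders used across the suite.
# Every oracle here recomputes its quantity by a different algorithm than
# the package implementation.

# great-circle distances on the R = 6371 km sphere, straight from the
# haversine formula (no geosphere)
oracle_dist_km <- function(p, q) {
  to_rad <- pi / 180
  dlat <- (q[2] - p[2]) * to_rad
  dlon <- (q[1] - p[1]) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(p[2] * to_rad) * cos(q[2] * to_rad) * sin(dlon / 2)^2
  2 * 6371 * asin(min(1, sqrt(a)))
}

oracle_dist_matrix <- function(pts) {
  n <- nrow(pts)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- oracle_dist_km(pts[i, ], pts[j, ])
  d
}

# maximum subset with all pairwise distances strictly > min_km, by
# exhaustive enumeration (n <= 15)
brute_force_thin_size <- function(pts, min_km) {
  n <- nrow(pts)
  d <- oracle_dist_matrix(pts)
  best <- 1L
  for (code in seq_len(2^n) - 1L) {
    sel <- which(bitwAnd(code, 2^(seq_len(n) - 1L)) > 0)
    if (length(sel) <= best) next
    ok <- TRUE
    for (i in sel) {
      if (any(d[i, setdiff(sel, i)] <= min_km)) { ok <- FALSE; break }
    }
    if (ok) best <- length(sel)
  }
  best
}

# trapezoidal area under the empirical ROC curve
trapezoid_auc <- function(pres, bg) {
  thr <- sort(unique(c(pres, bg, -Inf, Inf)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pres >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(bg >= t), numeric(1))
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# generic L1-penalized Gibbs likelihood maximizer: split lambda = a - b
# with a, b >= 0 and box-constrained L-BFGS-B (a different algorithm from
# the package's coordinate descent)
lbfgs_maxent <- function(presX, bgX, betas) {
  J <- ncol(presX)
  pbar <- colMeans(presX)
  negobj <- function(ab) {
    lam <- ab[1:J] - ab[J + 1:J]
    eta <- as.vector(bgX %*% lam)
    M <- max(eta)
    -(sum(pbar * lam) - (M + log(sum(exp(eta - M)))) -
        sum(betas * (ab[1:J] + ab[J + 1:J])))
  }
  neggrad <- function(ab) {
    lam <- ab[1:J] - ab[J + 1:J]
    eta <- as.vector(bgX %*% lam)
    M <- max(eta)
    q <- exp(eta - M) / sum(exp(eta - M))
    g <- pbar - as.vector(crossprod(bgX, q))
    -c(g - betas, -g - betas)
  }
  fit <- optim(rep(0, 2 * J), negobj, neggrad, method = "L-BFGS-B",
               lower = rep(0, 2 * J),
               control = list(maxit = 5000, factr = 10, pgtol = 1e-12))
  fit$par[1:J] - fit$par[J + 1:J]
}

# exhaustive maximum sensitivity + specificity threshold search
exhaustive_mtsps <- function(pres, bg) {
  pooled <- sort(unique(c(pres, bg)))
  cand <- (pooled[-1] + pooled[-length(pooled)]) / 2
  best_t <- NA_real_
  best_ss <- -Inf
  for (t in cand) {
    ss <- sum(pres >= t) / length(pres) + sum(bg < t) / length(bg)
    if (ss > best_ss + 1e-15) { best_ss <- ss; best_t <- t }
  }
  best_t
}

# tiny unmasked grid filled with a constant
flat_grid <- function(nr = 5, nc = 5, value = 1, origin = c(0, nr),
                      cell = 1, name = "g") {
  ClimateGrid(name, matrix(value, nr, nc), origin, cell)
}

# random small feature-level maxent instance
random_maxent_instance <- function(seed) {
  set.seed(seed)
  J <- sample(2:6, 1)
  n_bg <- sample(50:200, 1)
  n_pr <- sample(10:40, 1)
  bgX <- matrix(runif(n_bg * J), n_bg, J)
  # presences biased toward high values of the first feature
  w <- exp(2 * bgX[, 1])
  rows <- sample(n_bg, n_pr, replace = TRUE, prob = w)
  presX <- bgX[rows, , drop = FALSE]
  betas <- runif(J, 0.005, 0.05)
  list(presX = presX, bgX = bgX, betas = betas)
}

# covariates for a strongly (but not completely) separated
# presence/background instance: presences sit in the top decile of x while
# the background spans [0, 1], so the penalized likelihood stays bounded
separable_instance <- function(n_pres = 30, n_bg = 200, seed = 1, lo = 0.9) {
  set.seed(seed)
  bg <- cbind(x = runif(n_bg, 0, 1), y = runif(n_bg, 0, 1))
  pres <- cbind(x = runif(n_pres, lo, 1), y = runif(n_pres, 0, 1))
  list(pres = pres, bg = bg)
}
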