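# Independent oracles used to freeze expected values. These deliberately use
# naive textbook formulations, not the package's optimized code paths.

# Textbook Kalman predict + update with simple-form covariance update.
oracle_kf_step <- function(x, P, A, Q, H, R, z) {
  xm <- A %*% x
  Pm <- A %*% P %*% t(A) + Q
  S <- as.numeric(H %*% Pm %*% t(H)) + R
  K <- Pm %*% t(H) / S
  xn <- xm + K %*% (z - H %*% xm)
  Pn <- (diag(nrow(P)) - K %*% H) %*% Pm
  list(x = as.numeric(xn), P = Pn, xm = as.numeric(xm), Pm = Pm,
       K = as.numeric(K))
}

# Brute-force matrix power by repeated multiplication.
mat_pow <- function(A, h) {
  out <- diag(nrow(A))
  for (i in seq_len(h)) {
    out <- out %*% A
  }
  out
}

# Lag (in samples) maximizing the cross-correlation of b against a.
oracle_xcorr_lag <- function(a, b, max_lag) {
  lags <- 0:max_lag
  cc <- vapply(lags, function(L) {
    n <- length(a) - L
    sum(a[seq_len(n)] * b[seq_len(n) + L])
  }, numeric(1))
  lags[which.max(cc)]
}

# Simulate directly from the filter's state-space model (matched model):
# x_{k} = A x_{k-1} + w, w ~ N(0, Q), z = H x + v, v ~ N(0, R).
sim_matched_model <- function(n, f = 0.2, dt = 0.01, q0 = 1, r_var = 0.25,
                              sigma2_resp = 25, alpha = 0.01, seed = 1) {
  set.seed(seed)
  A <- kf_transition(f, dt)
  qdiag <- c(q0, (2 * pi * f)^2, alpha * sigma2_resp)
  x <- c(10, 0, 0)
  z <- numeric(n)
  for (k in seq_len(n)) {
    x <- as.numeric(A %*% x) + rnorm(3) * sqrt(qdiag)
    z[k] <- x[1L] + x[3L] + rnorm(1, sd = sqrt(r_var))
  }
  resp_signal(z, dt = dt)
}

# Uniformly random proper rotation via QR decomposition.
rand_rotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) {
    Q[, 1L] <- -Q[, 1L]
  }
  Q
}

# Smallest covariance eigenvalue over every step of a filter trace.
min_P_eigen <- function(fit) {
  min(apply(fit$P, 1, function(p) {
    P <- matrix(c(p[1], p[2], p[3], p[2], p[4], p[5], p[3], p[5], p[6]), 3)
    min(eigen(P, symmetric = TRUE, only.values = TRUE)$values)
  }))
}
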