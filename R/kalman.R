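# Constant-velocity Kalman filter, state (x, y, vx, vy), position-only
# measurements. Time is measured in frames (dt = frame gap).

.kf_init <- function(z, measurement_noise) {
  list(m = c(z[1], z[2], 0, 0),
       P = diag(c(1, 1, 1e4, 1e4)) * measurement_noise)
}

.kf_F <- function(dt) {
  matrix(c(1, 0, 0, 0,
           0, 1, 0, 0,
           dt, 0, 1, 0,
           0, dt, 0, 1), 4, 4)
}

# discrete white-noise-acceleration process covariance (per-axis block form)
.kf_Q <- function(dt, q) {
  Qa <- q * matrix(c(dt^4 / 4, dt^3 / 2, dt^3 / 2, dt^2), 2, 2)
  Q <- matrix(0, 4, 4)
  Q[c(1, 3), c(1, 3)] <- Qa
  Q[c(2, 4), c(2, 4)] <- Qa
  Q
}

.kf_predict <- function(st, dt, q) {
  F <- .kf_F(dt)
  list(m = as.numeric(F %*% st$m),
       P = F %*% st$P %*% t(F) + .kf_Q(dt, q))
}

.kf_update <- function(st, z, r) {
  H <- matrix(c(1, 0, 0, 1, 0, 0, 0, 0), 2, 4)
  S <- H %*% st$P %*% t(H) + diag(2) * r
  K <- st$P %*% t(H) %*% solve(S)
  m <- st$m + as.numeric(K %*% (z - H %*% st$m))
  P <- (diag(4) - K %*% H) %*% st$P
  list(m = m, P = P)
}

# run the filter over a fragment's detection positions; returns the state
# after the last update (frames may have gaps)
.kf_run <- function(frames, x, y, q, r) {
  st <- .kf_init(c(x[1], y[1]), r)
  n <- length(frames)
  if (n > 1) for (k in 2:n) {
    gap <- frames[k] - frames[k - 1]
    for (g in seq_len(gap)) st <- .kf_predict(st, 1, q)
    st <- .kf_update(st, c(x[k], y[k]), r)
  }
  st
}
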