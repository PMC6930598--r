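# Independent oracles used across the suite. These deliberately do not call
# the package's computational kernels.

# plain-R NIPALS PLS1 with autoscaling; predicts newdata for a fixed lv
oracle_pls_predict <- function(X, y, Xnew, lv) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl < 1e-12] <- 1
  E <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  ybar <- mean(y)
  f <- y - ybar
  p <- ncol(E)
  W <- P <- matrix(0, p, lv)
  q <- numeric(lv)
  for (a in seq_len(lv)) {
    w <- drop(crossprod(E, f))
    if (sqrt(sum(w^2)) < 1e-12) { lv <- a - 1; break }
    w <- w / sqrt(sum(w^2))
    t <- drop(E %*% w)
    tt <- sum(t^2)
    pa <- drop(crossprod(E, t)) / tt
    qa <- sum(f * t) / tt
    W[, a] <- w; P[, a] <- pa; q[a] <- qa
    E <- E - tcrossprod(t, pa)
    f <- f - qa * t
  }
  B <- W[, 1:lv, drop = FALSE] %*%
    solve(crossprod(P[, 1:lv, drop = FALSE], W[, 1:lv, drop = FALSE]),
          q[1:lv])
  En <- sweep(sweep(Xnew, 2, ctr), 2, scl, "/")
  drop(En %*% B) + ybar
}

# brute-force leave-one-out predictions by explicit refits
oracle_pls_loo <- function(X, y, lv) {
  vapply(seq_len(nrow(X)), function(i) {
    oracle_pls_predict(X[-i, , drop = FALSE], y[-i],
                       X[i, , drop = FALSE], lv)
  }, numeric(1))
}

# retention time by numerical integration of the migration ODE
# dx/dt = 1 / (t0 (1 + k(phi(t)))) with a fourth-order Runge-Kutta stepper
oracle_lss_ode <- function(logkw, S, run, t_max = 200, dt = 0.002) {
  phi <- function(t) {
    pmin(run$phi0 + pmax(t - run$tD, 0) / run$tG * (run$phiF - run$phi0),
         run$phiF)
  }
  rate <- function(t) 1 / (run$t0 * (1 + 10^(logkw - S * phi(t))))
  t <- 0; x <- 0
  while (x < 1 && t < t_max) {
    k1 <- rate(t); k2 <- rate(t + dt / 2); k4 <- rate(t + dt)
    step <- dt * (k1 + 4 * k2 + k4) / 6
    if (x + step >= 1) return(t + dt * (1 - x) / step)
    x <- x + step
    t <- t + dt
  }
  t
}

# mean raw SRD of the permutation null for a tie-free reference: the
# expected Spearman footrule distance, (n^2 - 1) / 3
footrule_mean <- function(n) (n^2 - 1) / 3

# assemble-and-pretreat shortcut used in many tests
fixture_matrix <- function(kind = NULL) {
  m <- assemble_matrix()
  if (is.null(kind)) m else pretreat(m, kind)
}
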