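# Shared test utilities: finite-difference oracles and small builders.

# central finite difference of f (vector-valued) along coordinate j
fd_partial <- function(f, X, j, h = 1e-6) {
  Xp <- X; Xp[, j] <- Xp[, j] + h
  Xm <- X; Xm[, j] <- Xm[, j] - h
  (f(Xp) - f(Xm)) / (2 * h)
}

# finite-difference gradient of a scalar function of a parameter vector
fd_grad <- function(f, theta, idx = seq_along(theta), h = 1e-6) {
  vapply(idx, function(i) {
    e <- numeric(length(theta)); e[i] <- h
    (f(theta + e) - f(theta - e)) / (2 * h)
  }, numeric(1))
}

# evaluator closures over the analytic cylinder solution, with
# finite-difference first derivatives of the stress components
cylinder_sigma_eval <- function(case, h = 1e-6) {
  function(X) {
    list(sigma = cylinder_stress(X, case),
         grads = lapply(1:2, function(j)
           fd_partial(function(Z) cylinder_stress(Z, case), X, j, h)))
  }
}

cylinder_u_eval <- function(case, h = 1e-6) {
  function(X) {
    g <- lapply(1:2, function(j)
      fd_partial(function(Z) cylinder_displacement(Z, case), X, j, h))
    # columns dux/dx, dux/dy, duy/dx, duy/dy
    list(grad_u = cbind(g[[1]][, 1], g[[2]][, 1], g[[1]][, 2], g[[2]][, 2]))
  }
}

# random admissible deformation gradients near identity
random_F <- function(n, scale = 0.1, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    repeat {
      F <- diag(3) + matrix(rnorm(9, 0, scale), 3, 3)
      if (det(F) > 0.2) return(F)
    }
  })
}

rand_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3))) * sample(c(-1, 1), 1)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / (abs(y) + 1e-300)), tol)
}
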