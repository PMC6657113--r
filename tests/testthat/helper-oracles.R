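# Independent brute-force implementations of the energetics quantities,
# written as plain per-voxel loops straight from the definitions. These are
# deliberately slow and share no code with the package internals; they are
# the reference the vectorized implementation is checked against.

RHO_SI <- 1025      # kg/m^3
MU_DEFAULT <- 4e-3  # Pa.s

naive_kinetic_energy <- function(v, m, spacing_mm, rho = RHO_SI) {
  d <- dim(v)  # nx ny nz nt 3
  dV <- prod(spacing_mm) * 1e-9
  ke <- numeric(d[4])
  for (t in seq_len(d[4]))
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
      if (m[i, j, k, t] == 1)
        ke[t] <- ke[t] + 0.5 * rho * dV * sum(v[i, j, k, t, ]^2)
  ke * 1e3
}

# derivative of component `ci` along axis `ax` at voxel (i,j,k), honouring
# the mask contract: central if both neighbours in mask, one-sided if one,
# zero if none
naive_deriv <- function(v, m, t, ci, ax, i, j, k, h_m) {
  d <- dim(v)
  at <- function(p) {
    if (p[1] < 1 || p[1] > d[1] || p[2] < 1 || p[2] > d[2] ||
        p[3] < 1 || p[3] > d[3]) return(NULL)
    if (m[p[1], p[2], p[3], t] != 1) return(NULL)
    v[p[1], p[2], p[3], t, ci]
  }
  e <- c(0, 0, 0); e[ax] <- 1
  vp <- at(c(i, j, k) + e)
  vm <- at(c(i, j, k) - e)
  v0 <- v[i, j, k, t, ci]
  if (!is.null(vp) && !is.null(vm)) (vp - vm) / (2 * h_m)
  else if (!is.null(vp)) (vp - v0) / h_m
  else if (!is.null(vm)) (v0 - vm) / h_m
  else 0
}

naive_energy_loss <- function(v, m, spacing_mm, mu = MU_DEFAULT) {
  d <- dim(v)
  h <- spacing_mm * 1e-3
  dV <- prod(spacing_mm) * 1e-9
  el <- numeric(d[4])
  for (t in seq_len(d[4]))
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (m[i, j, k, t] != 1) next
      g <- matrix(0, 3, 3)
      for (ci in 1:3) for (ax in 1:3)
        g[ci, ax] <- naive_deriv(v, m, t, ci, ax, i, j, k, h[ax])
      div <- sum(diag(g))
      phi <- 0
      for (ci in 1:3) for (cj in 1:3) {
        term <- g[ci, cj] + g[cj, ci] - (2 / 3) * div * (ci == cj)
        phi <- phi + term^2
      }
      el[t] <- el[t] + mu * dV * 0.5 * phi
    }
  el * 1e3
}

naive_vorticity_vol <- function(v, m, spacing_mm) {
  d <- dim(v)
  h <- spacing_mm * 1e-3
  dV_ml <- prod(spacing_mm) / 1000
  out <- numeric(d[4])
  for (t in seq_len(d[4]))
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (m[i, j, k, t] != 1) next
      g <- matrix(0, 3, 3)
      for (ci in 1:3) for (ax in 1:3)
        g[ci, ax] <- naive_deriv(v, m, t, ci, ax, i, j, k, h[ax])
      w <- c(g[3, 2] - g[2, 3], g[1, 3] - g[3, 1], g[2, 1] - g[1, 2])
      out[t] <- out[t] + sqrt(sum(w^2)) * dV_ml
    }
  out
}

# small random field + blobby random mask for equivalence testing
random_field_and_mask <- function(n = 8, nt = 2, seed = 1) {
  set.seed(seed)
  g <- voxel_grid(n, n, n, dx = 2, dy = 1.5, dz = 2.5, nt = nt)
  v <- array(rnorm(n^3 * nt * 3, sd = 0.5), c(n, n, n, nt, 3))
  m <- array(as.integer(runif(n^3 * nt) > 0.35), c(n, n, n, nt))
  list(field = velocity_field(g, v, venc = 5),
       mask = segmentation_mask(g, m),
       v = v, m = m, spacing = c(2, 1.5, 2.5))
}
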