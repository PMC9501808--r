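# Shared fixtures and independent oracles, built in code.

rand_chi <- function(convention = "axial") {
  v <- stats::runif(5, -5, 5)
  chi_tensor(v[1], v[2], v[3], v[4], v[5], convention = convention)
}

rand_rot <- function() random_rotations(1)[, , 1]

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

# Boltzmann orientational average of fn(b) over field directions b in the
# molecular frame, weighted by the anisotropic-susceptibility energy
# E = -(B0^2 / 2 mu0) b' chi b. Gauss-Legendre in cos(theta), uniform in phi.
# Independent oracle for every alignment-induced observable prefactor.
boltzmann_avg <- function(fn, chi_si, B0, temperature, n_gl = 64, n_phi = 64) {
  kB <- 1.380649e-23
  mu0 <- 1.25663706212e-6
  gl <- pracma::gaussLegendre(n_gl, -1, 1)
  ph <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  num <- 0
  den <- 0
  for (i in seq_len(n_gl)) {
    u <- gl$x[i]
    st <- sqrt(1 - u^2)
    b <- cbind(st * cos(ph), st * sin(ph), rep(u, n_phi))
    E <- -(B0^2 / (2 * mu0)) * rowSums((b %*% chi_si) * b)
    w <- exp(-E / (kB * temperature)) * gl$w[i]
    num <- num + sum(w * fn(b))
    den <- den + sum(w)
  }
  num / den
}

# Small standard scenario shared by several files (memoised per test run).
small_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_scenario(n_fixed = 12, n_mobile = 12, pool_size = 300,
                              planted_size = 3, metals = c("Tb", "Tm", "Yb"),
                              seed = 3)
    }
    cache
  }
})
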