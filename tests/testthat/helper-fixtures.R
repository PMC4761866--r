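# Shared fixtures and independent oracles for the test suite.

ascension <- c(-7.933, -14.367)

# two-epoch pure-dipole coefficient table in the standard text layout
dipole_table_lines <- function() {
  c("# two-epoch dipole fixture",
    "g/h n m 1900.0 1905.0 SV",
    "g 1 0 -30000 -29000 10")
}

# degree-2 fixture with g and h rows and an SV column
degree2_table_lines <- function() {
  c("g/h n m 1990.0 1995.0 2000.0 SV",
    "g 1 0 -29900 -29800 -29700 15.5",
    "g 1 1 -1900 -1850 -1800 10",
    "h 1 1 5400 5350 5300 -20",
    "g 2 0 -2100 -2120 -2140 -4.5",
    "g 2 1 3050 3055 3060 1",
    "h 2 1 -2250 -2300 -2350 -10",
    "g 2 2 1680 1685 1690 1.25",
    "h 2 2 -380 -400 -420 -4")
}

# random Gauss coefficient set to degree 3, reproducible in seed
random_degree3_set <- function(seed = 42, scale = 5000, epoch = 2000) {
  withr::with_seed(seed, {
    g <- matrix(0, 3, 4); h <- matrix(0, 3, 4)
    for (n in 1:3) {
      for (m in 0:n) {
        g[n, m + 1] <- stats::runif(1, -scale, scale)
        if (m > 0) h[n, m + 1] <- stats::runif(1, -scale, scale)
      }
    }
    g[1, 1] <- -30000  # keep a dominant dipole so F never vanishes
    magplume:::new_gauss_set(epoch, g, h)
  })
}

# --- independent synthesis oracle -------------------------------------------
# Evaluates the field elements from the definition of the scalar potential:
# V(r, theta, phi) summed term by term with Schmidt quasi-normalized Legendre
# functions built from an explicit Rodrigues-formula construction, and the
# vector components obtained by Richardson-extrapolated central differences of
# V. Shares no code with the package's recurrence-based synthesis.

# unnormalized associated Legendre P_n^m(x) (no Condon-Shortley phase) from
# repeated symbolic differentiation of the Legendre polynomial
oracle_plm <- function(n, m, x) {
  # P_n(x) coefficients via stats-free explicit construction (Rodrigues)
  # represent polynomial as coefficient vector, differentiate m times
  coefs <- numeric(2 * n + 1)
  for (k in 0:floor(n / 2)) {
    coefs[n - 2 * k + 1] <- (-1)^k * choose(n, k) * choose(2 * n - 2 * k, n) / 2^n
  }
  for (i in seq_len(m)) {
    dc <- numeric(length(coefs) - 1)
    for (p in seq_along(dc)) dc[p] <- coefs[p + 1] * p
    coefs <- dc
  }
  poly <- vapply(x, function(xx) sum(coefs * xx^(seq_along(coefs) - 1)), 0)
  (1 - x^2)^(m / 2) * poly
}

oracle_schmidt <- function(n, m, x) {
  norm <- if (m == 0) 1 else sqrt(2 * factorial(n - m) / factorial(n + m))
  norm * oracle_plm(n, m, x)
}

oracle_potential <- function(coeffs, r, theta, phi, a = 6371.2) {
  V <- 0
  for (n in seq_len(coeffs$max_degree)) {
    for (m in 0:n) {
      g <- coeffs$g[n, m + 1]; h <- coeffs$h[n, m + 1]
      if (g == 0 && h == 0) next
      V <- V + a * (a / r)^(n + 1) *
        (g * cos(m * phi) + h * sin(m * phi)) *
        oracle_schmidt(n, m, cos(theta))
    }
  }
  V
}

# Richardson-extrapolated central difference
rich_diff <- function(f, x, h) {
  d1 <- (f(x + h) - f(x - h)) / (2 * h)
  d2 <- (f(x + h / 2) - f(x - h / 2)) / h
  (4 * d2 - d1) / 3
}

oracle_field <- function(coeffs, lat, lon, a = 6371.2) {
  theta <- (90 - lat) * pi / 180
  phi <- lon * pi / 180
  X <- rich_diff(function(th) oracle_potential(coeffs, a, th, phi), theta,
                 1e-4) / a
  Y <- -rich_diff(function(ph) oracle_potential(coeffs, a, theta, ph), phi,
                  1e-4) / (a * sin(theta))
  Z <- rich_diff(function(r) oracle_potential(coeffs, r, theta, phi), a, 1e-2)
  c(X = X, Y = Y, Z = Z)
}

# uniform velocity field covering a box
uniform_field <- function(u = 0.3, v = 0, lat_range = c(-12, -4),
                          lon_range = c(-19, -10), t_max = 1200) {
  velocity_field(lats = seq(lat_range[1], lat_range[2], length.out = 5),
                 lons = seq(lon_range[1], lon_range[2], length.out = 5),
                 depths = 0, times = c(0, t_max),
                 u = array(u, c(2, 1, 5, 5)), v = array(v, c(2, 1, 5, 5)))
}

# small eddy flow + short schedule used by several dispersal tests
small_plume_run <- function(seed = 1, lifetime_days = 5, n_days = 12,
                            dt = 2, K_h = 10) {
  field <- synth_ocean_field(n_eddies = 3, depths = c(0, 10), n_days = n_days,
                             seed = seed)
  sched <- release_schedule(layer_depths = c(0, 10), per_layer_per_release = 10,
                            lifetime_days = lifetime_days)
  advect(sched, field, dispersion = dispersion_params(K_h = K_h),
         t_end = n_days * 24, dt = dt, seed = seed)
}
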