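# Shared helpers: tiny tables and synthetic pair geometries built in code.

# Observation table of one immune cell at given times/positions plus one
# stationary target.
toy_table <- function(t, x, y, z = 0, target = c(50, 40, 0)) {
  observation_table(rbind(
    data.frame(t = t, x = x, y = y, z = z, id = 1, class = 0),
    data.frame(t = t, x = target[1], y = target[2], z = target[3],
               id = 2, class = 1)))
}

# Build a triplet-target pair data frame directly from angles: incoming
# direction along +x, actual turning angle theta_a, target at angle
# theta_s from the incoming direction at distance rho.
pairs_from_angles <- function(theta_a, theta_s, rho = 10, cell_id = 1) {
  n <- length(theta_a)
  d <- data.frame(cell_id = cell_id, t = seq_len(n), n = 1,
                  px = -1, py = 0, cx = 0, cy = 0,
                  nx = cos(theta_a), ny = sin(theta_a), cz = 0,
                  target_id = 2,
                  tx = rho * cos(theta_s), ty = rho * sin(theta_s), tz = 0)
  d$d <- sqrt(d$tx^2 + d$ty^2)
  attr(d, "r_max") <- max(d$d) + 1
  attr(d, "mode") <- "2d"
  d
}

# High-resolution quadrature oracle for the von Mises arc mass.
vm_mass_quadrature <- function(kappa, a, b) {
  stats::integrate(function(th) dvonmises(th, kappa), a, b,
                   rel.tol = 1e-12, abs.tol = 1e-13,
                   subdivisions = 500L)$value
}
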