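# Shared fixtures: small noiseless generators and independent oracles.

# A single rigid-rotation track about `center` at angular velocity omega,
# built directly (independent of generate_tracks).
rigid_track <- function(omega, r = 20, theta0 = 0.3, n = 6, dt = 0.2,
                        center = c(0, 0), embryo = "E1", track = "T1") {
  th <- theta0 + omega * dt * (0:(n - 1))
  data.frame(embryo_id = embryo, track_id = track, frame = 0:(n - 1),
             x_um = center[1] + r * cos(th), y_um = center[2] + r * sin(th),
             stringsAsFactors = FALSE)
}

default_geom <- function(radius = 30, dt = 0.2) {
  lro_geometry(center = c(0, 0), radius = radius, anterior_axis_angle = pi / 2,
               dt = dt)
}

# Exhaustive-enumeration oracle for the two-sided Fisher exact p-value
# (minimum-likelihood rule), written from the hypergeometric pmf directly.
fisher_enum_p <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  a_min <- max(0, k - n)
  a_max <- min(k, m)
  a_obs <- tab[1, 1]
  pr <- vapply(a_min:a_max, function(a) {
    choose(m, a) * choose(n, k - a) / choose(m + n, k)
  }, numeric(1))
  p_obs <- pr[a_obs - a_min + 1]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p-value by enumerating all group assignments
# (no ties assumed).
mw_enum_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  u_stat <- function(ix) {
    rx <- rank(pooled)[ix]
    sum(rx) - nx * (nx + 1) / 2
  }
  u_obs <- u_stat(seq_len(nx))
  combos <- utils::combn(length(pooled), nx)
  us <- apply(combos, 2, u_stat)
  mu <- nx * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

default_scenarios <- function() {
  list(intervention_scenario("sham"),
       intervention_scenario("3ss", 3),
       intervention_scenario("4ss", 4),
       intervention_scenario("5ss", 5),
       intervention_scenario("6ss", 6),
       intervention_scenario("5+7ss", c(5, 7)))
}
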