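# Independent numerical oracles, deliberately coded on different paths than
# the package (Heun integrator vs the package's RK4 / exact stepping;
# vectorised entropy scorer vs the package's loop; bitmask enumeration vs
# combn).

# Heun (improved Euler) integrator; returns the state at `times` (which must
# be multiples of dt from times[1]).
heun_solve <- function(deriv, y0, times, dt) {
  out <- matrix(NA_real_, length(times), length(y0))
  y <- y0
  out[1, ] <- y
  for (i in seq_len(length(times) - 1L)) {
    t0 <- times[i]; t1 <- times[i + 1L]
    nsub <- max(1L, round((t1 - t0) / dt))
    h <- (t1 - t0) / nsub
    for (s in seq_len(nsub)) {
      tt <- t0 + (s - 1L) * h
      f1 <- deriv(tt, y)
      f2 <- deriv(tt + h, y + h * f1)
      y <- y + h / 2 * (f1 + f2)
    }
    out[i + 1L, ] <- y
  }
  out
}

# Vectorised brute-force Renyi/Shannon class-entropy scorer for one alpha:
# returns the criterion value at every threshold level (index 1 = level 0).
oracle_renyi_scores <- function(counts, alpha) {
  p <- counts / sum(counts)
  L <- length(p)
  sapply(seq_len(L), function(t) {
    p1 <- sum(p[1:t]); p2 <- 1 - p1
    if (p1 <= 0 || p2 <= 0) return(-Inf)
    lo <- p[1:t][p[1:t] > 0] / p1
    hi <- if (t < L) p[(t + 1):L][p[(t + 1):L] > 0] / p2 else numeric(0)
    if (length(hi) == 0) return(-Inf)
    if (alpha == 1) {
      -sum(lo * log(lo)) - sum(hi * log(hi))
    } else {
      (log(sum(lo^alpha)) + log(sum(hi^alpha))) / (1 - alpha)
    }
  })
}

# Exact two-tailed Mann-Whitney p by bitmask enumeration (n1 + n2 <= ~16).
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- c()
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    if (sum(bits) != n1) next
    us <- c(us, sum(r[bits == 1L]) - n1 * (n1 + 1) / 2)
  }
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Protocol-shaped simulation bundle used by several tests.
demo_fdg_world <- function(kin = fdg_kinetics(K1 = 0.1, k2 = 0.15, k3 = 0.05,
                                              vb = 0.1, suppression_factor = 1),
                           kel = 0.015, grid = 0.5) {
  p <- infusion_protocol()
  plasma <- simulate_plasma_curve(p, rate = p$fdg_rate, vd = 150, kel = kel,
                                  grid = grid, label = "plasma_fdg")
  tissue <- simulate_tissue_fdg(plasma, kin)
  list(protocol = p, plasma = plasma, tissue = tissue, kin = kin)
}
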