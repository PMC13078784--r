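# Independent oracles, kept deliberately naive and separate from the package
# implementations they check.

# Decay density by numerical convolution: Gaussian IRF x exponential,
# truncated to [0, W], mixed with uniform background. Quadrature-based;
# shares no code with the package's closed-form density.
oracleDecayDensity <- function(t, tau, m, s, W, b = 0) {
  convOne <- function(tt) {
    if (s <= 0) return(if (tt >= m) exp(-(tt - m) / tau) / tau else 0)
    stats::integrate(function(g) stats::dnorm(g, m, s) *
                       ifelse(tt - g >= 0, exp(-(tt - g) / tau) / tau, 0),
                     lower = m - 8 * s, upper = min(tt, m + 8 * s),
                     rel.tol = 1e-10, stop.on.error = FALSE)$value
  }
  grid <- seq(0, W, length.out = 4001)
  fg <- vapply(grid, convOne, numeric(1))
  Z <- sum((fg[-1] + fg[-length(fg)]) / 2) * diff(grid[1:2])
  sig <- stats::approx(grid, fg, xout = t, rule = 2)$y / Z
  (1 - b) * sig + b / W
}

# Brute-force contact count: explicit double loop with per-pair
# minimum-image displacement.
oracleContactCount <- function(frame, residues, cutoff) {
  lipid <- which(frame@kind == "lipid")
  site <- which(frame@kind == "protein" & !is.na(frame@residueId) &
                  frame@residueId %in% residues)
  n <- 0L
  for (i in lipid) for (j in site) {
    d <- frame@coords[i, ] - frame@coords[j, ]
    if (frame@periodic) d <- d - frame@box * round(d / frame@box)
    if (sum(d^2) < cutoff^2) n <- n + 1L
  }
  n
}

# Minimum distance between two points over all 27 periodic images.
oracleImageDistance <- function(a, b, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- a - (b + c(ix, iy, iz) * box)
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

# Random protein bead table for contact-count fixtures.
randomProteinBeads <- function(n, box, residues) {
  data.frame(residueId = sample(residues, n, replace = TRUE),
             x = runif(n, 0, box[1]), y = runif(n, 0, box[2]),
             z = runif(n, 0, box[3]))
}

# Draw nanotimes from the truncated IRF-convolved decay without using the
# package internals: plain rejection against the window.
oracleDrawNanotimes <- function(n, tau, m, s, W) {
  out <- numeric(0)
  while (length(out) < n) {
    t <- stats::rnorm(2 * n, m, s) + stats::rexp(2 * n, 1 / tau)
    out <- c(out, t[t >= 0 & t <= W])
  }
  out[seq_len(n)]
}
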