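# Independent reference computations used to check the package's results.
# These deliberately avoid the code paths they validate.

# Two-sided normal tail probability via the complementary error function
# (pracma's own erfc implementation, independent of stats::pnorm).
two_sided_p_oracle <- function(z) {
  pracma::erfc(abs(z) / sqrt(2))
}

# Brute-force Benjamini-Hochberg step-up adjustment from the definition:
# q_(i) = min_{j >= i} min(1, p_(j) * m / j), mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(pmin(1, ps[i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Closed-form two-parameter weighted least squares from the normal
# equations, written out as explicit sums.
wls2_oracle <- function(y, x, w) {
  s_w <- sum(w); s_x <- sum(w * x); s_xx <- sum(w * x^2)
  s_y <- sum(w * y); s_xy <- sum(w * x * y)
  det <- s_w * s_xx - s_x^2
  c(intercept = (s_xx * s_y - s_x * s_xy) / det,
    slope = (s_w * s_xy - s_x * s_y) / det)
}

# Reference 2x2 Woolf computation straight from the counts.
woolf_oracle <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  list(beta = log(a * d / (b * c)),
       se = sqrt(1 / a + 1 / b + 1 / c + 1 / d))
}
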