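# Brute-force transliteration of the five ALQFM statistics, written with
# explicit elementwise loops and kept independent of the package internals.
alqfm_oracle <- function(x, y, m_s = 1, m_r = 1) {
  n <- length(x)
  sx <- sy <- sxy <- sx2 <- sy2 <- sr <- sr2 <- 0
  for (i in seq_len(n)) {
    sx <- sx + x[i]
    sy <- sy + y[i]
    sxy <- sxy + x[i] * y[i]
    sx2 <- sx2 + x[i]^2
    sy2 <- sy2 + y[i]^2
    sr <- sr + x[i] / y[i]
    sr2 <- sr2 + (x[i] / y[i])^2
  }
  mx <- sx / n
  my <- sy / n
  num <- dx2 <- dy2 <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx2 <- dx2 + (x[i] - mx)^2
    dy2 <- dy2 + (y[i] - my)^2
  }
  pearson <- num / (sqrt(dx2) * sqrt(dy2))
  s_l <- (pearson + sr / sqrt(n * sr2)) / 2
  b <- (n * sxy - sx * sy) / (n * sy2 - sy^2) * (m_r / m_s) * 100
  r_pct <- sx / sy * (m_r / m_s) * 100
  alpha <- abs(r_pct / b - 1)
  p_l_verbatim <- (pearson * b + sx * sxy / (sy * sqrt(sx2) * sqrt(sy2)) * 100) / 2
  p_l <- (pearson * b +
            sx * sxy / (sy * sqrt(sx2) * sqrt(sy2)) * 100 * (m_r / m_s)) / 2
  list(s_l = s_l, b = b, r = r_pct, alpha = alpha,
       p_l = p_l, p_l_verbatim = p_l_verbatim)
}

# random strictly positive fingerprint vectors for property tests
random_xy <- function(n) {
  list(x = stats::runif(n, 0.1, 100), y = stats::runif(n, 0.1, 100))
}

# small fingerprint_set used across tests
toy_fps <- function() {
  a <- matrix(c(1, 2, 3,
                2, 4, 6,
                3, 6, 9), nrow = 3, byrow = TRUE,
              dimnames = list(c("S1", "S2", "S3"), c("P1", "P2", "P3")))
  b <- matrix(c(5, 1,
                10, 2,
                15, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("S1", "S2", "S3"), c("P1", "P2")))
  fingerprint_set(list(ch1 = a, ch2 = b))
}
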