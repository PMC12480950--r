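# Independent oracle implementations, kept deliberately separate from the
# package code paths: direct transcriptions of the published coefficient
# polynomials and closed forms, evaluated inline.

# Weiss & Price (1980) N2O solubility coefficient K0, mol L-1 atm-1
oracle_wp_k0 <- function(TK, S) {
  exp(-62.7062 + 97.3066 * (100 / TK) + 24.1406 * log(TK / 100) +
        S * (-0.058420 + 0.033193 * (TK / 100) - 0.0051313 * (TK / 100)^2))
}

# Weiss & Price (1980) N2O moist-air equilibrium function F', mol L-1 atm-1
oracle_wp_fprime <- function(TK, S) {
  exp(-165.8806 + 222.8743 * (100 / TK) + 92.0792 * log(TK / 100) -
        1.48425 * (TK / 100)^2 +
        S * (-0.056235 + 0.031619 * (TK / 100) - 0.0048472 * (TK / 100)^2))
}

# Hamme & Emerson (2004) air-saturation concentrations, umol kg-1
oracle_he <- function(TK, S, gas = c("N2", "Ar")) {
  gas <- match.arg(gas)
  a <- switch(gas,
    N2 = c(6.42931, 2.92704, 4.32531, 4.69149,
           -7.44129e-3, -8.02566e-3, -1.46775e-2),
    Ar = c(2.79150, 3.17609, 4.13116, 4.90379,
           -6.96233e-3, -7.66670e-3, -1.16888e-2))
  t <- TK - 273.15
  Ts <- log((298.15 - t) / (273.15 + t))
  exp(a[1] + a[2] * Ts + a[3] * Ts^2 + a[4] * Ts^3 +
        S * (a[5] + a[6] * Ts + a[7] * Ts^2))
}

# forward headspace partition for a known true dissolved concentration
oracle_forward_headspace <- function(cw0, cair, ratio, k0rt) {
  (cw0 + cair * ratio) / (ratio + k0rt)
}

# forward isotope-pairing slopes for known (D, A, FN)
oracle_ipt_forward <- function(d, a, fn) {
  list(p29 = 2 * d * fn * (1 - fn) + a * fn, p30 = d * fn^2)
}

# Benjamini-Hochberg step-up by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# textbook paired-t statistic and two-sided p
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), n - 1))
}
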