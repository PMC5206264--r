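# Independent oracles used across the suite. These never call the code
# paths they check.

# O(n^2) pair enumeration of Kendall's tau-b
tau_b_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tie_x <- tie_y <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- sign(x[j] - x[i])
      b <- sign(y[j] - y[i])
      if (a == 0 && b == 0) {
        # tied in both: contributes to neither denominator term
      } else if (a == 0) {
        tie_x <- tie_x + 1
      } else if (b == 0) {
        tie_y <- tie_y + 1
      } else if (a == b) {
        conc <- conc + 1
      } else {
        disc <- disc + 1
      }
    }
  }
  (conc - disc) / sqrt((conc + disc + tie_x) * (conc + disc + tie_y))
}

# Fine-grid trapezoid of the piecewise-linear interpolant through the
# schedule nodes: what the composite trapezoid rule must equal exactly.
trapz_interp_oracle <- function(lambda, means, n_grid = 1e5) {
  g <- seq(0, 1, length.out = n_grid)
  f <- approx(lambda, means, xout = g)$y
  pracma::trapz(g, f)
}

# Pearson correlation evaluated from the defining covariance formula
pearson_oracle <- function(x, y) {
  mean((x - mean(x)) * (y - mean(y))) / (sqrt(mean((x - mean(x))^2)) * sqrt(mean((y - mean(y))^2)))
}

expect_topology_equal <- function(a, b, tol = 1e-6) {
  expect_equal(a$name, b$name)
  expect_equal(nrow(a$atoms), nrow(b$atoms))
  for (col in c("index", "resnr", "cgnr")) {
    expect_equal(a$atoms[[col]], b$atoms[[col]])
  }
  for (col in c("residue", "atom_name")) {
    expect_equal(a$atoms[[col]], b$atoms[[col]])
  }
  for (col in c("charge", "sigma", "epsilon", "mass")) {
    expect_lt(max(abs(a$atoms[[col]] - b$atoms[[col]])), tol)
  }
  expect_identical(unname(a$passthrough_blocks), unname(b$passthrough_blocks))
}

toy_itp_lines <- function(charges = c(0.5, -0.5), sigmas = c(0.3, 0.25),
                          extra_sections = character(0)) {
  n <- length(charges)
  c("[ atomtypes ]",
    "; name  mass  charge ptype sigma epsilon",
    sprintf("ct%d  12.011  0.0  A  %.7g  0.35", seq_len(n), sigmas),
    "",
    "[ moleculetype ]",
    "TOY  3",
    "",
    "[ atoms ]",
    "; nr type resnr residue atom cgnr charge mass",
    sprintf("%d  ct%d  1  TOY  C%d  %d  %.6f  12.011", seq_len(n), seq_len(n),
            seq_len(n), seq_len(n), charges),
    extra_sections)
}
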