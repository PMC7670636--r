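# Shared fixtures, built once per test file.

# Small noise-free phantom with deterministic geometry. Tube lengths and
# the BG tube count shrink with the grid so that capsules fit inside the
# proportionally smaller basal-ganglia blobs.
cleanPhantom <- function(seed = 3, n_wm = 4L, n_bg = 2L, grid = 64L) {
  if (grid < 48L) n_bg <- 0L
  else if (grid < 64L) n_bg <- min(n_bg, 1L)
  lens <- if (grid >= 64L) c(3, 10) else if (grid >= 48L) c(2.5, 6)
          else c(2, 4.5)
  generatePhantom(phantomSpec(grid_shape = grid, n_tubes_wm = n_wm,
                              n_tubes_bg = n_bg,
                              n_confounders_vent = if (grid >= 48L) 2L
                                                   else 0L,
                              n_confounders_shell = if (grid >= 48L) 3L
                                                    else 0L,
                              tube_length_range_mm = lens, noise_sd = 0,
                              bias_field_amplitude = 0, seed = seed))
}

# Independent double-entered within-pair correlation.
pairCor <- function(X) {
  Z <- rbind(X, X[, c(2, 1), drop = FALSE])
  stats::cor(Z[, 1], Z[, 2])
}

# Independent per-pair bivariate-normal log density sum (2x2), used as the
# likelihood oracle for the univariate twin model.
bruteLoglikUni <- function(a, c_, e, mu, groups) {
  ll <- 0
  for (g in groups) {
    S <- matrix(c(a^2 + c_^2 + e^2, g$r_A * a^2 + c_^2,
                  g$r_A * a^2 + c_^2, a^2 + c_^2 + e^2), 2, 2)
    Si <- solve(S)
    ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
    for (i in seq_len(g$n)) {
      d <- unname(g$X[i, ]) - mu
      ll <- ll - log(2 * pi) - 0.5 * ld - 0.5 * drop(t(d) %*% Si %*% d)
    }
  }
  ll
}

# Independent per-pair 4-dim normal log density sum for the bivariate model.
bruteLoglikBiv <- function(LA, LC, LE, mu, groups) {
  ll <- 0
  for (g in groups) {
    A <- LA %*% t(LA); C <- LC %*% t(LC); E <- LE %*% t(LE)
    W <- A + C + E; X <- g$r_A * A + C
    S <- rbind(cbind(W, X), cbind(X, W))
    Si <- solve(S)
    ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
    mu4 <- c(mu, mu)
    for (i in seq_len(g$n)) {
      d <- unname(g$X[i, ]) - mu4
      ll <- ll - 2 * log(2 * pi) - 0.5 * ld - 0.5 * drop(t(d) %*% Si %*% d)
    }
  }
  ll
}

# One-way single-measure ICC via an explicit stats::aov ANOVA table.
aovICC <- function(x) {
  df <- data.frame(y = c(x[, 1], x[, 2]),
                   unit = factor(rep(seq_len(nrow(x)), 2)))
  tab <- summary(stats::aov(y ~ unit, data = df))[[1]]
  msb <- tab["unit", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  (msb - msw) / (msb + msw)
}

# A stub classifier that always emits a fixed class, for refinement
# contract tests (zero weights, biased output layer).
constantClassifier <- function(cls, side = 8L) {
  m <- initNetwork(networkSpec(input_side = side), seed = 1)
  for (l in 1:4) {
    m$convs[[l]]$W[] <- 0
    m$convs[[l]]$b[] <- 0
  }
  m$fc$W[] <- 0; m$fc$b[] <- 0
  m$out$W[] <- 0
  m$out$b <- c(0, 0, 0)
  m$out$b[cls] <- 10
  m
}
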