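# Univariate ACE family and bivariate Cholesky maximum-likelihood models.

test_that("univariate pair covariance follows the ACE structure", {
  expect_equal(pairCovarianceUni(1, 0, 0, 1), matrix(1, 2, 2))
  # hand arithmetic: 0.9497^2 + 0.1414^2 + 0.2793^2 = 0.99993254,
  # 0.5 * 0.9497^2 + 0.1414^2 = 0.47095901
  S <- pairCovarianceUni(0.9497, 0.1414, 0.2793, 0.5)
  expect_equal(S[1, 1], 0.99993254, tolerance = 1e-7)
  expect_equal(S[1, 2], 0.47095901, tolerance = 1e-7)
  # off-diagonal difference between r_A = 1 and 0.5 equals a^2 / 2
  for (p in list(c(0.8, 0.3, 0.5), c(0.2, 0.9, 0.4))) {
    d <- pairCovarianceUni(p[1], p[2], p[3], 1)[1, 2] -
      pairCovarianceUni(p[1], p[2], p[3], 0.5)[1, 2]
    expect_equal(d, 0.5 * p[1]^2)
  }
})

test_that("model log-likelihood equals the brute-force per-pair oracle", {
  co <- simulateTwinCohort(twinSimSpec(n_mz = 30L, n_dz = 20L, n_nt = 25L,
                                       seed = 77L))
  groups <- pvstwin:::pairData(co, "trait1")
  for (par in list(c(0.9, 0.2, 0.3, 0), c(0.5, 0.5, 0.7, 0.1),
                   c(0.1, 0.8, 0.6, -0.2))) {
    expect_equal(
      pvstwin:::loglikUniStats(par[1], par[2], par[3], par[4], groups),
      bruteLoglikUni(par[1], par[2], par[3], par[4], groups),
      tolerance = 1e-8)
  }
  # bivariate
  LA <- matrix(c(0.8, 0.3, 0, 0.9), 2, 2)
  LC <- matrix(c(0.4, -0.1, 0, 0.3), 2, 2)
  LE <- matrix(c(0.4, 0.05, 0, 0.3), 2, 2)
  cob <- simulateTwinCohort(twinSimSpec(n_mz = 25L, n_dz = 15L, n_nt = 15L,
                                        paths_a = LA, paths_c = LC,
                                        paths_e = LE, seed = 78L))
  gb <- pvstwin:::pairData(cob, c("trait1", "trait2"))
  expect_equal(pvstwin:::loglikBivStats(LA, LC, LE, c(0.1, -0.1), gb),
               bruteLoglikBiv(LA, LC, LE, c(0.1, -0.1), gb),
               tolerance = 1e-8)
})

test_that("ML fit agrees with the Falconer closed form at large n", {
  co <- simulateTwinCohort(twinSimSpec(n_mz = 4000L, n_dz = 2000L,
                                       n_nt = 2000L,
                                       paths_a = sqrt(0.8),
                                       paths_c = sqrt(0.1),
                                       paths_e = sqrt(0.1),
                                       covariate_effects = c(age = 0,
                                                             sex = 0),
                                       seed = 55L))
  fit <- fitUnivariateACE(co, "trait1")
  g <- fit@statistics$groups
  de <- function(X) {
    Z <- rbind(X, X[, 2:1])
    stats::cor(Z[, 1], Z[, 2])
  }
  rmz <- de(g$MZ$X)
  r05 <- de(rbind(g$DZ$X, g$NT$X))
  falc <- c(a2 = 2 * (rmz - r05), c2 = 2 * r05 - rmz, e2 = 1 - rmz)
  v <- varianceComponents(fit) / sum(varianceComponents(fit))
  expect_equal(unname(v), unname(falc), tolerance = 0.03)
  expect_lt(abs(heritability(fit) - 0.8), 0.05)
  expect_true(fit@convergence)
})

test_that("no familial resemblance yields near-zero heritability", {
  co <- simulateTwinCohort(twinSimSpec(paths_a = 0, paths_c = 0,
                                       paths_e = 1, seed = 56L))
  adj <- residualize(co, "trait1", c("age", "sex"))
  expect_lt(heritability(fitUnivariateACE(adj, "trait1")), 0.15)
})

test_that("log-likelihood nesting holds across ACE/AE/CE/E on any dataset", {
  for (s in c(61, 62, 63)) {
    co <- simulateTwinCohort(twinSimSpec(seed = s))
    adj <- residualize(co, "trait1", c("age", "sex"))
    cmp <- compareModels(adj, "trait1")
    ll <- cmp$table$loglik
    names(ll) <- cmp$table$model
    expect_gte(ll["ACE"] + 1e-6, ll["AE"])
    expect_gte(ll["ACE"] + 1e-6, ll["CE"])
    expect_gte(min(ll["AE"], ll["CE"]) + 1e-6, ll["E"])
    expect_true(all(cmp$table$lrt_vs_ace[-1] >= 0))
    expect_equal(cmp$table$aic,
                 -2 * cmp$table$loglik + 2 * c(4, 3, 3, 2))
  }
})

test_that("genetic influence is detected: ACE strongly beats CE when a2 = 0.9", {
  ps <- vapply(1:20, function(i) {
    co <- simulateTwinCohort(twinSimSpec(paths_a = sqrt(0.9),
                                         paths_c = sqrt(0.02),
                                         paths_e = sqrt(0.08),
                                         seed = 8000 + i))
    adj <- residualize(co, "trait1", c("age", "sex"))
    cmp <- compareModels(adj, "trait1")
    cmp$table$p_vs_ace[cmp$table$model == "CE"]
  }, numeric(1))
  expect_gt(mean(ps < 0.001), 0.95)
})

test_that("bivariate pair covariance blocks follow r_A A + C", {
  I2 <- diag(2)
  Z2 <- matrix(0, 2, 2)
  S <- pairCovarianceBiv(I2, Z2, Z2, 1)
  expect_equal(S, rbind(cbind(I2, I2), cbind(I2, I2)))
  set.seed(4)
  for (i in 1:5) {
    LA <- matrix(c(abs(rnorm(1)), rnorm(1), 0, abs(rnorm(1))), 2, 2)
    LC <- matrix(c(abs(rnorm(1)), rnorm(1), 0, abs(rnorm(1))), 2, 2)
    LE <- matrix(c(abs(rnorm(1)) + 0.2, rnorm(1), 0,
                   abs(rnorm(1)) + 0.2), 2, 2)
    S1 <- pairCovarianceBiv(LA, LC, LE, 1)
    S5 <- pairCovarianceBiv(LA, LC, LE, 0.5)
    expect_true(all(eigen(S1, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-10))
    expect_equal(S1[1:2, 3:4] - S5[1:2, 3:4], 0.5 * LA %*% t(LA))
  }
})

test_that("genetic correlation: analytic cases and A-matrix equivalence", {
  mkL <- function(a11, a12, a22) matrix(c(a11, a12, 0, a22), 2, 2)
  expect_equal(geneticCorrelation(mkL(0.8, 0, 0.9)), 0)
  expect_equal(geneticCorrelation(mkL(0.8, 0.5, 0)), 1)
  expect_true(is.na(geneticCorrelation(mkL(0.8, 0, 0))))
  expect_equal(geneticCorrelation(mkL(0.8112, 0.2850, 0.9064)), 0.30,
               tolerance = 5e-4)
  set.seed(5)
  for (i in 1:10) {
    L <- mkL(abs(rnorm(1)) + 0.1, rnorm(1), abs(rnorm(1)) + 0.1)
    A <- L %*% t(L)
    expect_equal(geneticCorrelation(L), A[1, 2] / sqrt(A[1, 1] * A[2, 2]),
                 tolerance = 1e-12)
  }
})

test_that("shared heritability: analytic cases, absolute-value convention", {
  sh <- function(...) sharedHeritability(c(...))
  expect_equal(as.numeric(sh(a11 = 0.8, a12 = 0.4, c11 = 0.5, c12 = 0,
                             e11 = 0.3, e12 = 0)), 1)
  expect_equal(as.numeric(sh(a11 = 0.8, a12 = 0, c11 = 0.5, c12 = 0.2,
                             e11 = 0.3, e12 = 0.1)), 0)
  expect_true(is.na(sh(a11 = 0.8, a12 = 0, c11 = 0.5, c12 = 0,
                       e11 = 0.3, e12 = 0)))
  expect_equal(as.numeric(sh(a11 = 0.8112, a12 = 0.2850, c11 = 0.4,
                             c12 = 0.06, e11 = 0.4266, e12 = 0.05634)),
               0.828, tolerance = 2e-3)
  # negative cross paths: unsigned value in [0,1], signed variant recorded
  s <- sh(a11 = 0.8, a12 = 0.3, c11 = 0.5, c12 = -0.2, e11 = 0.3,
          e12 = 0.1)
  expect_true(as.numeric(s) >= 0 && as.numeric(s) <= 1)
  expect_false(is.null(attr(s, "signed")))
})

test_that("bivariate fit recovers strong cross-trait structure", {
  LA <- matrix(c(0.8112, 0.2850, 0, 0.9064), 2, 2)
  LC <- matrix(c(0.4, 0.06, 0, 0.30), 2, 2)
  LE <- matrix(c(0.4266, 0.05634, 0, 0.28), 2, 2)
  co <- simulateTwinCohort(twinSimSpec(n_mz = 2000L, n_dz = 1000L,
                                       n_nt = 1000L, paths_a = LA,
                                       paths_c = LC, paths_e = LE,
                                       covariate_effects = c(age = 0,
                                                             sex = 0),
                                       seed = 90L))
  fit <- fitBivariateACE(co, c("trait1", "trait2"))
  expect_true(fit@convergence)
  expect_equal(geneticCorrelation(fit), 0.30, tolerance = 0.05)
  expect_equal(as.numeric(sharedHeritability(fit)), 0.828,
               tolerance = 0.08)
  # two independent traits: fitted genetic correlation near zero
  co0 <- simulateTwinCohort(twinSimSpec(n_mz = 1000L, n_dz = 500L,
                                        n_nt = 500L,
                                        paths_a = diag(c(0.9, 0.9)),
                                        paths_c = diag(c(0.2, 0.2)),
                                        paths_e = diag(c(0.37, 0.37)),
                                        covariate_effects = c(age = 0,
                                                              sex = 0),
                                        seed = 91L))
  fit0 <- fitBivariateACE(co0, c("trait1", "trait2"))
  expect_lt(abs(geneticCorrelation(fit0)), 0.1)
})

test_that("heritability estimates are scale invariant", {
  co <- simulateTwinCohort(twinSimSpec(seed = 92L))
  f1 <- fitUnivariateACE(co, "trait1")
  co2 <- co
  co2$trait1 <- co2$trait1 * 7.3
  f2 <- fitUnivariateACE(co2, "trait1")
  expect_equal(heritability(f1), heritability(f2), tolerance = 1e-4)
})

test_that("profile intervals contain the estimate and tighten with information", {
  co <- simulateTwinCohort(twinSimSpec(seed = 93L))
  adj <- residualize(co, "trait1", c("age", "sex"))
  fit <- fitUnivariateACE(adj, "trait1")
  ci <- confidenceInterval(fit, "h2")
  expect_lte(ci[1], heritability(fit))
  expect_gte(ci[2], heritability(fit))
  # ten-fold more DZ pairs: narrower interval, other counts fixed
  cbig <- simulateTwinCohort(twinSimSpec(n_dz = 790L, seed = 93L))
  abig <- residualize(cbig, "trait1", c("age", "sex"))
  cibig <- confidenceInterval(fitUnivariateACE(abig, "trait1"), "h2")
  expect_lt(diff(cibig), diff(ci))
  # bivariate rg interval brackets its estimate
  LA <- matrix(c(0.8, 0.3, 0, 0.9), 2, 2)
  cob <- simulateTwinCohort(twinSimSpec(paths_a = LA,
                                        paths_c = diag(c(0.3, 0.3)),
                                        paths_e = diag(c(0.45, 0.3)),
                                        seed = 94L))
  a1 <- residualize(cob, "trait1", c("age", "sex"))
  a2 <- residualize(a1, "trait2", c("age", "sex"))
  fb <- fitBivariateACE(a2, c("trait1", "trait2"))
  cib <- confidenceInterval(fb, "rg")
  expect_lte(cib[1], geneticCorrelation(fb))
  expect_gte(cib[2], geneticCorrelation(fb))
})

test_that("incomplete pairs are dropped with a message; identifiability is enforced", {
  co <- simulateTwinCohort(twinSimSpec(seed = 95L))
  co$trait1[1] <- NA
  expect_message(f <- fitUnivariateACE(co, "trait1"), "dropped")
  expect_equal(sum(f@npairs), 349L)
  solo <- co[co$group == "MZ", ]
  expect_error(fitUnivariateACE(solo, "trait1"), "identifiability")
})
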