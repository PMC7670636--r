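#' Expected pair covariance under the univariate ACE model
#'
#' The 2x2 covariance matrix of a trait measured on both members of a pair:
#' diagonal a^2 + c^2 + e^2, off-diagonal r_A * a^2 + c^2, where the
#' additive-genetic correlation r_A is 1 for MZ pairs and 0.5 for DZ twins
#' and non-twin siblings, and the shared environment contributes fully
#' within every pair.
#'
#' @param a,c,e nonnegative path coefficients.
#' @param r_A additive-genetic relatedness of the pair.
#' @return a 2x2 covariance matrix.
#' @export
pairCovarianceUni <- function(a, c, e, r_A) {
  v <- a^2 + c^2 + e^2
  cv <- r_A * a^2 + c^2
  matrix(c(v, cv, cv, v), 2, 2)
}

#' Expected pair covariance under the bivariate Cholesky ACE model
#'
#' The 4x4 covariance of two traits on two pair members, ordered
#' (member1-trait1, member1-trait2, member2-trait1, member2-trait2).
#' The within-person block is A + C + E and the cross-person block is
#' r_A * A + C, with A = L_A L_A' etc. Positive semidefinite by
#' construction.
#'
#' @param LA,LC,LE 2x2 lower-triangular path matrices (nonnegative
#'   diagonals).
#' @param r_A additive-genetic relatedness.
#' @return a 4x4 covariance matrix.
#' @export
pairCovarianceBiv <- function(LA, LC, LE, r_A) {
  A <- LA %*% t(LA); C <- LC %*% t(LC); E <- LE %*% t(LE)
  W <- A + C + E
  X <- r_A * A + C
  rbind(cbind(W, X), cbind(X, W))
}

# ---- internal: pair reshaping and sufficient statistics -------------------

# Reshape a cohort into per-group pair matrices: columns (m1 traits...,
# m2 traits...). Incomplete pairs are dropped with a message.
pairData <- function(cohort, traits) {
  need <- c("family_id", "member", "group", traits)
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort table lacks columns: ", paste(miss, collapse = ", "))
  ok <- stats::complete.cases(cohort[traits])
  keep_fam <- names(which(tapply(ok, cohort$family_id, all)))
  two_fam <- names(which(table(cohort$family_id) == 2L))
  fams <- intersect(keep_fam, two_fam)
  dropped <- length(unique(cohort$family_id)) - length(fams)
  if (dropped > 0L)
    message(dropped, " incomplete pair(s) dropped")
  sub <- cohort[cohort$family_id %in% fams, ]
  sub <- sub[order(sub$family_id, sub$member), ]
  # first and second row per family after ordering by member
  first <- !duplicated(sub$family_id)
  m1 <- sub[first, , drop = FALSE]
  m2 <- sub[!first, , drop = FALSE]
  stopifnot(identical(m1$family_id, m2$family_id))
  groups <- m1$group
  out <- list()
  for (g in c("MZ", "DZ", "NT")) {
    sel <- groups == g
    if (!any(sel)) next
    X <- cbind(as.matrix(m1[sel, traits, drop = FALSE]),
               as.matrix(m2[sel, traits, drop = FALSE]))
    colnames(X) <- c(paste0("m1_", traits), paste0("m2_", traits))
    out[[g]] <- list(X = X, n = sum(sel),
                     r_A = if (g == "MZ") 1 else 0.5,
                     S = crossprod(X), s = colSums(X))
  }
  if (length(out) < 2L || !"MZ" %in% names(out))
    stop("need MZ pairs plus at least one r_A = 0.5 group for ",
         "identifiability of a vs c")
  out
}

# Univariate Gaussian pair log-likelihood from sufficient statistics.
loglikUniStats <- function(a, c, e, mu, groups) {
  v <- a^2 + c^2 + e^2
  ll <- 0
  for (g in groups) {
    cv <- g$r_A * a^2 + c^2
    det <- v^2 - cv^2
    if (det <= 0 || v <= 0) return(-Inf)
    s1 <- unname(g$s[1]); s2 <- unname(g$s[2])
    M11 <- g$S[1, 1] - 2 * mu * s1 + g$n * mu^2
    M22 <- g$S[2, 2] - 2 * mu * s2 + g$n * mu^2
    M12 <- g$S[1, 2] - mu * (s1 + s2) + g$n * mu^2
    tr <- (v * (M11 + M22) - 2 * cv * M12) / det
    ll <- ll + (-g$n * log(2 * pi) - g$n / 2 * log(det) - tr / 2)
  }
  ll
}

# Bivariate (4-dim) Gaussian pair log-likelihood from sufficient statistics.
loglikBivStats <- function(LA, LC, LE, mu, groups) {
  ll <- 0
  mu4 <- c(mu, mu)
  for (g in groups) {
    Sg <- pairCovarianceBiv(LA, LC, LE, g$r_A)
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    logdet <- 2 * sum(log(diag(ch)))
    M <- g$S - outer(mu4, g$s) - outer(g$s, mu4) + g$n * outer(mu4, mu4)
    tr <- sum(diag(chol2inv(ch) %*% M))
    ll <- ll + (-2 * g$n * log(2 * pi) - g$n / 2 * logdet - tr / 2)
  }
  ll
}

# Double-entered within-pair correlation and variance for moment starts.
doubleEntered <- function(X) {
  Z <- rbind(X, X[, c(2, 1), drop = FALSE])
  list(r = stats::cor(Z[, 1], Z[, 2]), v = stats::var(as.vector(X)),
       m = mean(X))
}

#' Fit a univariate twin variance-component model by maximum likelihood
#'
#' Maximizes the sum over pairs of the bivariate-normal log density with
#' group-specific pair covariance ([pairCovarianceUni()]) and a single
#' shared mean. Paths are constrained nonnegative; dropped components are
#' fixed at zero for the AE/CE/E submodels. Optimization is bounded
#' quasi-Newton from a moment-based (Falconer) start plus a fixed lattice
#' of variance-share starts; the best likelihood wins, so the fit is
#' deterministic given the data.
#'
#' @param cohort a cohort data.frame with `family_id`, `member`, `group`
#'   and the trait column; DZ and NT pairs enter as separate groups sharing
#'   r_A = 0.5.
#' @param trait name of the (already adjusted/standardized) trait column.
#' @param model one of "ACE", "AE", "CE", "E".
#' @return an [ACEFit-class].
#' @export
fitUnivariateACE <- function(cohort, trait, model = c("ACE", "AE", "CE",
                                                      "E")) {
  model <- match.arg(model)
  groups <- pairData(cohort, trait)
  de_mz <- doubleEntered(groups$MZ$X)
  X05 <- do.call(rbind, lapply(groups[setdiff(names(groups), "MZ")],
                               function(g) g$X))
  de_05 <- doubleEntered(X05)
  vemp <- stats::var(as.vector(do.call(rbind, lapply(groups, `[[`, "X"))))
  memp <- mean(do.call(rbind, lapply(groups, `[[`, "X")))

  # Falconer moment start + lattice of variance shares
  a2f <- min(max(2 * (de_mz$r - de_05$r), 0.01), 0.95)
  c2f <- min(max(2 * de_05$r - de_mz$r, 0.01), 0.95)
  e2f <- max(1 - a2f - c2f, 0.05)
  shares <- rbind(c(a2f, c2f, e2f) / sum(c(a2f, c2f, e2f)),
                  c(0.6, 0.2, 0.2), c(0.2, 0.6, 0.2),
                  c(1, 1, 1) / 3, c(0.85, 0.05, 0.10), c(0.05, 0.05, 0.9))

  free <- switch(model, ACE = c(TRUE, TRUE, TRUE), AE = c(TRUE, FALSE, TRUE),
                 CE = c(FALSE, TRUE, TRUE), E = c(FALSE, FALSE, TRUE))
  negll <- function(par) {
    p <- c(0, 0, 0)
    p[free] <- par[seq_len(sum(free))]
    mu <- par[sum(free) + 1L]
    -loglikUniStats(p[1], p[2], p[3], mu, groups)
  }
  lower <- c(rep(0, sum(free)), -Inf)
  lower[sum(free)] <- 1e-6  # e path strictly positive
  best <- NULL
  for (i in seq_len(nrow(shares))) {
    p0 <- sqrt(shares[i, ] * vemp)
    par0 <- c(p0[free], memp)
    opt <- tryCatch(stats::nlminb(par0, negll, lower = lower),
                    error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$objective < best$objective))
      best <- opt
  }
  if (is.null(best) || !is.finite(best$objective))
    stop("univariate twin model failed to converge from all starts")
  paths <- c(a = 0, c = 0, e = 0)
  paths[c("a", "c", "e")[free]] <- best$par[seq_len(sum(free))]
  npairs <- vapply(groups, `[[`, integer(1), "n")
  new("ACEFit", model = model, paths = paths,
      mu = best$par[sum(free) + 1L], loglik = -best$objective,
      npairs = npairs, convergence = best$convergence == 0L,
      statistics = list(groups = groups, trait = trait))
}

#' Compare twin models by likelihood-ratio test and AIC
#'
#' Fits the ACE model and its AE, CE and E submodels, then reports the
#' likelihood-ratio statistic 2(loglik_full - loglik_reduced) with degrees
#' of freedom equal to the number of dropped paths (chi-square upper-tail
#' p; the boundary-mixture correction is not applied, which is
#' conservative), and AIC = -2 loglik + 2 (free parameters) per model.
#' Comparing ACE to CE measures the genetic influence.
#'
#' @param cohort,trait as in [fitUnivariateACE()].
#' @return a `ModelComparison` list with `fits` and a `table` data.frame.
#' @export
compareModels <- function(cohort, trait) {
  models <- c("ACE", "AE", "CE", "E")
  nfree <- c(ACE = 4, AE = 3, CE = 3, E = 2)
  fits <- lapply(models, function(m) fitUnivariateACE(cohort, trait, m))
  names(fits) <- models
  ll <- vapply(fits, slot, numeric(1), "loglik")
  full <- ll["ACE"]
  lrt <- pmax(2 * (full - ll[-1]), 0)
  df <- nfree["ACE"] - nfree[-1]
  tab <- data.frame(model = models, loglik = ll,
                    aic = -2 * ll + 2 * nfree,
                    lrt_vs_ace = c(NA, lrt), df = c(NA, df),
                    p_vs_ace = c(NA, stats::pchisq(lrt, df,
                                                   lower.tail = FALSE)),
                    row.names = NULL)
  structure(list(fits = fits, table = tab), class = "ModelComparison")
}

#' @export
print.ModelComparison <- function(x, ...) {
  print(x$table, digits = 4)
  invisible(x)
}

#' Genetic correlation from a bivariate Cholesky fit
#'
#' The correlation between the latent additive-genetic influences on the
#' two traits: a12 / sqrt(a12^2 + a22^2) in the path parameterization,
#' which equals the correlation implied by the genetic covariance matrix
#' A = L_A L_A' whenever a11 > 0. Undefined (NA) when a12 = a22 = 0.
#'
#' @param x a [CholeskyFit-class], or a 2x2 lower-triangular genetic path
#'   matrix.
#' @return scalar in \[-1, 1\], or NA.
#' @export
setGeneric("geneticCorrelation",
           function(x) standardGeneric("geneticCorrelation"))

#' @rdname geneticCorrelation
#' @export
setMethod("geneticCorrelation", "CholeskyFit",
          function(x) geneticCorrelation(x@LA))

#' @rdname geneticCorrelation
#' @export
setMethod("geneticCorrelation", "matrix", function(x) {
  a12 <- x[2, 1]; a22 <- x[2, 2]
  if (a12 == 0 && a22 == 0) return(NA_real_)
  a12 / sqrt(a12^2 + a22^2)
})

#' Shared heritability from a bivariate Cholesky fit
#'
#' The proportion of the cross-trait phenotypic covariance attributable to
#' the genetic cross-path: |a11 a12| / (|a11 a12| + |c11 c12| + |e11 e12|),
#' using absolute values of the path coefficients so the proportion stays
#' in \[0, 1\] when some paths are negative. When signs make the unsigned
#' and signed versions differ, the signed value (no absolute values) is
#' attached as `attr(, "signed")`. NA when all three products are zero.
#'
#' @param x a [CholeskyFit-class] or a named numeric with elements a11,
#'   a12, c11, c12, e11, e12.
#' @return scalar in \[0, 1\], or NA.
#' @export
setGeneric("sharedHeritability",
           function(x) standardGeneric("sharedHeritability"))

#' @rdname sharedHeritability
#' @export
setMethod("sharedHeritability", "CholeskyFit", function(x) {
  sharedHeritability(c(a11 = x@LA[1, 1], a12 = x@LA[2, 1],
                       c11 = x@LC[1, 1], c12 = x@LC[2, 1],
                       e11 = x@LE[1, 1], e12 = x@LE[2, 1]))
})

#' @rdname sharedHeritability
#' @export
setMethod("sharedHeritability", "numeric", function(x) {
  ta <- x[["a11"]] * x[["a12"]]
  tc <- x[["c11"]] * x[["c12"]]
  te <- x[["e11"]] * x[["e12"]]
  denom <- abs(ta) + abs(tc) + abs(te)
  if (denom == 0) return(NA_real_)
  out <- abs(ta) / denom
  signed_denom <- ta + tc + te
  if (any(c(ta, tc, te) < 0) && signed_denom != 0) {
    signed <- ta / signed_denom
    if (!isTRUE(all.equal(signed, out))) attr(out, "signed") <- signed
  }
  out
})

# Parameter vector <-> path matrices for the bivariate model.
bivUnpack <- function(par) {
  list(LA = matrix(c(par[1], par[2], 0, par[3]), 2, 2),
       LC = matrix(c(par[4], par[5], 0, par[6]), 2, 2),
       LE = matrix(c(par[7], par[8], 0, par[9]), 2, 2),
       mu = par[10:11])
}

# Nearest lower-triangular Cholesky-like factor of a symmetric matrix,
# used only to build optimization starts.
safeCholStart <- function(M) {
  M <- (M + t(M)) / 2
  ei <- eigen(M, symmetric = TRUE)
  ei$values <- pmax(ei$values, 1e-3)
  Mp <- ei$vectors %*% diag(ei$values) %*% t(ei$vectors)
  t(chol(Mp))
}

#' Fit the bivariate Cholesky ACE model by maximum likelihood
#'
#' Maximizes the 4-dimensional normal log-likelihood over the nine path
#' coefficients (diagonals constrained nonnegative, off-diagonals free in
#' sign) and the two trait means, with group-specific genetic relatedness.
#' Starts from a moment-based decomposition (A ~ 2(X_MZ - X_0.5),
#' C ~ 2 X_0.5 - X_MZ, E = W - A - C, each projected to positive definite)
#' plus fixed generic starts; deterministic given the data.
#'
#' @param cohort a cohort data.frame.
#' @param traits character(2), the two adjusted trait columns.
#' @return a [CholeskyFit-class]; derive [geneticCorrelation()] and
#'   [sharedHeritability()] from it.
#' @export
fitBivariateACE <- function(cohort, traits) {
  stopifnot(length(traits) == 2L)
  groups <- pairData(cohort, traits)

  crossCov <- function(X) {
    # symmetrized cross-member covariance, double-entered
    M1 <- X[, 1:2, drop = FALSE]; M2 <- X[, 3:4, drop = FALSE]
    Z1 <- rbind(M1, M2); Z2 <- rbind(M2, M1)
    stats::cov(Z1, Z2)
  }
  withinCov <- function(X)
    stats::cov(rbind(X[, 1:2, drop = FALSE], X[, 3:4, drop = FALSE]))

  Xmz <- groups$MZ$X
  X05 <- do.call(rbind, lapply(groups[setdiff(names(groups), "MZ")],
                               function(g) g$X))
  W <- withinCov(do.call(rbind, lapply(groups, `[[`, "X")))
  Cmz <- (crossCov(Xmz) + t(crossCov(Xmz))) / 2
  C05 <- (crossCov(X05) + t(crossCov(X05))) / 2
  Ah <- 2 * (Cmz - C05)
  Ch <- 2 * C05 - Cmz
  Eh <- W - Ah - Ch
  mu0 <- colMeans(rbind(do.call(rbind, lapply(groups, function(g)
    g$X[, 1:2, drop = FALSE])), do.call(rbind, lapply(groups, function(g)
    g$X[, 3:4, drop = FALSE]))))

  packL <- function(L) c(L[1, 1], L[2, 1], L[2, 2])
  starts <- list(
    c(packL(safeCholStart(Ah)), packL(safeCholStart(Ch)),
      packL(safeCholStart(Eh)), mu0),
    c(sqrt(0.6) * c(1, 0.3, 1), sqrt(0.1) * c(1, 0.1, 1),
      sqrt(0.3) * c(1, 0.1, 1), mu0),
    c(sqrt(0.3) * c(1, 0, 1), sqrt(0.3) * c(1, 0, 1),
      sqrt(0.4) * c(1, 0, 1), mu0))

  negll <- function(par) {
    p <- bivUnpack(par)
    -loglikBivStats(p$LA, p$LC, p$LE, p$mu, groups)
  }
  lower <- c(0, -Inf, 0, 0, -Inf, 0, 1e-4, -Inf, 1e-4, -Inf, -Inf)
  best <- NULL
  for (par0 in starts) {
    opt <- tryCatch(stats::nlminb(par0, negll, lower = lower,
                                  control = list(iter.max = 500,
                                                 eval.max = 1000)),
                    error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$objective) &&
        (is.null(best) || opt$objective < best$objective))
      best <- opt
  }
  if (is.null(best))
    stop("bivariate Cholesky model failed to converge from all starts")
  p <- bivUnpack(best$par)
  npairs <- vapply(groups, `[[`, integer(1), "n")
  new("CholeskyFit", LA = p$LA, LC = p$LC, LE = p$LE, mu = p$mu,
      loglik = -best$objective, npairs = npairs,
      convergence = best$convergence == 0L,
      statistics = list(groups = groups, traits = traits))
}

# ---- profile-likelihood confidence intervals ------------------------------

# Profile log-likelihood of h2 for a univariate ACE fit: optimize over
# total variance V, the c-share of the non-genetic variance, and the mean.
profileH2 <- function(groups, h2, start) {
  negll <- function(par) {
    V <- par[1]; pc <- par[2]; mu <- par[3]
    a <- sqrt(h2 * V)
    c <- sqrt(pc * (1 - h2) * V)
    e <- sqrt(max((1 - pc) * (1 - h2) * V, 1e-12))
    -loglikUniStats(a, c, e, mu, groups)
  }
  opt <- stats::nlminb(start, negll, lower = c(1e-6, 0, -Inf),
                       upper = c(Inf, 1 - 1e-9, Inf))
  -opt$objective
}

profileRg <- function(groups, rg, start) {
  k <- rg / sqrt(1 - rg^2)
  negll <- function(par) {
    LA <- matrix(c(par[1], k * par[2], 0, par[2]), 2, 2)
    LC <- matrix(c(par[3], par[4], 0, par[5]), 2, 2)
    LE <- matrix(c(par[6], par[7], 0, par[8]), 2, 2)
    -loglikBivStats(LA, LC, LE, par[9:10], groups)
  }
  lower <- c(0, 0, 0, -Inf, 0, 1e-4, -Inf, 1e-4, -Inf, -Inf)
  opt <- stats::nlminb(start, negll, lower = lower,
                       control = list(iter.max = 400))
  -opt$objective
}

profileShared <- function(groups, s, start) {
  bestll <- -Inf
  for (sgn in c(1, -1)) {
    negll <- function(par) {
      a11 <- par[1]; a22 <- par[2]
      c11 <- par[3]; c12 <- par[4]; c22 <- par[5]
      e11 <- par[6]; e12 <- par[7]; e22 <- par[8]
      ta <- s / (1 - s) * (abs(c11 * c12) + abs(e11 * e12))
      a12 <- sgn * ta / max(a11, 1e-6)
      LA <- matrix(c(a11, a12, 0, a22), 2, 2)
      LC <- matrix(c(c11, c12, 0, c22), 2, 2)
      LE <- matrix(c(e11, e12, 0, e22), 2, 2)
      -loglikBivStats(LA, LC, LE, par[9:10], groups)
    }
    lower <- c(1e-4, 0, 0, -Inf, 0, 1e-4, -Inf, 1e-4, -Inf, -Inf)
    opt <- tryCatch(stats::nlminb(start, negll, lower = lower,
                                  control = list(iter.max = 400)),
                    error = function(e) NULL)
    if (!is.null(opt) && -opt$objective > bestll) bestll <- -opt$objective
  }
  bestll
}

#' Profile-likelihood confidence interval for a fitted quantity
#'
#' The interval is the set of values of the quantity whose profile
#' log-likelihood lies within half a chi-square(1) quantile of the maximum,
#' searched by bisection on each side of the point estimate and clipped to
#' the quantity's natural range. Boundary estimates yield one-sided
#' intervals. A percentile bootstrap over families is available as an
#' alternative.
#'
#' @param fit an [ACEFit-class] (quantity "h2") or [CholeskyFit-class]
#'   (quantity "rg" or "shared_h2").
#' @param quantity which derived quantity to bracket.
#' @param level confidence level.
#' @param method "profile" (default) or "bootstrap".
#' @param n_boot bootstrap resamples (bootstrap method only).
#' @param seed seed for the bootstrap resampling.
#' @return numeric `c(lower, upper)`, containing the point estimate.
#' @export
confidenceInterval <- function(fit, quantity = c("h2", "rg", "shared_h2"),
                               level = 0.95,
                               method = c("profile", "bootstrap"),
                               n_boot = 1000L, seed = 1L) {
  quantity <- match.arg(quantity)
  method <- match.arg(method)
  if (method == "bootstrap")
    return(bootstrapCI(fit, quantity, level, n_boot, seed))
  groups <- fit@statistics$groups
  crit <- stats::qchisq(level, 1) / 2
  target <- fit@loglik - crit

  if (quantity == "h2") {
    stopifnot(is(fit, "ACEFit"))
    est <- heritability(fit)
    v <- sum(fit@paths^2)
    nong <- fit@paths["c"]^2 + fit@paths["e"]^2
    pc0 <- if (nong > 0) unname(fit@paths["c"]^2 / nong) else 0.5
    start <- c(v, min(max(pc0, 1e-3), 1 - 1e-3), fit@mu)
    pl <- function(q) profileH2(groups, q, start)
    rng <- c(1e-6, 1 - 1e-6)
  } else {
    stopifnot(is(fit, "CholeskyFit"))
    if (quantity == "rg") {
      est <- geneticCorrelation(fit)
      start <- c(fit@LA[1, 1], max(fit@LA[2, 2], 1e-3),
                 fit@LC[1, 1], fit@LC[2, 1], fit@LC[2, 2],
                 max(fit@LE[1, 1], 1e-3), fit@LE[2, 1],
                 max(fit@LE[2, 2], 1e-3), fit@mu)
      pl <- function(q) profileRg(groups, q, start)
      rng <- c(-1 + 1e-6, 1 - 1e-6)
    } else {
      est <- as.numeric(sharedHeritability(fit))
      start <- c(max(fit@LA[1, 1], 1e-3), max(fit@LA[2, 2], 1e-3),
                 fit@LC[1, 1], fit@LC[2, 1], fit@LC[2, 2],
                 max(fit@LE[1, 1], 1e-3), fit@LE[2, 1],
                 max(fit@LE[2, 2], 1e-3), fit@mu)
      pl <- function(q) profileShared(groups, q, start)
      rng <- c(1e-6, 1 - 1e-6)
    }
  }
  if (is.na(est)) return(c(NA_real_, NA_real_))
  est_in <- min(max(est, rng[1]), rng[2])

  sideRoot <- function(bound) {
    f_bound <- pl(bound) - target
    if (f_bound >= 0) return(bound)  # one-sided: CI reaches the range edge
    lo <- min(bound, est_in); hi <- max(bound, est_in)
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      fm <- pl(mid) - target
      inner_is_hi <- bound < est_in
      if (fm >= 0) { if (inner_is_hi) hi <- mid else lo <- mid }
      else { if (inner_is_hi) lo <- mid else hi <- mid }
      if (hi - lo < 1e-4) break
    }
    (lo + hi) / 2
  }
  lo <- sideRoot(rng[1])
  hi <- sideRoot(rng[2])
  c(min(lo, est), max(hi, est))
}

# Percentile bootstrap over families, refitting the model per resample.
bootstrapCI <- function(fit, quantity, level, n_boot, seed) {
  groups <- fit@statistics$groups
  stat <- switch(quantity,
                 h2 = function(f) heritability(f),
                 rg = function(f) geneticCorrelation(f),
                 shared_h2 = function(f) as.numeric(sharedHeritability(f)))
  uni <- is(fit, "ACEFit")
  traits <- if (uni) fit@statistics$trait else fit@statistics$traits
  vals <- withSeed(seed, {
    vapply(seq_len(n_boot), function(b) {
      rows <- list()
      for (gname in names(groups)) {
        g <- groups[[gname]]
        idx <- sample.int(g$n, g$n, replace = TRUE)
        X <- g$X[idx, , drop = FALSE]
        ntr <- length(traits)
        fam <- sprintf("%s%05d", gname, seq_len(g$n))
        d1 <- data.frame(family_id = fam, member = 1L, group = gname)
        d2 <- data.frame(family_id = fam, member = 2L, group = gname)
        for (j in seq_len(ntr)) {
          d1[[traits[j]]] <- X[, j]
          d2[[traits[j]]] <- X[, ntr + j]
        }
        rows[[gname]] <- rbind(d1, d2)
      }
      boot <- do.call(rbind, rows)
      f <- tryCatch(
        if (uni) fitUnivariateACE(boot, traits, fit@model)
        else fitBivariateACE(boot, traits),
        error = function(e) NULL)
      if (is.null(f)) NA_real_ else stat(f)
    }, numeric(1))
  })
  stats::quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2),
                  na.rm = TRUE, names = FALSE)
}
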