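#' Specification of a simulated twin/sibling cohort
#'
#' Defines an ACE generative model for paired phenotypes. Monozygotic (MZ)
#' pairs share their additive-genetic latent exactly (genetic relatedness
#' r_A = 1); dizygotic (DZ) twins and non-twin siblings (NT) share half of
#' it on average (r_A = 0.5). The shared-environment latent C is identical
#' within every pair; the unique-environment latent E is independent per
#' member. Path coefficients may be scalars (one trait) or lower-triangular
#' 2x2 matrices (bivariate Cholesky model).
#'
#' Default pair counts (138 MZ, 79 DZ, 133 NT) give the 700-subject /
#' 350-pair cohort structure used throughout.
#'
#' @param n_mz,n_dz,n_nt pair counts per group.
#' @param paths_a,paths_c,paths_e path coefficients; scalars or 2x2
#'   lower-triangular matrices with nonnegative diagonals.
#' @param relatedness named additive-genetic correlations per group.
#' @param covariate_effects named slopes for `age` (per year, centred at
#'   28.5) and `sex` (additive shift for males), applied to every trait.
#' @param traits character names of trait columns.
#' @param seed integer seed.
#' @return a `TwinSimSpec` list.
#' @export
twinSimSpec <- function(n_mz = 138L, n_dz = 79L, n_nt = 133L,
                        paths_a = 0.9497, paths_c = 0.1414,
                        paths_e = 0.2793,
                        relatedness = c(MZ = 1, DZ = 0.5, NT = 0.5),
                        covariate_effects = c(age = 0.02, sex = 0.2),
                        traits = NULL, seed = 1L) {
  bivar <- is.matrix(paths_a)
  for (p in list(paths_a, paths_c, paths_e)) {
    if (is.matrix(p)) {
      if (!all(dim(p) == c(2L, 2L)) || abs(p[1, 2]) > 1e-12)
        stop("bivariate path matrices must be 2x2 lower-triangular")
      if (p[1, 1] < 0 || p[2, 2] < 0)
        stop("path-matrix diagonals must be nonnegative")
    }
  }
  if (bivar && !(is.matrix(paths_c) && is.matrix(paths_e)))
    stop("paths_a, paths_c, paths_e must all be matrices for bivariate use")
  stopifnot(all(c("MZ", "DZ", "NT") %in% names(relatedness)))
  if (is.null(traits)) traits <- if (bivar) c("trait1", "trait2") else "trait1"
  structure(list(n_mz = as.integer(n_mz), n_dz = as.integer(n_dz),
                 n_nt = as.integer(n_nt), paths_a = paths_a,
                 paths_c = paths_c, paths_e = paths_e,
                 relatedness = relatedness,
                 covariate_effects = covariate_effects,
                 traits = traits, bivariate = bivar,
                 seed = as.integer(seed)),
            class = "TwinSimSpec")
}

#' Simulate a twin/sibling cohort from an ACE model
#'
#' Draws latent A/C/E values with the within-pair correlation structure of
#' the classical twin design and builds traits as covariate effects plus
#' the path-weighted latents. MZ and DZ pairs share age and sex within the
#' pair; non-twin siblings draw ages independently within 22--35 years and
#' sexes independently (about half the NT pairs end up opposite-sex).
#'
#' @param spec a `TwinSimSpec`.
#' @return a `data.frame` with columns `family_id`, `member`, `group`,
#'   `age`, `sex` and one column per trait; two rows per family.
#' @export
simulateTwinCohort <- function(spec) {
  stopifnot(inherits(spec, "TwinSimSpec"))
  withSeed(spec$seed, {
    groups <- c(rep("MZ", spec$n_mz), rep("DZ", spec$n_dz),
                rep("NT", spec$n_nt))
    np <- length(groups)
    if (np == 0L) stop("cohort must contain at least one pair")
    r_A <- unname(spec$relatedness[groups])

    twin <- groups %in% c("MZ", "DZ")
    age1 <- sample(22:35, np, replace = TRUE)
    age2 <- ifelse(twin, age1, sample(22:35, np, replace = TRUE))
    sex1 <- sample(c("M", "F"), np, replace = TRUE)
    sex2 <- ifelse(twin, sex1, sample(c("M", "F"), np, replace = TRUE))

    be <- spec$covariate_effects
    cov1 <- be[["age"]] * (age1 - 28.5) + be[["sex"]] * (sex1 == "M")
    cov2 <- be[["age"]] * (age2 - 28.5) + be[["sex"]] * (sex2 == "M")

    ntr <- length(spec$traits)
    y1 <- matrix(0, np, ntr)
    y2 <- matrix(0, np, ntr)
    if (!spec$bivariate) {
      A1 <- stats::rnorm(np)
      A2 <- r_A * A1 + sqrt(1 - r_A^2) * stats::rnorm(np)
      C <- stats::rnorm(np)
      y1[, 1] <- spec$paths_a * A1 + spec$paths_c * C +
        spec$paths_e * stats::rnorm(np)
      y2[, 1] <- spec$paths_a * A2 + spec$paths_c * C +
        spec$paths_e * stats::rnorm(np)
    } else {
      # two latent genetic dimensions, each correlated r_A within pair
      A1 <- matrix(stats::rnorm(np * 2), np, 2)
      A2 <- r_A * A1 + sqrt(1 - r_A^2) * matrix(stats::rnorm(np * 2), np, 2)
      Cs <- matrix(stats::rnorm(np * 2), np, 2)
      E1 <- matrix(stats::rnorm(np * 2), np, 2)
      E2 <- matrix(stats::rnorm(np * 2), np, 2)
      y1 <- A1 %*% t(spec$paths_a) + Cs %*% t(spec$paths_c) +
        E1 %*% t(spec$paths_e)
      y2 <- A2 %*% t(spec$paths_a) + Cs %*% t(spec$paths_c) +
        E2 %*% t(spec$paths_e)
    }
    y1 <- y1 + cov1
    y2 <- y2 + cov2

    df <- data.frame(
      family_id = rep(sprintf("F%04d", seq_len(np)), each = 2L),
      member = rep(1:2, np),
      group = rep(groups, each = 2L),
      age = as.numeric(rbind(age1, age2)),
      sex = as.character(rbind(sex1, sex2)),
      stringsAsFactors = FALSE)
    for (j in seq_len(ntr))
      df[[spec$traits[j]]] <- as.numeric(rbind(y1[, j], y2[, j]))
    df
  })
}

#' Write / read a cohort table
#'
#' Cohorts are stored as UTF-8 comma-delimited text with a header row.
#'
#' @param cohort a cohort `data.frame`.
#' @param path file path.
#' @return `readCohort` returns the cohort `data.frame`.
#' @export
writeCohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
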