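# Printed per-salt and per-ion results shipped as package data: these are
# the study's tabulated estimates at 25 degC and serve as inputs to the
# decomposition stage and as references for recovery experiments.

#' Printed per-salt volumetric parameters (25 degC)
#'
#' The published per-salt estimates: partial molar volume `V` (cm^3/mol)
#' with SE, thermal expansion `alpha` (10^-3 cm^3/mol/K), quadratic
#' coefficient `beta` (10^-3 cm^3/mol/K^2, quadratic rows only) and the
#' printed extremum temperature. `order` distinguishes the linear- and
#' quadratic-model rows.
#'
#' @param order `"quadratic"` (default), `"linear"` or `"both"`.
#' @return data.frame, one row per solute (16 salts + HCl).
#' @export
table1_volumes <- function(order = c("quadratic", "linear", "both")) {
  order <- match.arg(order)
  solute <- c("LiCl", "NaCl", "KCl", "MgCl2", "LiBr", "NaBr", "KBr", "MgBr2",
              "LiI", "NaI", "KI", "MgI2", "Li2SO4", "Na2SO4", "K2SO4",
              "MgSO4", "HCl")
  lin <- data.frame(
    solute = solute, order = "linear",
    V = c(17.85, 16.37, 27.19, 18.09, 24.01, 23.16, 33.53, 33.18, 35.70,
          35.86, 44.66, 54.62, 11.83, 11.20, 33.37, -4.74, 17.70),
    V_se = c(0.09, 0.09, 0.11, 0.13, 0.08, 0.12, 0.14, 0.11, 0.08, 0.11,
             0.11, 0.14, 0.10, 0.17, 0.10, 0.10, 0.05),
    alpha_1e3 = c(-3, 61, 61, -10, 20, 89, 77, 40, 32, 108, 91, 89, 36,
                  171, 142, 58, 6),
    alpha_se_1e3 = c(10, 11, 14, 16, 9, 15, 17, 12, 9, 13, 12, 16, 11, 21,
                     12, 12, 6),
    beta_1e3 = NA_real_, beta_se_1e3 = NA_real_, T_extr = NA_real_)
  quad <- data.frame(
    solute = solute, order = "quadratic",
    V = c(17.89, 16.43, 27.22, 18.06, 24.03, 23.21, 33.54, 33.15, 35.75,
          35.90, 44.71, 54.72, 11.89, 11.30, 33.32, -4.71, 17.69),
    V_se = c(0.10, 0.12, 0.18, 0.20, 0.09, 0.18, 0.21, 0.12, 0.09, 0.13,
             0.12, 0.16, 0.11, 0.25, 0.14, 0.11, 0.07),
    alpha_1e3 = c(13, 87, 66, -4, 26, 106, 83, 55, 50, 123, 113, 129, 60,
                  221, 145, 73, 21),
    alpha_se_1e3 = c(20, 25, 36, 41, 18, 37, 43, 24, 18, 26, 24, 32, 22,
                     52, 28, 25, 13),
    beta_1e3 = c(-1.6, -2.6, 0.0, -0.5, -0.6, -1.5, -0.2, -1.6, -1.8,
                 -1.5, -2.2, -4.1, -2.4, -5.5, -0.1, -1.5, -1.7),
    beta_se_1e3 = c(1.8, 2.2, 3.1, 3.5, 1.6, 3.2, 3.7, 2.1, 1.6, 2.2, 2.1,
                    2.7, 1.9, 4.5, 2.5, 2.2, 1.2),
    T_extr = c(31, 29, 42, 32, 38, 47, 59, Inf, 33, 39, 65, 51, 41, 37,
               45, Inf, 45))
  switch(order, quadratic = quad, linear = lin, both = rbind(lin, quad))
}

#' Printed per-ion volumes (20--40 degC)
#'
#' The published self-consistent ionic volumes: `V` (cm^3/mol) with SEs
#' per temperature, the 25 degC first derivative `dVdT_1e3`
#' (10^-3 cm^3/mol/K), the quadratic coefficient `d2VdT2_1e3`
#' (10^-3 cm^3/mol/K^2) and the extremum temperature. The proton row is
#' the Marcus polynomial, SE-free.
#'
#' @return list with components `values` (long data.frame: ion, T, V,
#'   SE) and `derivatives` (ion, dVdT_1e3, dVdT_se_1e3, d2VdT2_1e3,
#'   d2VdT2_se_1e3, T_extr).
#' @export
table2_ions <- function() {
  ions <- c("H", ion_order())
  Ts <- c(20, 25, 30, 35, 40)
  V <- rbind(
    H  = c(-5.33, -5.41, -5.49, -5.59, -5.69),
    Li = c(-5.44, -5.56, -5.72, -5.90, -5.91),
    Na = c(-6.20, -5.91, -5.74, -5.57, -5.32),
    K  = c(4.32, 4.48, 4.52, 4.65, 5.01),
    Mg = c(-27.07, -27.26, -27.59, -27.86, -27.81),
    Cl = c(22.67, 22.85, 23.03, 23.09, 23.07),
    Br = c(29.68, 29.96, 30.25, 30.41, 30.51),
    I  = c(40.59, 41.06, 41.48, 41.75, 41.83),
    SO4 = c(22.63, 23.24, 23.81, 24.28, 24.30))
  SE <- rbind(
    H  = c(NA, NA, NA, NA, NA),
    Li = c(0.22, 0.21, 0.20, 0.21, 0.25),
    Na = c(0.24, 0.22, 0.22, 0.22, 0.26),
    K  = c(0.24, 0.22, 0.22, 0.22, 0.26),
    Mg = c(0.43, 0.40, 0.39, 0.41, 0.47),
    Cl = c(0.18, 0.16, 0.16, 0.17, 0.19),
    Br = c(0.23, 0.21, 0.21, 0.22, 0.25),
    I  = c(0.23, 0.21, 0.21, 0.22, 0.25),
    SO4 = c(0.45, 0.41, 0.41, 0.42, 0.49))
  values <- data.frame(
    ion = rep(ions, each = length(Ts)),
    T = rep(Ts, times = length(ions)),
    V = as.vector(t(V)), SE = as.vector(t(SE)))
  derivatives <- data.frame(
    ion = ions,
    dVdT_1e3 = c(-16.5, -31.8, 44.7, 17.1, -57.6, 35.8, 57.2, 89.9, 124.4),
    dVdT_se_1e3 = c(NA, 5.5, 5.9, 5.9, 10.6, 4.3, 5.6, 5.6, 11.1),
    d2VdT2_1e3 = c(-0.17, 0.56, -0.30, 1.31, 1.49, -1.50, -1.47, -2.62,
                   -3.61),
    d2VdT2_se_1e3 = c(NA, 0.49, 0.51, 0.51, 0.93, 0.38, 0.50, 0.49, 0.97),
    T_extr = c(-24, 53, Inf, 18, 44, 37, 44, 42, 42))
  list(values = values, derivatives = derivatives)
}

#' Ion volume models built from the printed ionic table
#'
#' One [thermal_volume_model()] per ion, taking the printed 25 degC
#' value, the printed first derivative as `alpha` and the printed
#' quadratic coefficient as `beta`. These serve as the default ground
#' truth for the synthetic full-study generator.
#'
#' @return named list of 8 models (proton excluded; see [hplus_model()]).
#' @export
table2_ion_models <- function() {
  tab <- table2_ions()
  v25 <- tab$values[tab$values$T == 25 & tab$values$ion != "H", ]
  der <- tab$derivatives[tab$derivatives$ion != "H", ]
  models <- Map(function(v, a, b) {
    thermal_volume_model(v, a * 1e-3, b * 1e-3, t_ref = 25)
  }, v25$V, der$dVdT_1e3, der$d2VdT2_1e3)
  stats::setNames(models, v25$ion)
}

#' Reproduce the ionic table from the printed per-salt table
#'
#' Runs the per-temperature decomposition chain: evaluates each salt's
#' quadratic thermal model at 20--40 degC (propagating the printed SEs),
#' solves the proton-constrained weighted least squares at each
#' temperature, refits a quadratic V(T) per ion to recover derivative
#' rows and extremum temperatures, and runs the cation/anion curvature
#' contrast.
#'
#' @param table1 per-salt table in the layout of [table1_volumes()].
#' @param temperatures degC.
#' @param registry solute registry.
#' @return list: `by_temperature` (long ion x T data.frame), `summary`
#'   (ions x temperatures + derivative rows + T_extr), and
#'   `curvature_test` (an `htest`).
#' @export
reproduce_table2 <- function(table1 = table1_volumes(),
                             temperatures = seq(20, 40, 5),
                             registry = salt_registry()) {
  stopifnot(length(temperatures) >= 3)
  per_t <- lapply(temperatures, function(Ti) {
    dt <- Ti - 25
    V <- table1$V + table1$alpha_1e3 * 1e-3 * dt +
      ifelse(is.na(table1$beta_1e3), 0, table1$beta_1e3 * 1e-3) * dt^2
    # printed covariances are unavailable; propagate printed SEs only
    SE <- sqrt(table1$V_se^2 + (table1$alpha_se_1e3 * 1e-3 * dt)^2 +
                 ifelse(is.na(table1$beta_se_1e3), 0,
                        (table1$beta_se_1e3 * 1e-3)^2) * dt^4)
    sys <- build_system(data.frame(solute = table1$solute, V = V, SE = SE),
                        registry = registry)
    cbind(T = Ti, decompose_at_T(sys, Ti))
  })
  long <- do.call(rbind, per_t)
  # quadratic refit per ion; per-point variances are known (propagated
  # from the decomposition), so the coefficient covariance is the
  # unscaled (X'WX)^-1 - the refit residuals are exactly zero when the
  # salt inputs are themselves quadratic in T
  fits <- lapply(split(long, long$ion), function(df) {
    dt <- df$T - 25
    X <- cbind(1, dt, dt^2)
    w <- 1 / df$SE^2
    xtwx <- crossprod(X * sqrt(w))
    co <- solve(xtwx, crossprod(X * w, df$V))
    thermal_volume_model(co[[1]], co[[2]], co[[3]], t_ref = 25,
                         covariance = solve(xtwx))
  })
  fits <- fits[ion_order()]
  beta <- vapply(fits, `[[`, numeric(1), "beta")
  se <- vapply(fits, function(f) sqrt(f$covariance[3, 3]), numeric(1))
  test <- curvature_contrast(beta, se)
  set <- structure(list(models = fits, hplus = hplus_model(25),
                        method = "per-temperature", t_ref = 25,
                        covariance = NULL, delta_d0 = NULL,
                        residual_sd = NA_real_, n_obs = nrow(table1)),
                   class = "ion_volume_set")
  list(by_temperature = long,
       summary = summary(set, temperatures = temperatures),
       ion_set = set,
       curvature_test = test)
}
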