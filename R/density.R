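# Pitzer-type density model for dilute electrolyte solutions:
#
#   V2^0(T) + Av(T)*omega*ln(1 + b*sqrt(omega*m))/b
#       = M/d0 - 10^3/(d*d0) * (d - d0)/m
#
# with quadratic thermal expansion V2^0(T) = V_ref + alpha*dT + beta*dT^2,
# fitted globally per solute across dilution series and temperatures with
# one nuisance solvent-density offset delta_d0 per (series, T).

#' Debye-Hueckel volume correction term
#'
#' \eqn{A_v \omega \ln(1 + b\sqrt{\omega m})/b}: the theoretical
#' limiting-law contribution of ion-solvent electrostatics to the
#' apparent molar volume. Zero at infinite dilution and strictly
#' increasing in molality and valence factor.
#'
#' @param m molality (mol/kg), non-negative.
#' @param omega valence factor (>= 1 for any electrolyte).
#' @param T temperature (degC).
#' @param ctx a [reference_context()].
#' @return cm^3/mol.
#' @examples
#' dh_term(0.03, 1, 25)   # ~0.295 with the default Pitzer Av table
#' @export
dh_term <- function(m, omega, T, ctx = reference_context()) {
  if (any(m < 0)) stop("dh_term: molality must be non-negative", call. = FALSE)
  stopifnot(all(omega >= 1))
  av <- av_slope(T, ctx)
  av * omega * log(1 + ctx$b * sqrt(omega * m)) / ctx$b
}

#' Measured side of the apparent-volume relation
#'
#' \eqn{M/d_0 - 10^3 (d - d_0) / (d d_0 m)}, the experimentally
#' accessible combination equal to the apparent molar volume plus the
#' Debye-Hueckel term. Implemented exactly as the model is written
#' (first term uses \eqn{d_0}, not \eqn{d}).
#'
#' @param d solution density (g/cm^3).
#' @param d0 solvent density (g/cm^3).
#' @param m molality (mol/kg), strictly positive.
#' @param M molar mass of the solute (g/mol).
#' @return cm^3/mol.
#' @export
apparent_rhs <- function(d, d0, m, M) {
  if (any(m <= 0))
    stop("apparent_rhs: molality must be strictly positive (singular at m = 0)",
         call. = FALSE)
  stopifnot(all(d > 0), all(d0 > 0))
  M / d0 - 1e3 / (d * d0) * (d - d0) / m
}

#' Predict solution density from a thermal volume model
#'
#' Exact closed-form inversion of the apparent-volume relation: with
#' \eqn{V_\psi(m,T) = V(T) + A_v\omega\ln(1+b\sqrt{\omega m})/b} and
#' \eqn{d_0' = d_0(T) + \Delta d_0},
#' \deqn{d = d_0' / (1 - m (M - d_0' V_\psi)/10^3).}
#' At `m = 0` this returns `d0'` exactly.
#'
#' @param m molality (mol/kg), non-negative.
#' @param T temperature (degC).
#' @param model a [thermal_volume_model()] for the solute.
#' @param salt a [salt_spec()].
#' @param delta_d0 local solvent-density offset (g/cm^3), default 0.
#' @param ctx a [reference_context()].
#' @return density in g/cm^3.
#' @export
predict_density <- function(m, T, model, salt, delta_d0 = 0,
                            ctx = reference_context()) {
  stopifnot(inherits(model, "thermal_volume_model"),
            inherits(salt, "salt_spec"))
  if (any(m < 0)) stop("predict_density: negative molality", call. = FALSE)
  d0p <- d0_ref(T) + delta_d0
  vpsi <- predict(model, T) + dh_term(m, salt$omega, T, ctx)
  denom <- 1 - m * (salt$M - d0p * vpsi) / 1e3
  if (any(denom <= 0))
    stop("predict_density: nonphysical parameters drive the density denominator <= 0",
         call. = FALSE)
  d0p / denom
}

#' Validate a table of densimeter observations
#'
#' Checks the record contract: positive molality and density, one solute
#' per table, and warns (softly) about temperatures outside the studied
#' 20--40 degC window.
#'
#' @param records data.frame with columns `solute`, `series_id`,
#'   `temperature_C`, `molality_mol_kg`, `density_g_cm3`.
#' @return the records, invisibly, after validation.
#' @export
validate_density_records <- function(records) {
  need <- c("solute", "series_id", "temperature_C", "molality_mol_kg",
            "density_g_cm3")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(records$molality_mol_kg) |
                 records$molality_mol_kg <= 0)
  if (length(bad))
    stop("non-positive molality in record row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(records$density_g_cm3) | records$density_g_cm3 <= 0)
  if (length(bad))
    stop("non-positive density in record row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  if (any(records$temperature_C < 20 | records$temperature_C > 40))
    warning("records outside the studied 20-40 degC window", call. = FALSE)
  invisible(records)
}

#' Read/write density records as CSV
#'
#' CSV dialect: header required, decimal point, UTF-8; columns `solute`,
#' `series_id`, `temperature_C`, `molality_mol_kg`, `density_g_cm3`.
#'
#' @param path file path.
#' @return data.frame of validated records.
#' @export
read_density_csv <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_density_records(rec)
  rec
}

#' @rdname read_density_csv
#' @param records record table to write.
#' @export
write_density_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- global per-salt fit --------------------------------------------------

# internal: delta_d0 key per record
.dd0_key <- function(records, per_temperature) {
  if (per_temperature)
    paste(records$series_id, records$temperature_C, sep = "@")
  else as.character(records$series_id)
}

#' Global fit of one solute's density data
#'
#' Unweighted nonlinear least squares on density residuals
#' `d_obs - predict_density(...)`, with global parameters
#' `(V_ref, alpha[, beta])` and one local solvent-density offset
#' `delta_d0` per (series, temperature) pair (or per series). Both the
#' linear (`beta = 0`) and quadratic thermal-expansion models are
#' fitted; in `"auto"` mode the quadratic model is selected when both
#' AIC and the F-test (alpha = 0.05) favor it.
#'
#' @param records density records for a single solute
#'   (see [validate_density_records()]).
#' @param salt the matching [salt_spec()].
#' @param ctx a [reference_context()].
#' @param model_order `"auto"`, `"linear"` or `"quadratic"`.
#' @param per_temperature_offsets one `delta_d0` per (series, T) when
#'   `TRUE` (default), per series otherwise.
#' @return object of class `salt_fit`: the selected
#'   [thermal_volume_model()] (with covariance), the `delta_d0` table,
#'   residual summaries, AIC for both orders and the F-test p-value.
#' @export
fit_salt <- function(records, salt, ctx = reference_context(),
                     model_order = c("auto", "linear", "quadratic"),
                     per_temperature_offsets = TRUE) {
  model_order <- match.arg(model_order)
  validate_density_records(records)
  stopifnot(inherits(salt, "salt_spec"))
  if (length(unique(records$solute)) > 1)
    stop("fit_salt expects records for a single solute", call. = FALSE)

  temps <- sort(unique(records$temperature_C))
  n_t <- length(temps)
  per_series_m <- tapply(records$molality_mol_kg, records$series_id,
                         function(x) length(unique(x)))
  if (any(per_series_m < 2))
    stop("each dilution series needs >= 2 distinct molalities", call. = FALSE)
  if (n_t < 2 && model_order != "quadratic")
    stop("parameter not identifiable from the design: alpha (need >= 2 temperatures)",
         call. = FALSE)
  if (n_t < 3 && model_order %in% c("quadratic", "auto")) {
    if (model_order == "quadratic")
      stop("parameter not identifiable from the design: beta (need >= 3 temperatures)",
           call. = FALSE)
    model_order <- "linear"
  }

  fits <- list(
    linear = .fit_salt_order(records, salt, ctx, quadratic = FALSE,
                             per_temperature_offsets),
    quadratic = if (n_t >= 3)
      .fit_salt_order(records, salt, ctx, quadratic = TRUE,
                      per_temperature_offsets) else NULL
  )
  n <- nrow(records)
  aic <- vapply(fits, function(f) {
    if (is.null(f)) return(NA_real_)
    k <- length(f$par) + 1
    n * log(f$rss / n) + 2 * k
  }, numeric(1))
  f_p <- NA_real_
  if (!is.null(fits$quadratic)) {
    df2 <- n - length(fits$quadratic$par)
    fstat <- (fits$linear$rss - fits$quadratic$rss) /
      (fits$quadratic$rss / df2)
    f_p <- stats::pf(max(fstat, 0), 1, df2, lower.tail = FALSE)
  }
  use_quad <- switch(model_order,
    linear = FALSE,
    quadratic = TRUE,
    auto = !is.null(fits$quadratic) &&
      (aic["quadratic"] < aic["linear"]) && (f_p < 0.05))
  sel <- if (use_quad) fits$quadratic else fits$linear

  cov <- levmar_covariance(sel, n, names(sel$par))
  nglob <- if (use_quad) 3L else 2L
  cov3 <- matrix(0, 3, 3)
  cov3[seq_len(nglob), seq_len(nglob)] <- cov[seq_len(nglob), seq_len(nglob)]
  model <- thermal_volume_model(
    v_ref = sel$par[["V_ref"]], alpha = sel$par[["alpha"]],
    beta = if (use_quad) sel$par[["beta"]] else 0,
    t_ref = ctx$t_ref, covariance = cov3)

  dd0_names <- names(sel$par)[-seq_len(nglob)]
  dd0 <- data.frame(
    key = sub("^dd0:", "", dd0_names),
    delta_d0 = unname(sel$par[-seq_len(nglob)]),
    se = sqrt(diag(cov))[-seq_len(nglob)], row.names = NULL)
  dd0$flagged <- abs(dd0$delta_d0) > 2e-5

  structure(list(
    solute = salt$name, model = model, order = if (use_quad) "quadratic" else "linear",
    delta_d0 = dd0, residual_sd = sqrt(sel$rss / (n - length(sel$par))),
    n_obs = n, aic = aic, f_test_p = f_p, covariance = cov,
    residuals = data.frame(records[c("series_id", "temperature_C",
                                     "molality_mol_kg")],
                           residual = sel$residuals)),
    class = "salt_fit")
}

# one model order; returns the raw levmar fit with named parameters
.fit_salt_order <- function(records, salt, ctx, quadratic,
                            per_temperature_offsets) {
  key <- .dd0_key(records, per_temperature_offsets)
  keys <- unique(key)
  key_idx <- match(key, keys)
  m <- records$molality_mol_kg
  T <- records$temperature_C
  d_obs <- records$density_g_cm3
  d0 <- d0_ref(T)
  dh <- dh_term(m, salt$omega, T, ctx)
  dt <- T - ctx$t_ref
  M <- salt$M

  nglob <- if (quadratic) 3L else 2L
  par_names <- c(c("V_ref", "alpha", if (quadratic) "beta"),
                 paste0("dd0:", keys))

  # direct apparent-volume start: nearly the exact answer
  v_start <- stats::median(apparent_rhs(d_obs, d0, m, M) - dh)
  par0 <- c(v_start, rep(0, nglob - 1L), rep(0, length(keys)))

  unpack <- function(par) {
    v <- par[1] + par[2] * dt + if (quadratic) par[3] * dt^2 else 0
    dd0 <- par[nglob + key_idx]
    list(vpsi = v + dh, d0p = d0 + dd0)
  }
  pred <- function(par) {
    u <- unpack(par)
    denom <- 1 - m * (M - u$d0p * u$vpsi) / 1e3
    u$d0p / denom
  }
  resid_fn <- function(par) d_obs - pred(par)
  jac_fn <- function(par) {
    u <- unpack(par)
    denom <- 1 - m * (M - u$d0p * u$vpsi) / 1e3
    # d = d0p/denom; residual = d_obs - d, so J = -d(d)/d(par)
    dd_dvpsi <- -u$d0p * (m * u$d0p / 1e3) / denom^2
    dd_dd0p <- 1 / denom - u$d0p * (m * u$vpsi / 1e3) / denom^2
    J <- matrix(0, length(m), length(par))
    J[, 1] <- dd_dvpsi
    J[, 2] <- dd_dvpsi * dt
    if (quadratic) J[, 3] <- dd_dvpsi * dt^2
    J[cbind(seq_along(m), nglob + key_idx)] <- dd_dd0p
    -J
  }
  fit <- levmar(par0, resid_fn, jac_fn)
  names(fit$par) <- par_names
  fit
}

#' @export
print.salt_fit <- function(x, ...) {
  cat(sprintf("<salt_fit> %s (%s model, n = %d)\n", x$solute, x$order, x$n_obs))
  m <- x$model
  se <- sqrt(diag(m$covariance))
  cat(sprintf("  V2^0(%g degC) = %.3f (%.3f) cm^3/mol\n", m$t_ref, m$v_ref, se[1]))
  cat(sprintf("  alpha = %.1f (%.1f) 10^-3 cm^3/mol/K\n",
              1e3 * m$alpha, 1e3 * se[2]))
  if (x$order == "quadratic")
    cat(sprintf("  beta  = %.2f (%.2f) 10^-3 cm^3/mol/K^2\n",
                1e3 * m$beta, 1e3 * se[3]))
  cat(sprintf("  residual sd = %.2e g/cm^3 (instrument 7e-06); F-test p = %.3g\n",
              x$residual_sd, x$f_test_p))
  invisible(x)
}
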