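# Decomposition of salt volumes into single-ion partial molar volumes via
# ionic additivity V2^0(XnYm) = n*V2^0(X) + m*V2^0(Y). The 16-salt system
# is rank-deficient (its null space is the ionic charge vector), so the
# HCl data plus a literature proton-volume constraint close the system.

#' Proton partial molar volume (Marcus equation)
#'
#' Literature parameterization of the hydrated-proton volume,
#' \deqn{V_2^0(H^+, T) = -5.1 - 0.008 T - 1.7\times 10^{-4} T^2}
#' with T in degC; gives -5.41 cm^3/mol at 25 degC.
#'
#' @param T temperature (degC); intended for 0--60 degC.
#' @return cm^3/mol.
#' @export
hplus_volume <- function(T) {
  -5.1 - 0.008 * T - 1.7e-4 * T^2
}

#' @rdname hplus_volume
#' @param t_ref reference temperature for the returned
#'   [thermal_volume_model()] form.
#' @return `hplus_model()`: the same polynomial recentred at `t_ref`
#'   (alpha is then the first derivative at `t_ref`, beta the quadratic
#'   coefficient).
#' @export
hplus_model <- function(t_ref = 25) {
  beta <- -1.7e-4
  alpha <- -0.008 + 2 * beta * t_ref
  thermal_volume_model(hplus_volume(t_ref), alpha, beta, t_ref,
                       covariance = matrix(0, 3, 3))
}

#' Build the ionic-additivity system
#'
#' Assembles the stoichiometric design matrix (salts x ions, ions in the
#' canonical order Li, Na, K, Mg, Cl, Br, I, SO4) from per-salt volume
#' estimates, reports its rank and null space, and records the proton
#' constraint carried by the HCl row.
#'
#' @param salt_values data.frame with columns `solute`, `V` (cm^3/mol)
#'   and `SE`.
#' @param registry solute registry, default [salt_registry()].
#' @param include_hcl keep the HCl row (to be closed by the proton
#'   constraint in [decompose_at_T()]).
#' @param ions ion columns of the design. `NULL` (default) uses the
#'   ions actually observed among the salts, in canonical order; an
#'   explicit list raises a coverage error for any requested ion that
#'   no salt contains.
#' @return object of class `additivity_system` with fields `design`,
#'   `values`, `ions`, `rank`, `null_space`, `has_hcl`.
#' @export
build_system <- function(salt_values, registry = salt_registry(),
                         include_hcl = TRUE, ions = NULL) {
  stopifnot(all(c("solute", "V") %in% names(salt_values)))
  if (is.null(salt_values$SE)) salt_values$SE <- 1
  if (!include_hcl) salt_values <- salt_values[salt_values$solute != "HCl", ]
  requested <- ions
  all_ions <- unique(c(ion_order(),
                       setdiff(unlist(lapply(registry, function(s)
                         s$components$ion)), "H")))
  X <- matrix(0, nrow(salt_values), length(all_ions),
              dimnames = list(salt_values$solute, all_ions))
  n_h <- numeric(nrow(salt_values))
  for (i in seq_len(nrow(salt_values))) {
    s <- registry[[salt_values$solute[i]]]
    if (is.null(s)) stop("unknown solute: ", salt_values$solute[i],
                         call. = FALSE)
    for (j in seq_len(nrow(s$components))) {
      ion <- s$components$ion[j]
      if (ion == "H") n_h[i] <- n_h[i] + s$components$n[j]
      else X[i, ion] <- X[i, ion] + s$components$n[j]
    }
  }
  covered <- colSums(X != 0) > 0
  if (is.null(requested)) {
    ions <- all_ions[covered]
  } else {
    if (any(!requested %in% all_ions[covered]))
      stop("ion(s) never observed in any salt: ",
           paste(setdiff(requested, all_ions[covered]), collapse = ", "),
           call. = FALSE)
    ions <- requested
  }
  X <- X[, ions, drop = FALSE]
  # rank and null space of the unconstrained (H+ rows dropped) design
  sv <- svd(X, nv = ncol(X))
  sv$d <- c(sv$d, rep(0, ncol(X) - length(sv$d)))
  rk <- sum(sv$d > max(dim(X)) * max(sv$d) * 1e-12)
  nullsp <- if (rk < ncol(X)) sv$v[, (rk + 1):ncol(X), drop = FALSE] else
    matrix(numeric(0), ncol(X), 0)
  structure(list(design = X, n_h = n_h, values = salt_values, ions = ions,
                 rank = rk, null_space = nullsp,
                 has_hcl = any(n_h > 0)),
            class = "additivity_system")
}

#' @export
print.additivity_system <- function(x, ...) {
  cat(sprintf("<additivity_system> %d equations, %d ions, rank %d%s\n",
              nrow(x$design), ncol(x$design), x$rank,
              if (x$has_hcl) " (+ proton constraint rows)" else ""))
  invisible(x)
}

#' Single-ion volumes from salt volumes at one temperature
#'
#' Weighted least squares (weights 1/SE^2) on the additivity system
#' after substituting the fixed proton volume [hplus_volume()] into any
#' acid rows. SEs come from the weighted normal-equations covariance
#' scaled by the residual mean square.
#'
#' @param system an [build_system()] result.
#' @param T temperature (degC) at which the proton constraint is
#'   evaluated.
#' @param weighted use 1/SE^2 weights (default) or unweighted.
#' @return data.frame with columns `ion`, `V`, `SE`, plus attributes
#'   `residuals` (per salt) and `covariance`.
#' @export
decompose_at_T <- function(system, T, weighted = TRUE) {
  stopifnot(inherits(system, "additivity_system"))
  X <- system$design
  y <- system$values$V - system$n_h * hplus_volume(T)
  w <- if (weighted) 1 / system$values$SE^2 else rep(1, nrow(X))
  # constrained-system rank check (proton already substituted out)
  if (qr(X)$rank < ncol(X)) {
    stop("constrained additivity system is rank deficient (rank ",
         qr(X)$rank, " < ", ncol(X), ")", call. = FALSE)
  }
  sw <- sqrt(w)
  fit <- stats::lm.fit(X * sw, y * sw)
  est <- fit$coefficients
  dof <- max(nrow(X) - ncol(X), 1)
  s2 <- sum(fit$residuals^2) / dof
  covm <- chol2inv(chol(crossprod(X * sw))) * s2
  dimnames(covm) <- list(system$ions, system$ions)
  out <- data.frame(ion = system$ions, V = unname(est),
                    SE = sqrt(diag(covm)), row.names = NULL)
  attr(out, "residuals") <- data.frame(
    solute = rownames(X), residual = unname(fit$residuals) / sw)
  attr(out, "covariance") <- covm
  attr(out, "T") <- T
  out
}

# ---- grand global fit on raw density data --------------------------------

#' Global ionic fit on raw density data
#'
#' One nonlinear least squares over the complete density campaign:
#' parameters are `(V_ref, alpha, beta)` for each of the eight ions plus
#' one `delta_d0` per (solute, series, temperature); each solute's
#' apparent volume is assembled by ionic additivity
#' \eqn{\sum_i n_i V_i(T)} (the proton fixed to [hplus_model()]) plus
#' the Debye-Hueckel term. Residuals are unweighted density residuals
#' (single instrument, constant precision).
#'
#' @param records density records for the full campaign (all solutes).
#' @param registry solute registry, default [salt_registry()].
#' @param ctx a [reference_context()].
#' @param per_temperature_offsets as in [fit_salt()].
#' @return object of class `ion_volume_set`: per-ion
#'   [thermal_volume_model()]s with covariance, the fixed proton model,
#'   SE tables, and fit diagnostics.
#' @export
global_ionic_fit <- function(records, registry = salt_registry(),
                             ctx = reference_context(),
                             per_temperature_offsets = TRUE) {
  validate_density_records(records)
  ions <- ion_order()
  solutes <- unique(records$solute)
  unknown <- setdiff(solutes, names(registry))
  if (length(unknown)) stop("unknown solute(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  if (length(unique(records$temperature_C)) < 3)
    stop("global ionic fit needs records at >= 3 temperatures", call. = FALSE)

  # per-record stoichiometry rows
  S <- matrix(0, nrow(records), length(ions), dimnames = list(NULL, ions))
  n_h <- numeric(nrow(records))
  omega <- M <- numeric(nrow(records))
  for (so in solutes) {
    idx <- records$solute == so
    sp <- registry[[so]]
    omega[idx] <- sp$omega; M[idx] <- sp$M
    for (j in seq_len(nrow(sp$components))) {
      ion <- sp$components$ion[j]
      if (ion == "H") n_h[idx] <- n_h[idx] + sp$components$n[j]
      else S[idx, ion] <- S[idx, ion] + sp$components$n[j]
    }
  }
  covered <- colSums(S != 0) > 0
  if (any(!covered))
    stop("ion(s) not covered by any solute in the records: ",
         paste(ions[!covered], collapse = ", "), call. = FALSE)
  if (!any(n_h > 0)) {
    # no acid rows: additivity alone is rank deficient along the charges
    sv <- svd(unique(S))
    rk <- sum(sv$d > 1e-9 * max(sv$d))
    if (rk < length(ions))
      stop("design without acid rows is rank deficient; null direction ",
           "proportional to the ionic charges - include HCl records or a ",
           "proton constraint", call. = FALSE)
  }

  key <- paste(records$solute, .dd0_key(records, per_temperature_offsets),
               sep = "|")
  keys <- unique(key)
  key_idx <- match(key, keys)
  m <- records$molality_mol_kg
  T <- records$temperature_C
  d_obs <- records$density_g_cm3
  d0 <- d0_ref(T)
  dh <- dh_term(m, omega, T, ctx)
  dt <- T - ctx$t_ref
  vh <- n_h * predict(hplus_model(ctx$t_ref), T)

  n_ion <- length(ions)
  nglob <- 3L * n_ion
  par_names <- c(paste0(rep(ions, each = 3), ":", c("V_ref", "alpha", "beta")),
                 paste0("dd0:", keys))

  # start: per-record apparent volumes -> unweighted additivity solve
  v_app <- apparent_rhs(d_obs, d0, m, M) - dh - vh
  v0 <- stats::lm.fit(S, v_app)$coefficients
  par0 <- numeric(nglob + length(keys))
  par0[seq(1, nglob, by = 3)] <- v0

  vions <- function(par) {
    # V_i(T) per record, summed with stoichiometry
    vr <- par[seq(1, nglob, by = 3)]
    al <- par[seq(2, nglob, by = 3)]
    be <- par[seq(3, nglob, by = 3)]
    drop(S %*% vr) + drop(S %*% al) * dt + drop(S %*% be) * dt^2
  }
  pred <- function(par) {
    vpsi <- vions(par) + vh + dh
    d0p <- d0 + par[nglob + key_idx]
    denom <- 1 - m * (M - d0p * vpsi) / 1e3
    d0p / denom
  }
  resid_fn <- function(par) d_obs - pred(par)
  jac_fn <- function(par) {
    vpsi <- vions(par) + vh + dh
    d0p <- d0 + par[nglob + key_idx]
    denom <- 1 - m * (M - d0p * vpsi) / 1e3
    dd_dvpsi <- -d0p * (m * d0p / 1e3) / denom^2
    dd_dd0p <- 1 / denom - d0p * (m * vpsi / 1e3) / denom^2
    J <- matrix(0, length(m), length(par))
    for (i in seq_len(n_ion)) {
      base <- dd_dvpsi * S[, i]
      J[, 3 * i - 2] <- base
      J[, 3 * i - 1] <- base * dt
      J[, 3 * i]     <- base * dt^2
    }
    J[cbind(seq_along(m), nglob + key_idx)] <- dd_dd0p
    -J
  }
  fit <- levmar(par0, resid_fn, jac_fn)
  names(fit$par) <- par_names
  covm <- levmar_covariance(fit, nrow(records), par_names)

  models <- stats::setNames(vector("list", n_ion), ions)
  for (i in seq_len(n_ion)) {
    sl <- (3 * i - 2):(3 * i)
    models[[i]] <- thermal_volume_model(
      fit$par[[3 * i - 2]], fit$par[[3 * i - 1]], fit$par[[3 * i]],
      t_ref = ctx$t_ref, covariance = covm[sl, sl])
  }
  dd0 <- data.frame(key = keys,
                    delta_d0 = unname(fit$par[-seq_len(nglob)]),
                    row.names = NULL)
  structure(list(models = models, hplus = hplus_model(ctx$t_ref),
                 method = "global", t_ref = ctx$t_ref,
                 covariance = covm[seq_len(nglob), seq_len(nglob),
                                   drop = FALSE],
                 delta_d0 = dd0,
                 residual_sd = sqrt(fit$rss /
                                      (nrow(records) - length(fit$par))),
                 n_obs = nrow(records)),
            class = "ion_volume_set")
}

#' Summarize an ion volume set at chosen temperatures
#'
#' @param object an `ion_volume_set` (from [global_ionic_fit()] or
#'   [ion_set_from_models()]).
#' @param temperatures degC.
#' @param ... unused.
#' @return data.frame, ions x temperatures (values and SEs), plus
#'   derivative rows (`dV/dT` at `t_ref`, the quadratic coefficient)
#'   and the extremum temperature, mirroring the layout of the ionic
#'   results table.
#' @export
summary.ion_volume_set <- function(object, temperatures = seq(20, 40, 5),
                                   ...) {
  rows <- lapply(c(list(Hplus = object$hplus), object$models), function(mod) {
    pr <- predict(mod, temperatures, se = TRUE)
    c(stats::setNames(pr$V, paste0("V", temperatures)),
      stats::setNames(pr$SE, paste0("SE", temperatures)),
      dVdT_1e3 = 1e3 * mod$alpha,
      d2VdT2_1e3 = 1e3 * mod$beta,
      T_extr = as.numeric(extremum_temperature(mod)))
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(ion = c("H", names(object$models)), out)
  rownames(out) <- NULL
  out
}

#' @export
print.ion_volume_set <- function(x, ...) {
  cat(sprintf("<ion_volume_set> %d ions + fixed H+ (method: %s)\n",
              length(x$models), x$method))
  print(summary(x, temperatures = x$t_ref), digits = 4)
  invisible(x)
}

#' Assemble an ion volume set from explicit models
#'
#' Mostly used to inject ground truth into the synthetic generators.
#'
#' @param models named list of [thermal_volume_model()]s for the eight
#'   ions (canonical order enforced).
#' @param t_ref reference temperature.
#' @return `ion_volume_set`.
#' @export
ion_set_from_models <- function(models, t_ref = 25) {
  stopifnot(setequal(names(models), ion_order()))
  structure(list(models = models[ion_order()], hplus = hplus_model(t_ref),
                 method = "explicit", t_ref = t_ref,
                 covariance = NULL, delta_d0 = NULL,
                 residual_sd = NA_real_, n_obs = 0L),
            class = "ion_volume_set")
}

# ---- cation/anion curvature contrast -------------------------------------

#' Test the cation-vs-anion curvature contrast
#'
#' Compares the quadratic thermal-expansion coefficients (beta) of
#' cations and anions. The default is a two-sided z-test on the
#' difference of inverse-variance-weighted group means (a reconstruction
#' of the published contrast, whose exact test is unnamed); a Welch
#' t-test on the unweighted group means is available as a variant.
#'
#' @param beta named numeric vector of quadratic coefficients, or an
#'   `ion_volume_set` (betas and SEs are then extracted).
#' @param se standard errors matching `beta` (ignored for an
#'   `ion_volume_set`).
#' @param cations,anions names defining the two groups.
#' @param method `"z"` (weighted, default) or `"welch"`.
#' @return an object of class `htest`.
#' @export
curvature_contrast <- function(beta, se = NULL,
                               cations = c("Li", "Na", "K", "Mg"),
                               anions = c("Cl", "Br", "I", "SO4"),
                               method = c("z", "welch")) {
  method <- match.arg(method)
  if (inherits(beta, "ion_volume_set")) {
    set <- beta
    beta <- vapply(set$models, `[[`, numeric(1), "beta")
    se <- vapply(set$models, function(m) sqrt(m$covariance[3, 3]), numeric(1))
  }
  stopifnot(!is.null(names(beta)), all(c(cations, anions) %in% names(beta)))
  if (length(cations) < 2 || length(anions) < 2)
    stop("need >= 2 ions per group", call. = FALSE)
  bc <- beta[cations]; ba <- beta[anions]
  if (method == "z") {
    sc <- se[cations]; sa <- se[anions]
    if (any(!is.finite(c(sc, sa))) || any(c(sc, sa) <= 0))
      stop("degenerate test: all betas need finite positive SEs", call. = FALSE)
    wc <- 1 / sc^2; wa <- 1 / sa^2
    mc <- sum(wc * bc) / sum(wc); ma <- sum(wa * ba) / sum(wa)
    v <- 1 / sum(wc) + 1 / sum(wa)
    z <- (mc - ma) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
    res <- list(statistic = c(z = z), p.value = p,
                estimate = c(`weighted mean beta (cations)` = mc,
                             `weighted mean beta (anions)` = ma),
                method = "Weighted z-test on quadratic thermal-expansion coefficients",
                data.name = "cation vs anion beta",
                alternative = "two.sided")
    class(res) <- "htest"
  } else {
    res <- stats::t.test(bc, ba)
    res$method <- paste("Welch", res$method)
  }
  attr(res, "signs") <- c(cations_positive = sum(bc > 0),
                          cations = length(bc),
                          anions_negative = sum(ba < 0),
                          anions = length(ba))
  res
}
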