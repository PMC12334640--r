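# JSON/CSV report rendering. An analysis session in R is the intended
# interface; these helpers serialize fit objects for provenance and for
# downstream tooling.

.ionvol_meta <- function() {
  list(package = "ionvol",
       version = as.character(utils::packageVersion("ionvol")))
}

#' Serialize a salt fit as a JSON report
#'
#' Parameters with SEs, the full covariance, per-series solvent
#' offsets, the AIC table, the F-test p-value and residual diagnostics,
#' plus package provenance.
#'
#' @param fit a [fit_salt()] result.
#' @param path output path; when `NULL` the report list is returned
#'   instead of written.
#' @export
write_salt_report <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "salt_fit"))
  m <- fit$model
  rep <- list(
    meta = .ionvol_meta(),
    solute = fit$solute,
    selected_order = fit$order,
    parameters = list(
      V_ref = m$v_ref, alpha = m$alpha, beta = m$beta, T_ref = m$t_ref,
      se = sqrt(diag(m$covariance))),
    covariance = m$covariance,
    delta_d0 = fit$delta_d0,
    aic = as.list(fit$aic),
    f_test_p = fit$f_test_p,
    residual_sd = fit$residual_sd,
    instrument_sd = 7e-6,
    extremum_T = as.numeric(extremum_temperature(m)),
    n_obs = fit$n_obs)
  if (is.null(path)) return(rep)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Serialize an ion volume set as a JSON report
#'
#' @param set an `ion_volume_set`.
#' @param path output path; `NULL` returns the report list.
#' @param temperatures evaluation temperatures for the table block.
#' @export
write_ion_report <- function(set, path = NULL,
                             temperatures = seq(20, 40, 5)) {
  stopifnot(inherits(set, "ion_volume_set"))
  ions <- names(set$models)
  rep <- list(
    meta = .ionvol_meta(),
    method = set$method,
    ion_columns = stats::setNames(as.list(seq_along(ions) - 1L), ions),
    models = lapply(set$models, function(m)
      list(V_ref = m$v_ref, alpha = m$alpha, beta = m$beta,
           T_ref = m$t_ref,
           se = if (!is.null(m$covariance)) sqrt(diag(m$covariance)),
           extremum_T = as.numeric(extremum_temperature(m)))),
    hplus = list(V_ref = set$hplus$v_ref, alpha = set$hplus$alpha,
                 beta = set$hplus$beta, T_ref = set$hplus$t_ref),
    table = summary(set, temperatures = temperatures),
    residual_sd = set$residual_sd,
    n_obs = set$n_obs)
  if (is.null(path)) return(rep)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
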