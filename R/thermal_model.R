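# Quadratic temperature dependence of a partial molar volume:
# V(T) = V_ref + alpha*(T - T_ref) + beta*(T - T_ref)^2

#' Thermal volume model
#'
#' A partial molar volume with quadratic temperature dependence
#' \deqn{V(T) = V_{ref} + \alpha (T - T_{ref}) + \beta (T - T_{ref})^2}
#' where `alpha` is the thermal expansion coefficient at `t_ref` and
#' `beta` the quadratic coefficient (half the second derivative).
#'
#' @param v_ref volume at the reference temperature (cm^3/mol).
#' @param alpha cm^3/mol/K.
#' @param beta cm^3/mol/K^2 (quadratic coefficient).
#' @param t_ref reference temperature, degC (default 25).
#' @param covariance optional 3x3 symmetric PSD covariance of
#'   (v_ref, alpha, beta).
#' @return object of class `thermal_volume_model`.
#' @export
thermal_volume_model <- function(v_ref, alpha = 0, beta = 0, t_ref = 25,
                                 covariance = NULL) {
  stopifnot(is.numeric(v_ref), length(v_ref) == 1, is.finite(v_ref))
  if (!is.null(covariance)) {
    covariance <- as.matrix(covariance)
    stopifnot(identical(dim(covariance), c(3L, 3L)))
    if (max(abs(covariance - t(covariance))) > 1e-8 * max(1, abs(covariance)))
      stop("covariance must be symmetric", call. = FALSE)
    if (min(eigen(covariance, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-8 * max(1, abs(covariance)))
      stop("covariance must be positive semidefinite", call. = FALSE)
  }
  structure(list(v_ref = v_ref, alpha = alpha, beta = beta, t_ref = t_ref,
                 covariance = covariance),
            class = "thermal_volume_model")
}

#' Evaluate a thermal volume model
#'
#' @param object a [thermal_volume_model()].
#' @param T temperatures (degC).
#' @param se logical; also return the propagated standard error (needs a
#'   stored covariance).
#' @param ... unused.
#' @return volumes in cm^3/mol, or a data.frame with columns `T`, `V`,
#'   `SE` when `se = TRUE`.
#' @export
predict.thermal_volume_model <- function(object, T, se = FALSE, ...) {
  dt <- T - object$t_ref
  v <- object$v_ref + object$alpha * dt + object$beta * dt^2
  if (!se) return(v)
  if (is.null(object$covariance))
    stop("model carries no covariance; cannot propagate SE", call. = FALSE)
  G <- cbind(1, dt, dt^2)
  vr <- rowSums((G %*% object$covariance) * G)
  data.frame(T = T, V = v, SE = sqrt(pmax(vr, 0)))
}

#' Temperature of the volume extremum
#'
#' Vertex of the quadratic temperature dependence,
#' \eqn{T_{extr} = T_{ref} - \alpha / (2\beta)}; `NA` when `beta = 0`
#' (a linear model has no extremum). An attribute `extrapolated` flags
#' vertices outside the studied 20--40 degC window.
#'
#' @param model a [thermal_volume_model()].
#' @param window temperature range regarded as interpolation.
#' @return extremum temperature (degC) or `NA_real_`.
#' @export
extremum_temperature <- function(model, window = c(20, 40)) {
  if (model$beta == 0) return(NA_real_)
  t_ex <- model$t_ref - model$alpha / (2 * model$beta)
  structure(t_ex, extrapolated = (t_ex < window[1] || t_ex > window[2]),
            maximum = model$beta < 0)
}

#' @export
print.thermal_volume_model <- function(x, ...) {
  cat(sprintf(
    "<thermal_volume_model> V(%g degC) = %.4g cm^3/mol, alpha = %.4g, beta = %.4g\n",
    x$t_ref, x$v_ref, x$alpha, x$beta))
  invisible(x)
}
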