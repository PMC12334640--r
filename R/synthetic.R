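# Generators reproducing the statistical structure the estimators assume:
# densimeter campaigns (closed-form density curves + Gaussian instrument
# noise + per-series solvent offsets) and ion-centered solvation
# snapshots (rigid waters with controlled radial shells and
# orientation distributions). They target the structure the analysis
# consumes, not full physical realism.

#' Design of a synthetic densimeter campaign
#'
#' Defaults mirror the studied campaign: an 8-point geometric molality
#' grid spanning 1e-3--3e-2 mol/kg (serial dilutions), temperatures
#' 20--40 degC in 5 degC steps, three dilution series per solute,
#' Gaussian instrument noise of sd 7e-6 g/cm^3, and per-(series, T)
#' solvent-density offsets drawn from N(0, 1e-5) truncated at
#' |2e-5| g/cm^3.
#'
#' @param molality molality grid (mol/kg).
#' @param temperatures degC.
#' @param n_series dilution series per solute.
#' @param noise_sd instrument noise sd (g/cm^3).
#' @param delta_d0_sd sd of the per-(series, T) solvent offsets.
#' @param delta_d0_max truncation bound on |delta_d0|.
#' @return object of class `density_design`.
#' @export
density_design <- function(molality = exp(seq(log(1e-3), log(3e-2),
                                              length.out = 8)),
                           temperatures = seq(20, 40, by = 5),
                           n_series = 3,
                           noise_sd = 7e-6,
                           delta_d0_sd = 1e-5,
                           delta_d0_max = 2e-5) {
  stopifnot(length(molality) >= 1, all(molality > 0),
            length(temperatures) >= 1, n_series >= 1,
            noise_sd >= 0, delta_d0_sd >= 0, delta_d0_max >= 0)
  structure(list(molality = molality, temperatures = temperatures,
                 n_series = as.integer(n_series), noise_sd = noise_sd,
                 delta_d0_sd = delta_d0_sd, delta_d0_max = delta_d0_max),
            class = "density_design")
}

# truncated normal via rejection (bounds are ~2 sd, cheap)
.rtnorm <- function(n, sd, bound) {
  if (sd == 0 || bound == 0) return(numeric(n))
  x <- stats::rnorm(n, 0, sd)
  while (any(bad <- abs(x) > bound)) x[bad] <- stats::rnorm(sum(bad), 0, sd)
  x
}

#' Generate a synthetic density dataset for one solute
#'
#' Densities lie on the closed-form model curve
#' ([predict_density()]) with the injected thermal volume model, plus
#' one solvent offset per (series, temperature) and Gaussian instrument
#' noise. Ground truth is attached as attribute `"truth"` for recovery
#' tests.
#'
#' @param salt a [salt_spec()].
#' @param truth the injected [thermal_volume_model()].
#' @param design a [density_design()].
#' @param ctx a [reference_context()].
#' @param seed optional integer seed (local RNG state).
#' @return validated record data.frame
#'   (see [validate_density_records()]).
#' @export
gen_density_dataset <- function(salt, truth, design = density_design(),
                                ctx = reference_context(), seed = NULL) {
  stopifnot(inherits(salt, "salt_spec"),
            inherits(truth, "thermal_volume_model"),
            inherits(design, "density_design"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  grid <- expand.grid(molality_mol_kg = design$molality,
                      temperature_C = design$temperatures,
                      series = seq_len(design$n_series),
                      KEEP.OUT.ATTRS = FALSE)
  key <- paste(grid$series, grid$temperature_C, sep = "@")
  keys <- unique(key)
  dd0 <- stats::setNames(.rtnorm(length(keys), design$delta_d0_sd,
                                 design$delta_d0_max), keys)
  d <- predict_density(grid$molality_mol_kg, grid$temperature_C, truth,
                       salt, delta_d0 = dd0[key], ctx = ctx) +
    stats::rnorm(nrow(grid), 0, design$noise_sd)
  rec <- data.frame(solute = salt$name,
                    series_id = sprintf("%s-s%d", salt$name, grid$series),
                    temperature_C = grid$temperature_C,
                    molality_mol_kg = grid$molality_mol_kg,
                    density_g_cm3 = unname(d))
  attr(rec, "truth") <- list(model = truth,
                             delta_d0 = data.frame(key = keys,
                                                   delta_d0 = unname(dd0)))
  validate_density_records(rec)
  rec
}

#' Generate the full synthetic study
#'
#' Assembles per-solute thermal models by ionic additivity from an ion
#' volume set (HCl = fixed proton model + Cl-), then generates one
#' density dataset per solute. The default design yields
#' 17 x 3 x 8 x 5 = 2040 records.
#'
#' @param ion_truth an `ion_volume_set`; default built from the printed
#'   ionic table ([table2_ion_models()]).
#' @param design a [density_design()].
#' @param registry solute registry.
#' @param ctx a [reference_context()].
#' @param seed optional integer seed.
#' @return record data.frame for all solutes, with attribute `"truth"`
#'   (the ion set and the per-solute salt models).
#' @export
gen_full_study <- function(ion_truth = ion_set_from_models(table2_ion_models()),
                           design = density_design(),
                           registry = salt_registry(),
                           ctx = reference_context(), seed = NULL) {
  stopifnot(inherits(ion_truth, "ion_volume_set"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  salt_truth <- lapply(registry, function(sp) {
    v <- a <- b <- 0
    for (j in seq_len(nrow(sp$components))) {
      ion <- sp$components$ion[j]; n <- sp$components$n[j]
      mod <- if (ion == "H") ion_truth$hplus else ion_truth$models[[ion]]
      if (is.null(mod)) stop("ion truth missing ion: ", ion, call. = FALSE)
      v <- v + n * mod$v_ref; a <- a + n * mod$alpha; b <- b + n * mod$beta
    }
    thermal_volume_model(v, a, b, t_ref = ion_truth$t_ref)
  })
  recs <- lapply(names(registry), function(so)
    gen_density_dataset(registry[[so]], salt_truth[[so]], design, ctx))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "truth") <- list(ion_set = ion_truth, salt_models = salt_truth)
  out
}

# ---- solvation snapshots --------------------------------------------------

#' Design of a synthetic solvation trajectory
#'
#' Defaults emulate the simulated systems: a 25 A cubic periodic box
#' holding one ion and ~507 rigid waters, sampled over 1e4 frames.
#' Modes:
#' \describe{
#'   \item{isotropic}{waters uniform in the box, orientations uniform
#'     (ideal gas) - the null model for map-flatness checks.}
#'   \item{hard-core}{uniform outside an excluded-volume radius `r_ex`;
#'     with `count = "poisson"` the per-frame count is Poisson so the
#'     fluid is a homogeneous Poisson process - the analytic reference
#'     for the V(N) estimator (E[V(N)] = N/rho + 4/3 pi r_ex^3).}
#'   \item{cation-like / anion-like / bulk-like}{Gaussian radial shells
#'     with mode-specific orientation peaks: oxygens toward a cation
#'     (theta near 180 deg in the first shell), one hydrogen toward an
#'     anion (theta near 60 deg), and a donor/acceptor mixture for bulk
#'     water.}
#' }
#'
#' @param box_edge A.
#' @param n_waters waters per frame (fixed-count modes).
#' @param n_frames frames.
#' @param mode see above.
#' @param r_ex excluded-volume radius (A), `< box_edge/4`.
#' @param rho target number density (A^-3); when given for
#'   hard-core/isotropic modes it overrides `n_waters`.
#' @param count `"fixed"` or `"poisson"` per-frame water count.
#' @param shells data.frame(radius, width, occupancy, theta_peak,
#'   theta_sd) overriding the mode's default shell structure.
#' @return object of class `solvation_design`.
#' @export
solvation_design <- function(box_edge = 25, n_waters = 507, n_frames = 1e4,
                             mode = c("isotropic", "hard-core",
                                      "cation-like", "anion-like",
                                      "bulk-like"),
                             r_ex = 0, rho = NULL,
                             count = c("fixed", "poisson"),
                             shells = NULL) {
  mode <- match.arg(mode)
  count <- match.arg(count)
  # structured modes exclude bulk water from the first-shell region by
  # default, so shells are not diluted by uniform background
  if (missing(r_ex))
    r_ex <- switch(mode, `cation-like` = 3.2, `anion-like` = 4.0,
                   `bulk-like` = 3.4, 0)
  stopifnot(box_edge > 0, n_frames >= 1, r_ex >= 0)
  if (r_ex >= box_edge / 4)
    stop("r_ex must be < box_edge/4", call. = FALSE)
  if (is.null(shells)) {
    shells <- switch(mode,
      `cation-like` = data.frame(
        radius = c(2.4, 4.5), width = c(0.15, 0.35),
        occupancy = c(6, 14), theta_peak = c(170, 150),
        theta_sd = c(12, 35)),
      `anion-like` = data.frame(
        radius = c(3.2, 5.0), width = c(0.2, 0.4),
        occupancy = c(7, 16), theta_peak = c(55, 85),
        theta_sd = c(15, 45)),
      `bulk-like` = data.frame(
        radius = c(2.8, 2.8), width = c(0.2, 0.2),
        occupancy = c(2, 2), theta_peak = c(150, 45),
        theta_sd = c(12, 20)),
      NULL)
  }
  if (!is.null(shells) && sum(shells$occupancy) > n_waters)
    stop("requested shell waters exceed n_waters", call. = FALSE)
  free_vol <- box_edge^3 - (4 / 3) * pi * r_ex^3
  if (!is.null(rho)) {
    if (!mode %in% c("isotropic", "hard-core"))
      stop("rho override is only meaningful for isotropic/hard-core modes",
           call. = FALSE)
    n_waters <- round(rho * free_vol)
  }
  structure(list(box_edge = box_edge, n_waters = as.integer(n_waters),
                 n_frames = as.integer(n_frames), mode = mode, r_ex = r_ex,
                 rho = n_waters / free_vol, count = count, shells = shells),
            class = "solvation_design")
}

# rigid TIP3P-like internal geometry
.OH <- 0.9572
.HOH_half <- 104.52 / 2 * pi / 180
.LQ <- .OH * cos(.HOH_half)   # O to hydrogen-midpoint distance

# orthonormal frame completing unit vectors u (rows)
.complete_frame <- function(u) {
  a <- matrix(c(1, 0, 0), nrow(u), 3, byrow = TRUE)
  swap <- abs(u[, 1]) > 0.9
  if (any(swap))
    a[swap, ] <- matrix(c(0, 1, 0), sum(swap), 3, byrow = TRUE)
  e1 <- a - u * rowSums(a * u)
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(u[, 2] * e1[, 3] - u[, 3] * e1[, 2],
              u[, 3] * e1[, 1] - u[, 1] * e1[, 3],
              u[, 1] * e1[, 2] - u[, 2] * e1[, 1])
  list(e1 = e1, e2 = e2)
}

# build H1/H2 given oxygen positions, O->Q unit axis
.build_hydrogens <- function(o, axis) {
  fr <- .complete_frame(axis)
  psi <- stats::runif(nrow(o), 0, 2 * pi)
  perp <- fr$e1 * cos(psi) + fr$e2 * sin(psi)
  h1 <- o + .OH * (cos(.HOH_half) * axis + sin(.HOH_half) * perp)
  h2 <- o + .OH * (cos(.HOH_half) * axis - sin(.HOH_half) * perp)
  list(h1 = h1, h2 = h2)
}

# unit O->Q axis at angle theta (deg) from the O->ion direction
.axis_at_theta <- function(o_to_ion_unit, theta_deg) {
  fr <- .complete_frame(o_to_ion_unit)
  phi <- stats::runif(nrow(o_to_ion_unit), 0, 2 * pi)
  th <- theta_deg * pi / 180
  cos(th) * o_to_ion_unit +
    sin(th) * (fr$e1 * cos(phi) + fr$e2 * sin(phi))
}

#' Generate synthetic solvation snapshots
#'
#' Waters are placed according to the design mode (uniform, hard-core,
#' or Gaussian radial shells) around an ion at the box center, with
#' rigid internal geometry (O-H 0.9572 A, H-O-H 104.52 deg) and
#' molecular orientation constructed by aligning the hydrogen-midpoint
#' axis to a sampled ion-O-Q angle with uniform azimuth.
#'
#' @param design a [solvation_design()].
#' @param seed optional integer seed.
#' @param hydrogens generate hydrogens (disable for V(N)-only analyses
#'   to save memory).
#' @return list of [solvation_snapshot()]s.
#' @export
gen_solvation_snapshots <- function(design = solvation_design(), seed = NULL,
                                    hydrogens = TRUE) {
  stopifnot(inherits(design, "solvation_design"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  L <- design$box_edge
  shells <- design$shells
  n_shell <- if (is.null(shells)) 0L else as.integer(sum(shells$occupancy))
  lapply(seq_len(design$n_frames), function(f) {
    n_bulk <- if (design$count == "poisson")
      stats::rpois(1, design$n_waters - n_shell)
    else design$n_waters - n_shell
    # bulk placement: uniform in the box, rejecting the excluded core
    o <- matrix(stats::runif(3 * ceiling(n_bulk * 1.15), -L / 2, L / 2),
                ncol = 3)
    if (design$r_ex > 0) o <- o[rowSums(o^2) > design$r_ex^2, , drop = FALSE]
    while (nrow(o) < n_bulk) {
      extra <- matrix(stats::runif(3 * n_bulk, -L / 2, L / 2), ncol = 3)
      if (design$r_ex > 0)
        extra <- extra[rowSums(extra^2) > design$r_ex^2, , drop = FALSE]
      o <- rbind(o, extra)
    }
    o <- o[seq_len(n_bulk), , drop = FALSE]
    theta <- 180 / pi * acos(stats::runif(n_bulk, -1, 1))
    if (!is.null(shells)) {
      for (s in seq_len(nrow(shells))) {
        k <- shells$occupancy[s]
        r <- abs(stats::rnorm(k, shells$radius[s], shells$width[s]))
        r <- pmin(r, L / 2 - 1e-6)
        u <- matrix(stats::rnorm(3 * k), ncol = 3)
        u <- u / sqrt(rowSums(u^2))
        o_s <- u * r
        th <- stats::rnorm(k, shells$theta_peak[s], shells$theta_sd[s])
        th <- pmin(pmax(th, 0), 180)
        o <- rbind(o_s, o)
        theta <- c(th, theta)
      }
    }
    h1 <- h2 <- NULL
    if (hydrogens) {
      d <- sqrt(rowSums(o^2))
      d[d < 1e-9] <- 1e-9
      to_ion <- -o / d          # ion is at the origin
      axis <- .axis_at_theta(to_ion, theta)
      hh <- .build_hydrogens(o, axis)
      h1 <- hh$h1; h2 <- hh$h2
    }
    solvation_snapshot(L, c(0, 0, 0), o, h1, h2, validate = FALSE)
  })
}
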