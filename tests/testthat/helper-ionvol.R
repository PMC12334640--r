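# shared fixtures and independent oracles

ctx_default <- reference_context()
registry <- salt_registry()

# independent oracle: invert the apparent-volume relation for density by
# root bracketing (never uses predict_density's closed form)
bisect_density <- function(v_psi, m, T, M, delta_d0 = 0) {
  d0 <- d0_ref(T) + delta_d0
  f <- function(d) (M / d0 - 1e3 / (d * d0) * (d - d0) / m) - v_psi
  stats::uniroot(f, c(0.9, 1.2), tol = 1e-14)$root
}

# independent oracle: vertex angle at B of triangle A-B-C via the law of
# cosines
angle_law_of_cosines <- function(a, b, c) {
  ab <- sqrt(sum((a - b)^2)); cb <- sqrt(sum((c - b)^2))
  ac <- sqrt(sum((a - c)^2))
  acos((ab^2 + cb^2 - ac^2) / (2 * ab * cb)) * 180 / pi
}

# random rigid motion (rotation + translation) applied to a snapshot
random_rigid_snapshot <- function(s) {
  theta <- stats::runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(theta[1]), -sin(theta[1])),
              c(0, sin(theta[1]), cos(theta[1])))
  Rz <- rbind(c(cos(theta[2]), -sin(theta[2]), 0),
              c(sin(theta[2]), cos(theta[2]), 0), c(0, 0, 1))
  R <- Rx %*% Rz
  tr <- stats::runif(3, -3, 3)
  mv <- function(m) sweep(m %*% t(R), 2, -tr)
  solvation_snapshot(s$box_edge, drop(R %*% s$ion) + tr,
                     mv(s$o), if (!is.null(s$h1)) mv(s$h1),
                     if (!is.null(s$h2)) mv(s$h2), validate = FALSE)
}

# chi-square goodness of fit of bin counts against expected proportions,
# restricted to bins with expected count >= min_expected
chisq_gof <- function(counts, expected_prop, min_expected = 20) {
  E <- sum(counts) * expected_prop / sum(expected_prop)
  keep <- E >= min_expected
  stat <- sum((counts[keep] - E[keep])^2 / E[keep])
  stats::pchisq(stat, sum(keep) - 1, lower.tail = FALSE)
}

nacl_truth <- thermal_volume_model(16.43, 87e-3, -2.6e-3, t_ref = 25)
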