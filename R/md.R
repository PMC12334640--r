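# Trajectory-analysis stage: per-water (d, theta) orientation records,
# 2D solvation maps, cumulative sphere-volume curves V(N) and the
# global-slope intercept estimator of ionic partial molar volume.
#
# All pair geometry uses the minimum image convention in a cubic
# periodic box; water internal geometry is unwrapped relative to its
# oxygen before any angle is computed.

min_image <- function(x, box) x - box * round(x / box)

#' Construct a solvation snapshot
#'
#' @param box_edge cubic box edge (Angstrom).
#' @param ion ion position, length-3 (Angstrom).
#' @param o,h1,h2 n x 3 matrices of water oxygen / hydrogen positions;
#'   `h1`/`h2` may be `NULL` for oxygen-only snapshots (sufficient for
#'   V(N) analysis, not for orientation analysis).
#' @param reference_atom_offset displacement from the stored ion position
#'   to the reference atom used for distances (zero except polyatomic
#'   ions, e.g. the sulfur of sulfate).
#' @param validate check O-H bond lengths (0.8--1.3 A after minimum-image
#'   unwrapping).
#' @return object of class `solvation_snapshot`.
#' @export
solvation_snapshot <- function(box_edge, ion, o, h1 = NULL, h2 = NULL,
                               reference_atom_offset = c(0, 0, 0),
                               validate = TRUE) {
  o <- matrix(as.numeric(o), ncol = 3)
  stopifnot(length(ion) == 3, box_edge > 0, all(is.finite(o)))
  if (!is.null(h1)) {
    h1 <- matrix(as.numeric(h1), ncol = 3)
    h2 <- matrix(as.numeric(h2), ncol = 3)
    stopifnot(nrow(h1) == nrow(o), nrow(h2) == nrow(o),
              all(is.finite(h1)), all(is.finite(h2)))
    if (validate) {
      for (h in list(h1, h2)) {
        bl <- sqrt(rowSums(min_image(h - o, box_edge)^2))
        if (any(bl < 0.8 | bl > 1.3))
          stop("O-H bond length outside (0.8, 1.3) A after unwrapping ",
               "(water ", which(bl < 0.8 | bl > 1.3)[1], ")", call. = FALSE)
      }
    }
  }
  structure(list(box_edge = box_edge, ion = as.numeric(ion),
                 reference_atom_offset = as.numeric(reference_atom_offset),
                 o = o, h1 = h1, h2 = h2),
            class = "solvation_snapshot")
}

#' @export
print.solvation_snapshot <- function(x, ...) {
  cat(sprintf("<solvation_snapshot> box %g A, %d waters%s\n",
              x$box_edge, nrow(x$o),
              if (is.null(x$h1)) " (oxygen only)" else ""))
  invisible(x)
}

# ---- trajectory exchange formats -----------------------------------------

#' Write snapshots as multi-frame XYZ
#'
#' Dialect: atom-count line; comment line carrying `box=<edge A>`;
#' records `<label> x y z` with labels `ION`, `OW`, `HW1`, `HW2`.
#'
#' @param snapshots list of [solvation_snapshot()]s.
#' @param path output file.
#' @export
write_xyz <- function(snapshots, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(snapshots)) {
    s <- snapshots[[i]]
    nw <- nrow(s$o)
    has_h <- !is.null(s$h1)
    nat <- 1L + nw * (if (has_h) 3L else 1L)
    writeLines(c(sprintf("%d", nat),
                 sprintf("box=%.6f frame=%d", s$box_edge, i)), con)
    writeLines(sprintf("ION %.6f %.6f %.6f", s$ion[1], s$ion[2], s$ion[3]),
               con)
    fmt <- function(lab, m, j) sprintf("%s %.6f %.6f %.6f", lab,
                                       m[j, 1], m[j, 2], m[j, 3])
    for (j in seq_len(nw)) {
      writeLines(fmt("OW", s$o, j), con)
      if (has_h) {
        writeLines(fmt("HW1", s$h1, j), con)
        writeLines(fmt("HW2", s$h2, j), con)
      }
    }
  }
  invisible(path)
}

#' Read solvation snapshots
#'
#' @param path multi-frame XYZ (dialect of [write_xyz()]) or
#'   multi-MODEL PDB with atom names `ION`/`OW`/`HW1`/`HW2`; for PDB the
#'   box edge is read from the CRYST1 record.
#' @param format `"xyz"` or `"pdb"`.
#' @param validate passed to [solvation_snapshot()].
#' @return list of [solvation_snapshot()]s. Malformed frames raise
#'   errors naming the frame index.
#' @export
read_snapshots <- function(path, format = c("xyz", "pdb"),
                           validate = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "xyz") .read_xyz(path, validate) else .read_pdb(path, validate)
}

.parse_frame_atoms <- function(lab, xyz, frame, box, validate) {
  ion_i <- which(lab == "ION")
  if (length(ion_i) != 1L)
    stop("frame ", frame, ": expected exactly one ION record", call. = FALSE)
  o_i <- which(lab == "OW"); h1_i <- which(lab == "HW1")
  h2_i <- which(lab == "HW2")
  if (length(h1_i) != length(o_i) || length(h2_i) != length(o_i))
    stop("frame ", frame, ": unpaired water hydrogens (",
         length(o_i), " OW, ", length(h1_i), " HW1, ", length(h2_i),
         " HW2)", call. = FALSE)
  has_h <- length(h1_i) > 0
  tryCatch(
    solvation_snapshot(box, xyz[ion_i, ], xyz[o_i, , drop = FALSE],
                       if (has_h) xyz[h1_i, , drop = FALSE],
                       if (has_h) xyz[h2_i, , drop = FALSE],
                       validate = validate),
    error = function(e) stop("frame ", frame, ": ", conditionMessage(e),
                             call. = FALSE))
}

.read_xyz <- function(path, validate) {
  lines <- readLines(path)
  out <- list()
  i <- 1L; frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    frame <- frame + 1L
    if (is.na(nat) || i + 1L + nat > length(lines) + 0L)
      stop("frame ", frame, ": malformed atom-count line", call. = FALSE)
    comment <- lines[i + 1L]
    bm <- regmatches(comment, regexec("box=([0-9.eE+-]+)", comment))[[1]]
    if (length(bm) < 2)
      stop("frame ", frame, ": comment line carries no box=<edge> field",
           call. = FALSE)
    box <- as.numeric(bm[2])
    rec <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(rec), "[[:space:]]+")
    lab <- vapply(toks, `[[`, "", 1)
    xyz <- matrix(as.numeric(unlist(lapply(toks, `[`, 2:4))),
                  ncol = 3, byrow = TRUE)
    if (any(!is.finite(xyz)))
      stop("frame ", frame, ": non-numeric coordinates", call. = FALSE)
    out[[frame]] <- .parse_frame_atoms(lab, xyz, frame, box, validate)
    i <- i + 2L + nat
  }
  out
}

.read_pdb <- function(path, validate) {
  lines <- readLines(path)
  cry <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cry)) stop("PDB carries no CRYST1 record (box unknown)",
                         call. = FALSE)
  box <- as.numeric(substr(cry[1], 7, 15))
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (!length(starts)) { starts <- 1L; ends <- length(lines) }
  if (length(starts) != length(ends))
    stop("unbalanced MODEL/ENDMDL records", call. = FALSE)
  lapply(seq_along(starts), function(frame) {
    seg <- lines[starts[frame]:ends[frame]]
    at <- grep("^(ATOM|HETATM)", seg, value = TRUE)
    lab <- trimws(substr(at, 13, 16))
    xyz <- cbind(as.numeric(substr(at, 31, 38)),
                 as.numeric(substr(at, 39, 46)),
                 as.numeric(substr(at, 47, 54)))
    .parse_frame_atoms(lab, xyz, frame, box, validate)
  })
}

# ---- orientation records and maps ----------------------------------------

#' Per-water orientation records
#'
#' For every water whose minimum-image ion-oxygen distance is at most
#' `r_max`, returns the distance `d` and the angle `theta` (degrees) at
#' the oxygen vertex between the O->ion and O->Q displacement vectors,
#' where Q is the midpoint of the two hydrogens.
#'
#' @param snapshot a [solvation_snapshot()] with hydrogens.
#' @param r_max sphere radius (A); must not exceed `box_edge/2`
#'   (minimum-image validity).
#' @param q_mode `"h_midpoint"` (default) or `"com"` (full water center
#'   of mass, 16:1:1 weights).
#' @return data.frame with columns `d`, `theta`.
#' @export
orientation_records <- function(snapshot, r_max = 12.5,
                                q_mode = c("h_midpoint", "com")) {
  q_mode <- match.arg(q_mode)
  s <- snapshot
  if (is.null(s$h1))
    stop("snapshot carries no hydrogens; orientation undefined", call. = FALSE)
  if (r_max > s$box_edge / 2)
    stop("r_max exceeds box_edge/2: sphere leaves the minimum-image cell",
         call. = FALSE)
  ion <- s$ion + s$reference_atom_offset
  r_oi <- min_image(matrix(ion, nrow(s$o), 3, byrow = TRUE) - s$o,
                    s$box_edge)
  d <- sqrt(rowSums(r_oi^2))
  keep <- d <= r_max
  if (!any(keep)) return(data.frame(d = numeric(0), theta = numeric(0)))
  h1 <- min_image(s$h1 - s$o, s$box_edge)
  h2 <- min_image(s$h2 - s$o, s$box_edge)
  r_oq <- if (q_mode == "h_midpoint") (h1 + h2) / 2 else
    (h1 * 1.008 + h2 * 1.008) / (15.999 + 2 * 1.008)
  num <- rowSums(r_oi * r_oq)
  den <- d * sqrt(rowSums(r_oq^2))
  ct <- pmin(1, pmax(-1, num / den))
  data.frame(d = d[keep], theta = acos(ct[keep]) * 180 / pi)
}

#' 2D distance-orientation density map
#'
#' Histograms orientation records on a (d, theta) grid. In raw mode the
#' map holds counts per bin; in corrected mode counts are divided by the
#' bin-integrated spherical Jacobian
#' \eqn{\int d^2 \,\mathrm{d}d \int \sin\theta \,\mathrm{d}\theta}
#' and normalized so that the mean over occupied far-field bins is one,
#' making bulk-like regions flat at ~1.
#'
#' @param records data.frame from [orientation_records()] (rows from
#'   several snapshots may be concatenated).
#' @param d_bins,theta_bins strictly increasing bin edges (A, degrees).
#' @param corrected apply the Jacobian correction.
#' @param far_field_min lower `d` edge from which bins count as far
#'   field for normalization; defaults to 2/3 of the largest `d` edge.
#' @return object of class `solvation_map`: list with `map` (matrix,
#'   d-bins x theta-bins), bin edges, `jacobian` and `n_records`.
#' @export
density_map <- function(records, d_bins = seq(0, 12.5, by = 0.25),
                        theta_bins = seq(0, 180, by = 5),
                        corrected = FALSE, far_field_min = NULL) {
  if (nrow(records) == 0) stop("no orientation records", call. = FALSE)
  if (is.unsorted(d_bins, strictly = TRUE) ||
      is.unsorted(theta_bins, strictly = TRUE))
    stop("bin edges must be strictly increasing", call. = FALSE)
  di <- cut(records$d, d_bins, include.lowest = TRUE, labels = FALSE)
  ti <- cut(records$theta, theta_bins, include.lowest = TRUE, labels = FALSE)
  ok <- !is.na(di) & !is.na(ti)
  counts <- matrix(0, length(d_bins) - 1, length(theta_bins) - 1)
  tb <- table(factor(di[ok], levels = seq_len(nrow(counts))),
              factor(ti[ok], levels = seq_len(ncol(counts))))
  counts[] <- as.numeric(tb)
  jac <- outer(diff(d_bins^3) / 3,
               -diff(cospi(theta_bins / 180)))
  map <- counts
  if (corrected) {
    map <- counts / jac
    if (is.null(far_field_min)) far_field_min <- 2 / 3 * max(d_bins)
    ff <- d_bins[-length(d_bins)] >= far_field_min
    occ <- map[ff, , drop = FALSE]
    occ <- occ[counts[ff, , drop = FALSE] > 0]
    if (length(occ)) map <- map / mean(occ)
  }
  structure(list(map = map, counts = counts, d_bins = d_bins,
                 theta_bins = theta_bins, jacobian = jac,
                 corrected = corrected, n_records = sum(ok)),
            class = "solvation_map")
}

#' @export
print.solvation_map <- function(x, ...) {
  cat(sprintf("<solvation_map> %dx%d bins, %d records%s\n",
              nrow(x$map), ncol(x$map), x$n_records,
              if (x$corrected) " (Jacobian-corrected)" else " (raw counts)"))
  invisible(x)
}

# ---- V(N) curves and the intercept estimator -----------------------------

#' Cumulative sphere-volume curve
#'
#' Per frame, sorts the minimum-image ion-oxygen distances and records
#' \eqn{V_N = (4/3)\pi d_{(N)}^3}, the volume of the sphere bordering
#' the N closest waters; aggregates mean and standard error across
#' frames.
#'
#' @param snapshots list of [solvation_snapshot()]s.
#' @param n_max largest N; the sphere must stay within minimum-image
#'   validity (`mean d_(N) < box/2`) and every frame must contain
#'   `n_max` waters within `box/2`.
#' @param keep_frames retain the per-frame V matrix (attribute
#'   `"frames"`) so [fit_vn_global()] can propagate frame-to-frame
#'   uncertainty.
#' @return object of class `vn_curve`: data.frame with columns `N`,
#'   `V_mean`, `V_se`, `n_frames`.
#' @export
vn_curve <- function(snapshots, n_max, keep_frames = TRUE) {
  stopifnot(length(snapshots) >= 1, n_max >= 1)
  box <- snapshots[[1]]$box_edge
  r_valid <- box / 2
  Vf <- matrix(NA_real_, length(snapshots), n_max)
  for (f in seq_along(snapshots)) {
    s <- snapshots[[f]]
    ion <- s$ion + s$reference_atom_offset
    dx <- min_image(s$o - matrix(ion, nrow(s$o), 3, byrow = TRUE),
                    s$box_edge)
    d <- sqrt(rowSums(dx^2))
    d <- d[d <= r_valid]
    if (length(d) < n_max)
      stop("frame ", f, ": only ", length(d), " waters within box/2; ",
           "admissible N_max = ", length(d), call. = FALSE)
    Vf[f, ] <- (4 / 3) * pi * sort(d)[seq_len(n_max)]^3
  }
  vm <- colMeans(Vf)
  if (any(vm >= (4 / 3) * pi * r_valid^3))
    stop("n_max too large for the box: mean radius at N = ",
         which(vm >= (4 / 3) * pi * r_valid^3)[1],
         " exceeds box/2; reduce n_max", call. = FALSE)
  vse <- if (nrow(Vf) > 1) apply(Vf, 2, stats::sd) / sqrt(nrow(Vf)) else
    rep(0, n_max)
  out <- data.frame(N = seq_len(n_max), V_mean = vm, V_se = vse,
                    n_frames = nrow(Vf))
  if (keep_frames) attr(out, "frames") <- Vf
  class(out) <- c("vn_curve", "data.frame")
  out
}

#' Global-slope intercept estimator of ionic volume
#'
#' Joint linear least squares \eqn{V = a N + c_{ion}} over several V(N)
#' curves with one shared slope `a` (the molar volume of a bulk water
#' molecule) and one intercept per ion (the ion's own partial molar
#' volume). The `n_skip` waters closest to the ion - the perturbed
#' solvation shells - are disregarded. When per-frame curves are
#' retained, standard errors propagate the frame-to-frame covariance of
#' the whole curve through the estimator's linear weights; otherwise
#' ordinary regression SEs are reported with a caveat (curve points are
#' strongly correlated across N).
#'
#' @param curves named list of [vn_curve()]s (one per ion).
#' @param n_skip number of proximal waters disregarded (default 35).
#' @param ctx a [reference_context()] for the cm^3/mol conversion.
#' @return list with `slope` (A^3), `slope_se`, `intercepts`
#'   (data.frame: ion, intercept_A3, se_A3, intercept_cm3mol, se_cm3mol),
#'   `slope_cm3mol`, `diagnostics`.
#' @export
fit_vn_global <- function(curves, n_skip = 35, ctx = reference_context()) {
  stopifnot(is.list(curves), length(curves) >= 1, !is.null(names(curves)))
  usable <- lapply(curves, function(cv) cv[cv$N > n_skip, , drop = FALSE])
  if (any(vapply(usable, nrow, 0L) < 5))
    stop("every curve needs >= 5 usable points with N > n_skip",
         call. = FALSE)
  ions <- names(curves)
  dat <- do.call(rbind, Map(function(cv, nm)
    data.frame(ion = nm, N = cv$N, V = cv$V_mean), usable, ions))
  dat$ion <- factor(dat$ion, levels = ions)
  ind <- vapply(ions, function(i) as.numeric(dat$ion == i),
                numeric(nrow(dat)))
  X <- cbind(ind, N = dat$N)
  colnames(X) <- c(ions, "slope")
  if (nrow(X) <= ncol(X)) stop("fewer points than parameters", call. = FALSE)
  fit <- stats::lm.fit(X, dat$V)
  est <- fit$coefficients
  W <- solve(crossprod(X), t(X))   # estimator weights: theta = W %*% V
  # frame-propagated SEs where per-frame curves are available
  have_frames <- all(vapply(curves, function(cv)
    !is.null(attr(cv, "frames")), TRUE))
  if (have_frames) {
    var_theta <- numeric(length(est))
    for (i in seq_along(ions)) {
      rows <- which(dat$ion == ions[i])
      Vf <- attr(curves[[i]], "frames")[, usable[[i]]$N, drop = FALSE]
      for (k in seq_along(est)) {
        comb <- Vf %*% W[k, rows]
        var_theta[k] <- var_theta[k] + stats::var(comb) / nrow(Vf)
      }
    }
    se <- sqrt(var_theta)
    se_method <- "frame-propagated"
  } else {
    s2 <- sum(fit$residuals^2) / (nrow(X) - ncol(X))
    se <- sqrt(diag(chol2inv(chol(crossprod(X)))) * s2)
    se_method <- "regression (correlated residuals; interpret with care)"
  }
  names(se) <- names(est)
  intercepts <- data.frame(
    ion = ions,
    intercept_A3 = unname(est[ions]), se_A3 = unname(se[ions]),
    intercept_cm3mol = unname(est[ions]) * ctx$avogadro_scale,
    se_cm3mol = unname(se[ions]) * ctx$avogadro_scale,
    row.names = NULL)
  rss_by_ion <- tapply(fit$residuals^2, dat$ion, sum)
  list(slope = unname(est["slope"]), slope_se = unname(se["slope"]),
       slope_cm3mol = unname(est["slope"]) * ctx$avogadro_scale,
       intercepts = intercepts,
       diagnostics = list(se_method = se_method, n_points = nrow(X),
                          rss_by_ion = rss_by_ion))
}
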