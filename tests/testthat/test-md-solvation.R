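test_that("XYZ writer/reader round trip and validation", {
  snaps <- gen_solvation_snapshots(solvation_design(n_waters = 3,
                                                    n_frames = 2),
                                   seed = 1)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(snaps, path)
  back <- read_snapshots(path)
  expect_length(back, 2)
  expect_equal(nrow(back[[1]]$o), 3)
  for (f in 1:2) {
    expect_lt(max(abs(back[[f]]$o - snaps[[f]]$o)), 1e-6)
    expect_lt(max(abs(back[[f]]$h1 - snaps[[f]]$h1)), 1e-6)
    expect_equal(back[[f]]$box_edge, snaps[[f]]$box_edge)
  }

  # box missing from the comment line
  lines <- readLines(path)
  no_box <- lines
  no_box[2] <- "frame without box"
  path2 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(no_box, path2)
  expect_error(read_snapshots(path2), "box")

  # unpaired hydrogens reported with the frame index
  drop_h <- lines[-5]  # remove one HW line from frame 1
  drop_h[1] <- as.character(as.integer(lines[1]) - 1L)
  path3 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(drop_h, path3)
  expect_error(read_snapshots(path3), "frame 1.*unpaired")
})

test_that("multi-MODEL PDB reader parses frames and box", {
  s <- gen_solvation_snapshots(solvation_design(n_waters = 2, n_frames = 1),
                               seed = 2)[[1]]
  pdb <- c(
    sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1", 25, 25, 25),
    "MODEL     1",
    sprintf("HETATM    1 ION  ION A   1    %8.3f%8.3f%8.3f",
            s$ion[1], s$ion[2], s$ion[3]),
    unlist(lapply(1:2, function(j) c(
      sprintf("ATOM  %5d OW   HOH A%4d    %8.3f%8.3f%8.3f", 3 * j - 1, j + 1,
              s$o[j, 1], s$o[j, 2], s$o[j, 3]),
      sprintf("ATOM  %5d HW1  HOH A%4d    %8.3f%8.3f%8.3f", 3 * j, j + 1,
              s$h1[j, 1], s$h1[j, 2], s$h1[j, 3]),
      sprintf("ATOM  %5d HW2  HOH A%4d    %8.3f%8.3f%8.3f", 3 * j + 1, j + 1,
              s$h2[j, 1], s$h2[j, 2], s$h2[j, 3])))),
    "ENDMDL")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, path)
  back <- read_snapshots(path, format = "pdb")
  expect_length(back, 1)
  expect_equal(back[[1]]$box_edge, 25)
  expect_lt(max(abs(back[[1]]$o - s$o)), 1e-3)
})

test_that("boundary-straddling waters are valid only after unwrapping", {
  # oxygen near +x face, hydrogens wrapped to the -x face:
  # unwrapped H sits at o + (0.57, +-0.76, 0), bond length 0.95 A
  o <- matrix(c(12.4, 0, 0), 1)
  h1 <- matrix(c(12.4 + 0.57 - 25, 0.76, 0), 1)
  h2 <- matrix(c(12.4 + 0.57 - 25, -0.76, 0), 1)
  raw_bond <- sqrt(sum((h1 - o)^2))
  expect_gt(raw_bond, 1.3)  # nonsense without minimum image
  s <- solvation_snapshot(25, c(0, 0, 0), o, h1, h2)  # validates unwrapped
  rec <- orientation_records(s, r_max = 12.5)
  expect_equal(rec$d, 12.4)
  # genuinely broken geometry is rejected
  expect_error(solvation_snapshot(25, c(0, 0, 0), o, h1 * 0.9, h2),
               "O-H bond")
})

test_that("orientation angles match geometry oracles", {
  # collinear: hydrogens away from the ion -> theta = 180
  s <- solvation_snapshot(25, c(0, 0, 0), matrix(c(3, 0, 0), 1),
                          matrix(c(3.57, 0.76, 0), 1),
                          matrix(c(3.57, -0.76, 0), 1))
  rec <- orientation_records(s)
  expect_equal(rec$d, 3)
  expect_equal(rec$theta, 180)
  # mirrored toward the ion -> theta = 0
  s0 <- solvation_snapshot(25, c(0, 0, 0), matrix(c(3, 0, 0), 1),
                           matrix(c(2.43, 0.76, 0), 1),
                           matrix(c(2.43, -0.76, 0), 1))
  expect_equal(orientation_records(s0)$theta, 0)

  # arbitrary coordinates against the law-of-cosines oracle
  set.seed(3)
  snaps <- gen_solvation_snapshots(solvation_design(n_waters = 20,
                                                    n_frames = 3), seed = 3)
  for (s in snaps) {
    rec <- orientation_records(s)
    q <- (s$h1 + s$h2) / 2
    d_all <- sqrt(rowSums(s$o^2))
    keep <- d_all <= 12.5
    oracle <- vapply(which(keep), function(j)
      angle_law_of_cosines(s$ion, s$o[j, ], q[j, ]), numeric(1))
    expect_equal(rec$theta, oracle, tolerance = 1e-9)
  }
  expect_error(orientation_records(snaps[[1]], r_max = 13), "box_edge/2")
})

test_that("orientation geometry is invariant under rigid motion and wrapping", {
  snaps <- gen_solvation_snapshots(solvation_design(n_waters = 30,
                                                    n_frames = 2), seed = 4)
  set.seed(9)
  for (s in snaps) {
    base <- orientation_records(s)
    # rotation is only a symmetry of the periodic cell inside the
    # inscribed sphere: confine waters to |r| < box/2 before moving
    keep <- sqrt(rowSums(s$o^2)) < s$box_edge / 2 - 1.5
    conf <- solvation_snapshot(s$box_edge, s$ion, s$o[keep, ],
                               s$h1[keep, ], s$h2[keep, ],
                               validate = FALSE)
    b0 <- orientation_records(conf, r_max = 10)
    moved <- random_rigid_snapshot(conf)
    rec2 <- orientation_records(moved, r_max = 10)
    expect_equal(nrow(rec2), nrow(b0))
    o <- order(b0$d); o2 <- order(rec2$d)
    expect_equal(b0$d[o], rec2$d[o2], tolerance = 1e-9)
    expect_equal(b0$theta[o], rec2$theta[o2], tolerance = 1e-6)
    # shifting any water by a full box period changes nothing
    shifted <- s
    shifted$o[1, 1] <- shifted$o[1, 1] + s$box_edge
    shifted$h1[1, 1] <- shifted$h1[1, 1] + s$box_edge
    shifted$h2[1, 1] <- shifted$h2[1, 1] + s$box_edge
    rec3 <- orientation_records(shifted)
    ob <- order(base$d)
    expect_equal(base$d[ob], rec3$d[order(rec3$d)], tolerance = 1e-9)
    expect_equal(base$theta[ob], rec3$theta[order(rec3$d)],
                 tolerance = 1e-7)
  }
})

test_that("density maps: binning, Jacobian correction, degenerate input", {
  rec1 <- data.frame(d = rep(5.1, 10), theta = rep(90.1, 10))
  mp <- density_map(rec1, d_bins = 0:13, theta_bins = seq(0, 180, 30))
  expect_equal(sum(mp$map > 0), 1)
  expect_equal(sum(mp$map), 10)
  expect_error(density_map(rec1[0, ]), "records")
  expect_error(density_map(rec1, d_bins = c(1, 1, 2)), "increasing")

  snaps <- gen_solvation_snapshots(solvation_design(mode = "isotropic",
                                                    n_frames = 150),
                                   seed = 5)
  rec <- do.call(rbind, lapply(snaps, orientation_records))
  # corrected map of an ideal gas is flat
  mp_c <- density_map(rec, d_bins = seq(2, 12.5, 1.5),
                      theta_bins = seq(0, 180, 20), corrected = TRUE)
  flat_p <- chisq_gof(mp_c$counts, mp_c$jacobian)
  expect_gt(flat_p, 0.01)
  occupied <- mp_c$map[mp_c$counts > 0]
  expect_lt(max(abs(occupied - 1)), 0.25)
  # raw map follows the d^2 sin(theta) profile: marginal over theta at
  # fixed d-band proportional to sin integrals
  mp_r <- density_map(rec, d_bins = c(9, 12), theta_bins = seq(0, 180, 15))
  p_theta <- chisq_gof(mp_r$map[1, ], -diff(cospi(seq(0, 180, 15) / 180)))
  expect_gt(p_theta, 0.01)
})

test_that("structured generators show the expected shell orientations", {
  first_shell <- function(mode, cut) {
    snaps <- gen_solvation_snapshots(solvation_design(mode = mode,
                                                      n_frames = 40),
                                     seed = 6)
    rec <- do.call(rbind, lapply(snaps, orientation_records))
    rec[rec$d < cut, ]
  }
  cat_fs <- first_shell("cation-like", 2.9)
  expect_gt(mean(cat_fs$theta > 120), 0.8)  # oxygens toward the cation
  an_fs <- first_shell("anion-like", 3.8)
  expect_gt(mean(an_fs$theta < 90), 0.8)    # one H toward the anion
  expect_lt(abs(median(an_fs$theta) - 55), 10)
  blk <- first_shell("bulk-like", 3.3)
  expect_gt(mean(blk$theta > 120), 0.3)     # donor population
  expect_gt(mean(blk$theta < 60), 0.3)      # acceptor population
})

test_that("V(N) curves: formula, monotonicity and bounds", {
  s <- solvation_snapshot(25, c(0, 0, 0),
                          rbind(c(1, 0, 0), c(0, 2, 0), c(0, 0, 3)))
  cv <- vn_curve(list(s), 3)
  expect_equal(cv$V_mean, (4 / 3) * pi * c(1, 8, 27))
  expect_equal(cv$V_se, rep(0, 3))
  expect_error(vn_curve(list(s), 4), "admissible")

  snaps <- gen_solvation_snapshots(solvation_design(mode = "hard-core",
                                                    r_ex = 2, rho = 0.0334,
                                                    n_frames = 30),
                                   seed = 7, hydrogens = FALSE)
  cv <- vn_curve(snaps, 100)
  expect_true(all(diff(cv$V_mean) > 0))
  expect_true(all(cv$V_se >= 0))
})

test_that("global V(N) fit recovers hard-core fluid parameters", {
  rho <- 0.0334
  mk <- function(r_ex, seed) {
    des <- solvation_design(mode = "hard-core", r_ex = r_ex, rho = rho,
                            n_frames = 1500, count = "poisson")
    vn_curve(gen_solvation_snapshots(des, seed = seed, hydrogens = FALSE),
             120)
  }
  curves <- list(small = mk(2, 21), big = mk(3, 22))
  fit <- fit_vn_global(curves, n_skip = 35)
  expect_equal(fit$slope, 1 / rho, tolerance = 0.02)
  z_slope <- (fit$slope - 1 / rho) / fit$slope_se
  expect_lt(abs(z_slope), 3)
  expected <- (4 / 3) * pi * c(2, 3)^3
  z_int <- (fit$intercepts$intercept_A3 - expected) / fit$intercepts$se_A3
  expect_lt(max(abs(z_int)), 3)
  # vanishing core -> intercept near zero
  c0 <- list(pt = mk(1e-6, 23))
  f0 <- fit_vn_global(c0, n_skip = 35)
  expect_lt(abs(f0$intercepts$intercept_A3[1]),
            3 * f0$intercepts$se_A3[1] + 1)
  # the published bulk-water slope converts to ~18.08 cm^3/mol
  expect_equal(aa3_to_cm3mol(30.023), 18.08, tolerance = 1e-3)
  expect_error(fit_vn_global(list(a = curves$small[1:38, ])), "usable")
})
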