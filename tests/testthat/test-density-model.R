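test_that("Debye-Hueckel term limits, monotonicity and validation", {
  expect_equal(dh_term(0, 1, 25, ctx_default), 0)
  m <- c(1e-4, 1e-3, 1e-2, 3e-2)
  expect_true(all(diff(dh_term(m, 1, 25, ctx_default)) > 0))
  expect_true(all(dh_term(0.01, c(1, 3, 4), 25, ctx_default) ==
                    cummax(dh_term(0.01, c(1, 3, 4), 25, ctx_default))))
  # small-m limit: Av * omega^(3/2) * sqrt(m) to first order
  for (om in c(1, 3, 4)) {
    lim <- av_slope(25, ctx_default) * om^1.5 * sqrt(1e-6)
    expect_equal(dh_term(1e-6, om, 25, ctx_default) / lim, 1,
                 tolerance = 2e-3)
  }
  expect_error(dh_term(-1e-3, 1, 25, ctx_default), "non-negative")
})

test_that("apparent-volume relation and closed-form inversion agree", {
  M <- registry$NaCl$M
  expect_equal(apparent_rhs(0.9971, 0.9971, 0.01, M), M / 0.9971)
  expect_error(apparent_rhs(0.998, 0.997, 0, M), "singular")

  # exact round trip for all solutes over the studied design
  for (s in registry) {
    mod <- thermal_volume_model(12.3, 0.05, -2e-3)
    for (T in c(20, 30, 40)) {
      m <- c(1e-3, 5e-3, 3e-2)
      d <- predict_density(m, T, mod, s, delta_d0 = 1.5e-5, ctx_default)
      v <- apparent_rhs(d, d0_ref(T) + 1.5e-5, m, s$M) -
        dh_term(m, s$omega, T, ctx_default)
      expect_lt(max(abs(v - predict(mod, T))), 1e-9)
    }
  }

  # independent bisection oracle for the inversion
  vpsi <- predict(nacl_truth, 25) + dh_term(0.03, 1, 25, ctx_default)
  d_oracle <- bisect_density(vpsi, 0.03, 25, registry$NaCl$M)
  d_closed <- predict_density(0.03, 25, nacl_truth, registry$NaCl,
                              ctx = ctx_default)
  expect_equal(d_closed, d_oracle, tolerance = 1e-10)
  expect_equal(round(d_closed, 5), 0.99830)
})

test_that("predicted density behaves physically", {
  # m = 0 returns the offset solvent density exactly
  expect_equal(predict_density(0, 25, nacl_truth, registry$NaCl,
                               delta_d0 = 2e-5), d0_ref(25) + 2e-5)
  # near-linear density-molality relation over the studied range
  mgso4 <- thermal_volume_model(-4.71, 73e-3, -1.5e-3)
  for (case in list(list(registry$NaCl, nacl_truth),
                    list(registry$MgSO4, mgso4))) {
    m <- seq(0, 0.03, length.out = 51)
    d <- predict_density(m, 25, case[[2]], case[[1]], ctx = ctx_default)
    chord <- d[1] + (d[51] - d[1]) * m / 0.03
    expect_lt(max(abs(d - chord)), 0.01 * (d[51] - d[1]))
  }
  # MgSO4 (larger M - d0*V) rises faster than NaCl
  dn <- predict_density(0.03, 25, nacl_truth, registry$NaCl,
                        ctx = ctx_default) - d0_ref(25)
  dm <- predict_density(0.03, 25, mgso4, registry$MgSO4,
                        ctx = ctx_default) - d0_ref(25)
  expect_gt(dm, dn)
  # solution denser than pure water for every studied solute
  t1 <- table1_volumes()
  for (i in seq_len(nrow(t1))) {
    s <- registry[[t1$solute[i]]]
    mod <- thermal_volume_model(t1$V[i], t1$alpha_1e3[i] * 1e-3,
                                t1$beta_1e3[i] * 1e-3)
    d <- predict_density(c(1e-3, 3e-2), 25, mod, s, ctx = ctx_default)
    expect_true(all(d > d0_ref(25)))
  }
})

test_that("global salt fit recovers noise-free truth exactly", {
  des <- density_design(noise_sd = 0, delta_d0_sd = 0)
  rec <- gen_density_dataset(registry$NaCl, nacl_truth, des, ctx_default,
                             seed = 1)
  fit <- fit_salt(rec, registry$NaCl, ctx_default,
                  model_order = "quadratic")
  expect_lt(abs(fit$model$v_ref - 16.43), 1e-6)
  expect_lt(abs(fit$model$alpha - 87e-3), 1e-6)
  expect_lt(abs(fit$model$beta + 2.6e-3), 1e-6)
  expect_lt(max(abs(fit$delta_d0$delta_d0)), 1e-9)

  # nonzero injected offsets are recovered too
  des2 <- density_design(noise_sd = 0)
  rec2 <- gen_density_dataset(registry$NaCl, nacl_truth, des2, ctx_default,
                              seed = 2)
  truth_dd0 <- attr(rec2, "truth")$delta_d0
  fit2 <- fit_salt(rec2, registry$NaCl, ctx_default,
                   model_order = "quadratic")
  key <- sub("^NaCl-s", "", fit2$delta_d0$key)
  expect_equal(fit2$delta_d0$delta_d0[match(truth_dd0$key, key)],
               truth_dd0$delta_d0, tolerance = 1e-8)
})

test_that("fit precision matches the instrument on study-like data", {
  # Monte-Carlo calibration at the study design and noise
  set.seed(42)
  reps <- 200
  stats <- vapply(seq_len(reps), function(i) {
    rec <- gen_density_dataset(registry$NaCl, nacl_truth, density_design(),
                               ctx_default)
    f <- fit_salt(rec, registry$NaCl, ctx_default,
                  model_order = "quadratic")
    c(f$model$v_ref, sqrt(f$model$covariance[1, 1]), f$residual_sd,
      max(abs(f$delta_d0$delta_d0)))
  }, numeric(4))
  # bias below 0.02 cm^3/mol; SE of the order printed for this salt (~0.1)
  expect_lt(abs(mean(stats[1, ]) - 16.43), 0.02)
  expect_gt(mean(stats[2, ]), 0.05)
  expect_lt(mean(stats[2, ]), 0.2)
  # residual sd consistent with the declared instrument precision
  expect_equal(mean(stats[3, ]), 7e-6, tolerance = 0.15)
  # fitted offsets stay below the generating ceiling (+ noise allowance)
  expect_lt(max(stats[4, ]), 2e-5 + 1e-5)
})

test_that("model selection is calibrated under the linear null", {
  lin_truth <- thermal_volume_model(16.43, 87e-3, 0, t_ref = 25)
  set.seed(7)
  reps <- 200
  picked_quad <- vapply(seq_len(reps), function(i) {
    rec <- gen_density_dataset(registry$NaCl, lin_truth, density_design(),
                               ctx_default)
    fit_salt(rec, registry$NaCl, ctx_default, model_order = "auto")$order ==
      "quadratic"
  }, logical(1))
  # F-test at alpha = 0.05 (AND AIC): selection rate must be near or
  # below the nominal size; 18/200 bounds the 5% rate at ~3 sigma
  expect_lte(sum(picked_quad), 18)
  # the choice of order barely moves V_ref
  rec <- gen_density_dataset(registry$NaCl, nacl_truth, density_design(),
                             ctx_default, seed = 11)
  vl <- fit_salt(rec, registry$NaCl, ctx_default, "linear")$model$v_ref
  vq <- fit_salt(rec, registry$NaCl, ctx_default, "quadratic")$model$v_ref
  expect_lt(abs(vl - vq), 0.25)
})

test_that("extremum temperature and identifiability diagnostics", {
  # literature proton model peaks near -24 degC
  ext <- extremum_temperature(hplus_model())
  expect_equal(as.numeric(ext), -23.53, tolerance = 0.01)
  expect_true(attr(ext, "extrapolated"))
  expect_true(is.na(extremum_temperature(thermal_volume_model(10, 0.1, 0))))
  expect_equal(as.numeric(extremum_temperature(
    thermal_volume_model(10, 0, -1e-3, t_ref = 25))), 25)

  # single-temperature designs are flagged by parameter name
  des1 <- density_design(temperatures = 25)
  rec1 <- gen_density_dataset(registry$NaCl, nacl_truth, des1, ctx_default,
                              seed = 3)
  expect_error(fit_salt(rec1, registry$NaCl, ctx_default, "linear"),
               "alpha")
  des2 <- density_design(temperatures = c(20, 30))
  rec2 <- gen_density_dataset(registry$NaCl, nacl_truth, des2, ctx_default,
                              seed = 3)
  expect_error(fit_salt(rec2, registry$NaCl, ctx_default, "quadratic"),
               "beta")
})

test_that("record validation and CSV round trip", {
  rec <- gen_density_dataset(registry$KCl,
                             thermal_volume_model(27.22, 66e-3, 0),
                             density_design(), ctx_default, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_density_csv(rec, path)
  back <- read_density_csv(path)
  expect_equal(back$density_g_cm3, rec$density_g_cm3, tolerance = 1e-12)

  bad <- rec
  bad$molality_mol_kg[3] <- -1
  expect_error(validate_density_records(bad), "row")
  expect_warning(validate_density_records(
    transform(rec, temperature_C = temperature_C + 30)), "window")
})
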