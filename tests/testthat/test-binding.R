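test_that("the binding isotherm matches the brute-force solver and its limits", {
  E0 <- 0.1; dE <- 0.5
  for (R_T in c(2e-8, 2e-7, 2e-6)) {
    for (K_A in 10^(4:9)) {
      P <- 10^seq(-9, -3, length.out = 25)
      e_model <- efret_model(P, E0, dE, K_A, R_T)
      e_oracle <- E0 + dE * oracle_complex_conc(P, R_T, K_A) / R_T
      expect_lt(max(abs(e_model - e_oracle)), 1e-10)
    }
  }
  # exact limit at zero protein
  expect_identical(efret_model(0, E0, dE, 1e7, 2e-7), E0)
  # saturation limit
  expect_equal(efret_model(1e9, E0, dE, 1e7, 2e-7), E0 + dE,
               tolerance = 1e-12)
  # stoichiometric (infinite-affinity) limit: E = E0 + dE * min(P,R)/R
  P <- c(0, 5e-8, 1e-7, 2e-7, 1e-6)
  expect_equal(efret_model(P, E0, dE, 1e18, 2e-7),
               E0 + dE * pmin(P, 2e-7) / 2e-7, tolerance = 1e-6)

  expect_error(efret_model(-1e-9, E0, dE, 1e7, 2e-7), "non-negative")
  expect_error(efret_model(1e-9, E0, dE, -1, 2e-7), "K_A")
})

test_that("fit_fret recovers noise-free parameters and flags degeneracy", {
  g <- gen_fret_curve(noise_sd = 0, seed = 3)
  fit <- fit_fret(g$data)
  expect_equal(fit$E0, g$truth$E0, tolerance = 1e-6)
  expect_equal(fit$dE, g$truth$dE, tolerance = 1e-6)
  expect_equal(fit$K_A, g$truth$K_A, tolerance = 1e-4)
  expect_true(fit$ka_identifiable)
  expect_false(fit$dE_degenerate)
  expect_equal(fit$fitted, g$data$E_FRET, tolerance = 1e-8)

  # stoichiometric regime: curve shape carries no affinity information
  gs <- gen_fret_curve(K_A = 1e12, noise_sd = 0.005, seed = 4)
  fs <- fit_fret(gs$data)
  expect_false(fs$ka_identifiable)

  # flat titration: dE degenerate, affinity unidentifiable
  gf <- gen_fret_curve(dE = 0, noise_sd = 5e-4, seed = 5)
  ff <- fit_fret(gf$data)
  expect_true(ff$dE_degenerate)
  expect_false(ff$ka_identifiable)

  expect_error(fit_fret(fret_titration(c(0, 1e-8, 1e-7), c(.1, .2, .3), 2e-7)),
               ">= 4")
})

test_that("FRET TSV round-trips through the reader", {
  path <- tempfile(fileext = ".tsv")
  g <- gen_fret_curve(noise_sd = 0.01, seed = 8, path = path)
  d <- read_fret_tsv(path)
  expect_equal(d$P_T, g$data$P_T, tolerance = 1e-9)
  expect_equal(d$E_FRET, g$data$E_FRET, tolerance = 1e-9)
  expect_equal(d$R_T, g$data$R_T)

  noheader <- tempfile(fileext = ".tsv")
  writeLines(c("P_T_molar\tE_FRET", "0\t0.1"), noheader)
  expect_error(read_fret_tsv(noheader), "R_T_molar")
})

test_that("ITC heats obey enthalpy conservation on a low-displacement schedule", {
  # 40 x 0.5 ul into 200 ul keeps displaced-volume losses ~1%; with a large
  # affinity and excess titrant the summed heat approaches dH * n * M0 * V0
  exp0 <- itc_experiment(rep(0.5e-6, 40), cell_conc = 20e-6,
                         syringe_conc = 400e-6, cell_vol = 200e-6)
  dH <- -12000; n <- 1
  q <- itc_one_site_heats(exp0, dH, 1e9, n)
  total <- sum(q)
  expect_equal(total, dH * n * 20e-6 * 200e-6, tolerance = 0.01)
  # heats have the sign of dH and decay toward zero past saturation
  expect_true(all(q <= 0))
  expect_lt(abs(q[40]), abs(q[1]) / 100)
})

test_that("fit_itc recovers parameters and derives thermodynamics exactly", {
  g <- gen_itc_series(noise_sd = 0, seed = 2)
  fit <- fit_itc(g$exp)
  expect_equal(fit$dH, g$truth$dH, tolerance = 1e-6)
  expect_equal(fit$K, g$truth$K, tolerance = 1e-6)
  expect_equal(fit$n, g$truth$n, tolerance = 1e-6)
  # derived identities, R = 1.9872 cal / (mol K), T = 298 K
  expect_identical(fit$temperature, 298)
  expect_equal(fit$dG, -1.9872 * 298 * log(fit$K), tolerance = 1e-15)
  expect_equal(fit$dS, (fit$dH - fit$dG) / 298, tolerance = 1e-15)
  expect_equal(fit$Kd, 1 / fit$K, tolerance = 1e-15)

  expect_error(fit_itc(itc_experiment(rep(1e-6, 6), heats = NULL,
                                      cell_conc = 2e-5, syringe_conc = 2e-4)),
               "no measured heats")
  short <- gen_itc_series(inj_vol = rep(2e-6, 4), noise_sd = 0, seed = 1)
  expect_error(fit_itc(short$exp), ">= 5")
})

test_that("ITC TSV round-trips and the experiment constructor validates", {
  path <- tempfile(fileext = ".tsv")
  g <- gen_itc_series(noise_sd = 1e-7, seed = 6, path = path)
  e <- read_itc_tsv(path)
  expect_equal(e$heats, g$exp$heats, tolerance = 1e-6)
  expect_equal(e$cell_conc, 20e-6)
  expect_equal(e$syringe_conc, 200e-6)
  expect_equal(e$temperature, 298)

  expect_error(itc_experiment(rep(30e-6, 10), cell_conc = 2e-5,
                              syringe_conc = 2e-4, cell_vol = 200e-6),
               "exceeds")
  expect_error(itc_experiment(c(-1e-6, 1e-6), cell_conc = 2e-5,
                              syringe_conc = 2e-4))
})
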