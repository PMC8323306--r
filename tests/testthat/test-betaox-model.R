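test_that("all rates vanish without substrates and clamped species stay put", {
  ps <- bx_parameter_set()
  st <- model_state(ps, palmitoylCoA_cyt = 0, malonylCoA = 0)
  expect_true(all(reaction_rates(st, ps) == 0))
  d <- time_derivatives(st, ps)
  expect_true(all(d == 0))

  st2 <- model_state(ps, palmitoylCoA_cyt = 3, malonylCoA = 0.1,
                     acylCoA_C16 = 1)
  d2 <- time_derivatives(st2, ps)
  expect_identical(unname(d2["palmitoylCoA_cyt"]), 0)
  expect_identical(unname(d2["malonylCoA"]), 0)
})

test_that("a lone substrate reduces the shared denominator to Michaelis-Menten", {
  ps <- bx_parameter_set()
  for (a16 in c(0.5, 2, 20)) {
    st <- model_state(ps, acylCoA_C16 = a16)
    v <- reaction_rates(st, ps)
    km <- ps$km$VLCAD[["C16"]]
    expect_equal(unname(v["VLCAD.C16"]),
                 ps$vol_factor * ps$vmax[["VLCAD"]] * a16 / (km + a16),
                 tolerance = 1e-12)
    # LCAD shares the same lone substrate
    km_l <- ps$km$LCAD[["C16"]]
    expect_equal(unname(v["LCAD.C16"]),
                 ps$vol_factor * ps$vmax[["LCAD"]] * a16 / (km_l + a16),
                 tolerance = 1e-12)
  }
})

test_that("malonyl-CoA strictly inhibits the CPT1B rate over an (S, M) grid", {
  ps <- bx_parameter_set()
  for (S in c(0.1, 0.5, 1, 5, 10)) {
    prev <- Inf
    for (M in c(0, 0.05, 0.1, 0.2, 0.4, 0.8)) {
      st <- model_state(ps, palmitoylCoA_cyt = S, malonylCoA = M)
      r <- reaction_rates(st, ps)[["CPT1B.C16"]]
      expect_lt(r, prev)
      prev <- r
    }
  }
})

test_that("derivatives conserve both moieties for random valid states", {
  ps <- bx_parameter_set()
  set.seed(7)
  coa_species <- c(paste0("acylCoA_C", bx_chains()),
                   paste0("enoylCoA_C", bx_chains()),
                   paste0("ketoacylCoA_C", bx_chains()), "acetylCoA",
                   "CoA_free")
  for (i in 1:25) {
    pools <- runif(22, 0, ps$coa_total / 40)
    args <- as.list(pools)
    names(args) <- coa_species[1:22]
    args$acylcarnitine_C16 <- runif(1, 0, ps$carnitine_total / 2)
    st <- do.call(model_state, c(list(ps, palmitoylCoA_cyt = runif(1, 0, 10),
                                      malonylCoA = runif(1, 0, 0.3)), args))
    d <- time_derivatives(st, ps)
    expect_equal(sum(d[coa_species]), 0, tolerance = 1e-9)
    expect_equal(sum(d[c("acylcarnitine_C16", "carnitine_free")]), 0,
                 tolerance = 1e-9)
  }
})

test_that("stoichiometry routes a lone pool to its direct product only", {
  ps <- bx_parameter_set()
  # only C16 acyl-CoA: dehydrogenation produces enoyl-C16, nothing else yet
  st <- model_state(ps, acylCoA_C16 = 2)
  d <- time_derivatives(st, ps)
  expect_lt(d[["acylCoA_C16"]], 0)
  expect_gt(d[["enoylCoA_C16"]], 0)
  expect_identical(unname(d[["acylCoA_C14"]]), 0)
  expect_identical(unname(d[["ketoacylCoA_C16"]]), 0)
  # only C16 ketoacyl-CoA: thiolysis yields C14 acyl-CoA plus acetyl-CoA
  st2 <- model_state(ps, ketoacylCoA_C16 = 2)
  d2 <- time_derivatives(st2, ps)
  expect_gt(d2[["acylCoA_C14"]], 0)
  expect_gt(d2[["acetylCoA"]], 0)
  expect_identical(unname(d2[["acylCoA_C12"]]), 0)
  # final C4 cleavage releases two acetyl-CoA per event
  st3 <- model_state(ps, ketoacylCoA_C4 = 2)
  d3 <- time_derivatives(st3, ps)
  v3 <- reaction_rates(st3, ps)[["MCKAT.C4"]]
  expect_equal(d3[["acetylCoA"]], 2 * v3, tolerance = 1e-12)
})

test_that("rates reject negative concentrations and incomplete parameters", {
  ps <- bx_parameter_set()
  st <- model_state(ps, palmitoylCoA_cyt = 1)
  st["acetylCoA"] <- -1
  expect_error(reaction_rates(st, ps), "negative")
  ps_bad <- ps
  ps_bad$vmax <- ps_bad$vmax[-3]
  expect_error(reaction_rates(model_state(ps), ps_bad), "VLCAD")
})

test_that("moieties are conserved along an integrated trajectory", {
  ps <- bx_parameter_set()
  st <- model_state(ps, palmitoylCoA_cyt = 2, malonylCoA = 0.1,
                    acylCoA_C16 = 5, ketoacylCoA_C8 = 3, acetylCoA = 10)
  traj <- integrate_model(st, ps, times = seq(0, 2, by = 0.1),
                          substeps = 200)
  coa_cols <- c(paste0("acylCoA_C", bx_chains()),
                paste0("enoylCoA_C", bx_chains()),
                paste0("ketoacylCoA_C", bx_chains()), "acetylCoA",
                "CoA_free")
  coa_tot <- rowSums(traj[, coa_cols])
  carn_tot <- rowSums(traj[, c("acylcarnitine_C16", "carnitine_free")])
  expect_equal(max(abs(coa_tot - coa_tot[1])), 0, tolerance = 1e-8)
  expect_equal(max(abs(carn_tot - carn_tot[1])), 0, tolerance = 1e-8)
})

test_that("zero substrate gives the exact all-zero steady state", {
  ps <- bx_parameter_set()
  res <- steady_state(ps, 0, 0)
  expect_true(res$converged)
  expect_identical(res$flux, 0)
  acyl <- res$state[grep("CoA_C|acylcarnitine|acetylCoA",
                         names(res$state))]
  expect_true(all(acyl[setdiff(names(acyl), "malonylCoA")] == 0))
})

test_that("with non-limiting downstream steps the flux is the CPT1B closed form", {
  ps <- nonlimiting_params()
  for (S in c(0.2, 1, 10)) {
    for (M in c(0, 0.2)) {
      res <- steady_state(ps, S, M)
      expect_true(res$converged)
      expect_equal(res$flux, cpt1_closed_form(ps, S, M),
                   tolerance = 0.01)
    }
  }
})

test_that("malonyl-CoA lowers the steady-state flux", {
  ps <- bx_parameter_set()
  j0 <- steady_state(ps, 1, 0)$flux
  j2 <- steady_state(ps, 1, 0.2)$flux
  expect_lt(j2, j0)
})

test_that("steady-state flux balances the acetyl-CoA sink (8 acetyl per C16)", {
  ps <- bx_parameter_set()
  for (S in c(0.5, 5)) {
    res <- steady_state(ps, S, 0)
    ac <- res$state[["acetylCoA"]]
    sink_flux <- ps$k_sink * ac / ps$vol_factor    # umol/min/mg
    expect_equal(8 * res$flux, sink_flux, tolerance = 1e-3)
  }
})

test_that("the solver is deterministic", {
  ps <- bx_parameter_set()
  a <- steady_state(ps, 1.7, 0.1)
  b <- steady_state(ps, 1.7, 0.1)
  expect_identical(a$state, b$state)
  expect_identical(a$flux, b$flux)
})

test_that("flux scans: degenerate grid, monotone endpoints, acylcarnitine rises", {
  ps <- bx_parameter_set()
  one <- flux_scan(ps, grid = 0)
  expect_equal(nrow(one), 1L)
  expect_equal(one$flux, 0)

  sc <- flux_scan(ps, grid = substrate_grid(10))
  expect_true(all(diff(sc$flux) > -1e-12))
  expect_true(all(diff(sc$acylcarnitine_C16) > 0))
  expect_true(all(sc$converged))

  # brute-force endpoint re-solves over random draws
  set.seed(11)
  for (i in 1:20) {
    ps_r <- random_params()
    lo <- steady_state(ps_r, 0.1, 0)
    hi <- steady_state(ps_r, 10, 0)
    expect_true(lo$converged && hi$converged)
    expect_gte(hi$flux, lo$flux)
  }
})

test_that("parameter files round-trip exactly", {
  ps <- bx_parameter_set(vmax = c(CPT1B = 2.5e-3), ki_malonyl = 0.07)
  path <- tempfile(fileext = ".params")
  write_parameter_file(ps, path)
  ps2 <- read_parameter_file(path)
  expect_equal(ps2$vmax, ps$vmax)
  expect_equal(ps2$km, ps$km)
  expect_equal(ps2$ki_malonyl, 0.07)
  expect_equal(ps2$coa_total, ps$coa_total)
})
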