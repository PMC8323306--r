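test_that("generators are fully deterministic under a fixed seed", {
  cfg <- cohort_config(seed = 42)
  expect_identical(generate_proteomics(cfg)$values,
                   generate_proteomics(cfg)$values)
  expect_identical(generate_lipidomics(cfg)$values,
                   generate_lipidomics(cfg)$values)
  o1 <- generate_ogtt(cfg); o2 <- generate_ogtt(cfg)
  expect_identical(o1$Y_LFD_1$glucose, o2$Y_LFD_1$glucose)
  expect_identical(o1$O_HFD_3$insulin, o2$O_HFD_3$insulin)
  # generators do not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_proteomics(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("all-unity multipliers with zero noise give identical animals", {
  cfg <- cohort_config(
    seed = 1,
    cv = list(proteomics = 0, lipidomics = 0, glucose = 0, insulin = 0),
    effects = list(cpt1b_age = 1, cpt1b_diet_young = 1, betaox_hfd = 1,
                   glyco_age = 1, glyco_diet_young = 1, lipid_block = 1))
  prot <- generate_proteomics(cfg)
  expect_true(all(apply(prot$values, 1, function(r) diff(range(r)) == 0)))
  lip <- generate_lipidomics(cfg)
  expect_true(all(apply(lip$values, 1, function(r) diff(range(r)) == 0)))
})

test_that("the proteomics panel has the documented shape and planted pattern", {
  cfg <- cohort_config(seed = 3)
  prot <- generate_proteomics(cfg)
  expect_equal(nrow(prot$values), 47)  # 16 beta-oxidation + 31 glycolysis
  expect_equal(ncol(prot$values), 2 * 6 + 2 * 10)
  expect_true(all(prot$values > 0))
  # planted-effect recovery across seeds (scaled-down regression check)
  seeds <- 1:10
  ok_cpt1b <- 0; ok_diet <- 0
  betaox <- c("CPT1B", "CPT2", "SLC25A20", "ACADVL", "ACADL", "ACADM",
              "ACADS", "ECHS1", "HADHA", "HADHB", "HADH", "ACAA2",
              "ETFA", "ETFB", "ETFDH", "CRAT")
  for (s in seeds) {
    p <- generate_proteomics(cohort_config(seed = s))
    fs <- factorial_screen(p)
    cpt <- fs[fs$analyte == "CPT1B", ]
    ok_cpt1b <- ok_cpt1b + (cpt$p_age < 0.05 && cpt$dir_age < 0)
    bx <- fs[fs$analyte %in% betaox, ]
    ok_diet <- ok_diet + (sum(bx$p_diet < 0.05 & bx$dir_diet > 0) >= 12)
  }
  expect_gte(ok_cpt1b, 9)
  expect_gte(ok_diet, 9)
})

test_that("lipidomics: 443 species, class standards round-trip, planted block", {
  cfg <- cohort_config(seed = 4)
  lip <- generate_lipidomics(cfg)
  expect_equal(nrow(lip$values), 443)
  expect_length(attr(lip, "planted_species"), 58)
  expect_true(all(attr(lip, "planted_species") %in% rownames(lip$values)))
  std <- attr(lip, "class_standards")
  expect_false("PR" %in% names(std))  # exercises the fallback path

  # multiplying one class and its standard by 10 leaves output unchanged
  norm1 <- normalize_to_class_standard(lip, std)
  lip10 <- lip
  tg <- lip10$classes == "TG"
  lip10$values[tg, ] <- lip10$values[tg, ] * 10
  std10 <- std; std10[["TG"]] <- std10[["TG"]] * 10
  norm10 <- normalize_to_class_standard(lip10, std10)
  with_std <- lip$classes != "PR"  # PR uses the all-standard mean, which moved
  expect_equal(norm10$values[with_std, ], norm1$values[with_std, ],
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(norm10$values[!with_std, ],
                                norm1$values[!with_std, ])))

  # zero-noise block recovery is exact
  cfg0 <- cohort_config(seed = 4, cv = list(lipidomics = 0))
  lip0 <- generate_lipidomics(cfg0)
  d0 <- differential(lip0, "old")
  expect_setequal(d0$analyte[d0$significant],
                  attr(lip0, "planted_species"))
  d0y <- differential(lip0, "young")
  expect_false(any(d0y$significant))
})

test_that("differential recovery: old flags the block, young stays null", {
  cfg <- cohort_config(seed = 11)
  lip <- generate_lipidomics(cfg)
  norm <- normalize_to_class_standard(lip, attr(lip, "class_standards"))
  planted <- attr(lip, "planted_species")
  d_old <- differential(norm, "old")
  d_young <- differential(norm, "young")
  flagged <- d_old$analyte[d_old$significant]
  jac <- length(intersect(flagged, planted)) /
    length(union(flagged, planted))
  expect_gte(jac, 0.9)
  expect_lte(sum(d_young$significant), 2)
})

test_that("OGTT generator: exact grids, positivity, round-trip, MISI ordering", {
  cfg <- cohort_config(seed = 8)
  ogtt <- generate_ogtt(cfg)
  expect_length(ogtt, 32)
  s1 <- ogtt[[1]]
  expect_equal(s1$glucose_times, c(0, 5, 15, 30, 45, 60, 90, 120))
  expect_equal(s1$insulin_times, c(0, 5, 15, 30, 60, 120))
  expect_true(all(unlist(lapply(ogtt, `[[`, "glucose")) > 0))
  expect_true(all(unlist(lapply(ogtt, `[[`, "insulin")) > 0))

  # zero-noise generator-fitter round trip
  cfg0 <- cohort_config(seed = 8, cv = list(glucose = 0, insulin = 0))
  o0 <- generate_ogtt(cfg0)
  truth <- attr(o0, "true_params")$young.LFD$g
  fit <- fit_ogtt(o0$Y_LFD_1, "glucose")
  for (p in c("C_b", "C_1", "C_2", "k_a", "k_e1", "k_e2"))
    expect_equal(fit[[p]], truth[[p]], tolerance = 1e-3)

  # group-mean MISI ordering across seeds (scaled-down regression check)
  ord_ok <- 0
  for (s in 1:10) {
    oo <- generate_ogtt(cohort_config(seed = s))
    mis <- vapply(oo, function(sr) {
      gf <- fit_ogtt(sr, "glucose")
      misi(gf, sr)$misi
    }, numeric(1))
    grp <- sub("_[0-9]+$", "", names(mis))
    gm <- tapply(mis, grp, mean)
    ord_ok <- ord_ok + (gm[["Y_LFD"]] > gm[["Y_HFD"]] &&
                          gm[["Y_HFD"]] > gm[["O_LFD"]] &&
                          gm[["O_LFD"]] > gm[["O_HFD"]])
  }
  expect_gte(ord_ok, 9)
})

test_that("config validation rejects degenerate cohorts", {
  expect_error(cohort_config(n_young = 1), ">= 2")
  expect_error(cohort_config(effects = list(lipid_block = -1)), "> 0")
})
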