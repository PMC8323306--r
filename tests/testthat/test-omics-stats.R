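mk_tab <- function(n_analyte = 10, n_per = 4, seed = 1, ages = "young") {
  set.seed(seed)
  ncol_total <- n_per * 2 * length(ages)
  v <- matrix(exp(rnorm(n_analyte * ncol_total, 10, 0.2)),
              nrow = n_analyte)
  rownames(v) <- paste0("a", seq_len(n_analyte))
  colnames(v) <- paste0("s", seq_len(ncol_total))
  tiny_omics(v, rep(ages, each = n_per * 2),
             rep(rep(c("LFD", "HFD"), each = n_per), length(ages)))
}

test_that("class-standard normalization divides by the right standard", {
  v <- matrix(c(2, 4, 6, 8), nrow = 2,
              dimnames = list(c("l1", "l2"), c("s1", "s2")))
  tab <- tiny_omics(v, c("young", "young"), c("LFD", "HFD"),
                    classes = c(l1 = "TG", l2 = "CER"))
  # all-ones standards: identity
  t1 <- normalize_to_class_standard(tab, c(TG = 1, CER = 1))
  expect_equal(t1$values, v)
  # one class halved, the other untouched
  t2 <- normalize_to_class_standard(tab, c(TG = 2, CER = 1))
  expect_equal(t2$values["l1", ], v["l1", ] / 2)
  expect_equal(t2$values["l2", ], v["l2", ])
  # missing class falls back to the mean of all standards: (1 + 3)/2 = 2
  t3 <- normalize_to_class_standard(tab, c(TG = 1, SM = 3))
  expect_equal(t3$values["l2", ], v["l2", ] / 2)
  expect_error(normalize_to_class_standard(tab, c(TG = 0, CER = 1)), "TG")
})

test_that("differential: identical groups give FC 1 and no flags", {
  v <- matrix(rep(c(3, 5, 7), each = 8), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("a", 1:3), paste0("s", 1:8)))
  tab <- tiny_omics(v, rep("young", 8), rep(c("LFD", "HFD"), each = 4))
  d <- differential(tab, "young")
  expect_equal(d$fold_change, rep(1, 3))
  expect_false(any(d$significant))
  expect_equal(d$p, rep(1, 3))  # degenerate-variance convention
})

test_that("a planted 4x shift is the only flagged analyte (oracle-checked)", {
  set.seed(42)
  n <- 100; per <- 5
  v <- matrix(exp(rnorm(n * per * 2, log(1000), 0.05)), nrow = n)
  rownames(v) <- paste0("a", seq_len(n))
  colnames(v) <- paste0("s", seq_len(per * 2))
  diet <- rep(c("LFD", "HFD"), each = per)
  v[17, diet == "HFD"] <- v[17, diet == "HFD"] * 4
  tab <- tiny_omics(v, rep("old", per * 2), diet)
  d <- differential(tab, "old")
  expect_identical(d$analyte[d$significant], "a17")

  # independent oracle: per-analyte t.test + stats::p.adjust step-up
  p_or <- apply(log2(v), 1, function(r)
    stats::t.test(r[diet == "HFD"], r[diet == "LFD"],
                  var.equal = TRUE)$p.value)
  expect_equal(d$p, unname(p_or), tolerance = 1e-12)
  expect_equal(d$q, unname(stats::p.adjust(p_or, "BH")), tolerance = 1e-12)
})

test_that("the significance flag needs both the q and fold-change gates", {
  set.seed(5)
  per <- 10
  base <- exp(rnorm(per * 2, log(1000), 0.01))
  v <- rbind(a1 = base, a2 = base)
  colnames(v) <- paste0("s", seq_len(per * 2))
  diet <- rep(c("LFD", "HFD"), each = per)
  v["a1", diet == "HFD"] <- v["a1", diet == "HFD"] * 1.2  # tiny FC, tiny p
  v["a2", diet == "HFD"] <- v["a2", diet == "HFD"] * 3
  tab <- tiny_omics(v, rep("old", per * 2), diet)
  d <- differential(tab, "old")
  expect_lt(d$q[d$analyte == "a1"], 0.05)
  expect_false(d$significant[d$analyte == "a1"])  # FC gate not met
  expect_true(d$significant[d$analyte == "a2"])
})

test_that("mean-centring leaves the t statistics unchanged", {
  tab <- mk_tab(20, 5, seed = 8)
  d <- differential(tab, "young")
  lv <- log2(tab$values)
  diet <- tab$samples$diet
  t_plain <- apply(lv, 1, function(r)
    stats::t.test(r[diet == "HFD"], r[diet == "LFD"],
                  var.equal = TRUE)$statistic)
  expect_equal(d$t, unname(t_plain), tolerance = 1e-10)
})

test_that("flag counts ignore row and column order", {
  set.seed(14)
  tab <- mk_tab(50, 5, seed = 14)
  tab$values[7, tab$samples$diet == "HFD"] <-
    tab$values[7, tab$samples$diet == "HFD"] * 4
  d0 <- differential(tab, "young")
  perm_r <- sample(nrow(tab$values)); perm_c <- sample(ncol(tab$values))
  tab2 <- omics_table(tab$values[perm_r, perm_c],
                      tab$samples[perm_c, ])
  d2 <- differential(tab2, "young")
  expect_equal(sum(d2$significant), sum(d0$significant))
  expect_setequal(d2$analyte[d2$significant], d0$analyte[d0$significant])
})

test_that("both FDR variants agree with independent step-up computations", {
  set.seed(77)
  for (i in 1:5) {
    p <- runif(200)^2
    expect_equal(fdr_bh(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
  # two-stage: fewer-or-equal q values than plain BH, never negative
  p <- runif(500)^3
  q2 <- fdr_two_stage(p)
  expect_true(all(q2 <= fdr_bh(p) + 1e-12))
  expect_true(all(q2 >= 0 & q2 <= 1))
})

test_that("diet-response scatter sits on the documented coordinates", {
  # all animals equal: the point (1, 1)
  v <- matrix(5, 1, 8, dimnames = list("a1", paste0("s", 1:8)))
  tab <- tiny_omics(v, rep("young", 8), rep(c("LFD", "HFD"), each = 4))
  sc <- diet_response_scatter(tab)
  expect_equal(sc$mean_lfd, 1)
  expect_equal(sc$mean_hfd, 1)
  # HFD doubled, balanced groups: grand mean 1.5x LFD -> (2/3, 4/3)
  v2 <- matrix(c(rep(3, 4), rep(6, 4)), 1, 8,
               dimnames = list("a1", paste0("s", 1:8)))
  tab2 <- tiny_omics(v2, rep("young", 8), rep(c("LFD", "HFD"), each = 4))
  sc2 <- diet_response_scatter(tab2)
  expect_equal(sc2$mean_lfd, 2 / 3)
  expect_equal(sc2$mean_hfd, 4 / 3)
  # scale-free by construction
  tab3 <- tab2; tab3$values <- tab3$values * 1e6
  expect_equal(diet_response_scatter(tab3)[, c("mean_lfd", "mean_hfd")],
               sc2[, c("mean_lfd", "mean_hfd")])
})

test_that("index correlations hit the exact limits and the textbook formula", {
  set.seed(2)
  n <- 12
  idx <- stats::setNames(runif(n, 1, 5), paste0("s", 1:n))
  noise <- rnorm(n, 0, 0.8)
  v <- rbind(a1 = idx,                      # r = 1
             a2 = -idx + 10,                # r = -1
             a3 = -0.6 * idx + 5 + noise - min(-0.6 * idx + 5 + noise) + 1,
             a4 = rep(3, n))                # zero variance
  colnames(v) <- names(idx)
  tab <- tiny_omics(v, rep(c("young", "old"), each = 6),
                    rep(c("LFD", "HFD"), 6))
  res <- correlate_with_index(tab, idx)
  expect_equal(res$r[res$analyte == "a1"], 1, tolerance = 1e-12)
  expect_equal(res$r[res$analyte == "a2"], -1, tolerance = 1e-12)
  expect_false(res$defined[res$analyte == "a4"])
  # textbook formula oracle
  x <- v["a3", ]; y <- idx
  r_or <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r[res$analyte == "a3"], r_or, tolerance = 1e-12)
  ct <- stats::cor.test(x, y)
  expect_equal(res$p[res$analyte == "a3"], ct$p.value, tolerance = 1e-12)
})

test_that("factorial screen: swapped diet labels flip directions, keep p-values", {
  set.seed(6)
  tab <- mk_tab(30, 3, seed = 6, ages = c("young", "old"))
  fs <- factorial_screen(tab)
  tab2 <- tab
  tab2$samples$diet <- ifelse(tab2$samples$diet == "HFD", "ZFD", "HFD")
  # relabelled: old HFD is now the former LFD group
  fs2 <- factorial_screen(tab2)
  expect_equal(fs2$p_diet, fs$p_diet, tolerance = 1e-9)
  expect_equal(fs2$p_age, fs$p_age, tolerance = 1e-9)
  nz <- fs$dir_diet != 0
  expect_equal(fs2$dir_diet[nz], -fs$dir_diet[nz])
  expect_error(factorial_screen(tiny_omics(
    matrix(1:4, 1, 4, dimnames = list("a", paste0("s", 1:4))),
    rep("young", 4), rep(c("LFD", "HFD"), 2))), "cells")
})

test_that("factorial screen detects a planted diet effect and not a phantom age effect", {
  set.seed(19)
  hits_diet <- 0; hits_age <- 0; reps <- 20
  for (r in 1:reps) {
    v <- matrix(exp(rnorm(24, log(100), 0.1)), 1, 24,
                dimnames = list("a1", paste0("s", 1:24)))
    ages <- rep(c("young", "old"), each = 12)
    diets <- rep(rep(c("LFD", "HFD"), each = 6), 2)
    v[1, diets == "HFD"] <- v[1, diets == "HFD"] * 1.5
    fs <- factorial_screen(tiny_omics(v, ages, diets))
    hits_diet <- hits_diet + (fs$p_diet < 0.05 && fs$dir_diet > 0)
    hits_age <- hits_age + (fs$p_age < 0.05)
  }
  expect_gte(hits_diet, 0.95 * reps)
  expect_lte(hits_age, 0.25 * reps)
})
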