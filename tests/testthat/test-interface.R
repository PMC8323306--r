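test_that("table reading validates schema, types and duplicates", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("# a comment", "protein\tvalue", "CPT1B\t1.5", "ACADVL\t2"),
             path)
  df <- read_table(path, columns = c(protein = "character",
                                     value = "numeric"),
                   id_column = "protein")
  expect_equal(df$value, c(1.5, 2))

  writeLines(c("protein\tvalue", "CPT1B\t1.5", "CPT1B\t2"), path)
  expect_error(read_table(path, id_column = "protein"),
               "duplicate protein.*CPT1B")
  writeLines(c("protein\tvalue", "CPT1B\tnot_a_number"), path)
  expect_error(read_table(path, columns = c(value = "numeric")),
               "non-numeric.*row 1")
  expect_error(read_table(tempfile(), NULL), "not found")
})

test_that("omics tables and OGTT series round-trip through text files", {
  cfg <- cohort_config(seed = 2, n_young = 2, n_old = 2)
  lip <- generate_lipidomics(cfg)
  dir <- tempfile(); dir.create(dir)
  write_omics_table(lip, dir, "lip")
  lip2 <- read_omics_table(file.path(dir, "lip_values.tsv"),
                           file.path(dir, "lip_samples.tsv"),
                           file.path(dir, "lip_classes.tsv"))
  expect_equal(lip2$values, lip$values, tolerance = 1e-9)
  expect_equal(lip2$samples$diet, lip$samples$diet)
  expect_equal(lip2$classes, lip$classes)

  ogtt <- generate_ogtt(cfg)
  path <- file.path(dir, "ogtt.tsv")
  write_ogtt(ogtt, path)
  back <- read_ogtt(path)
  expect_length(back, length(ogtt))
  expect_equal(back$Y_LFD_1$glucose, ogtt$Y_LFD_1$glucose,
               tolerance = 1e-9)
  expect_equal(back$Y_LFD_1$insulin_unit, "ng/mL")
})

test_that("omics container rejects inconsistent inputs", {
  v <- matrix(1:4, 2, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  samples <- data.frame(sample = c("s1", "s2"), age = "young",
                        diet = c("LFD", "HFD"))
  expect_error(omics_table(v, samples), "duplicate")
  v2 <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s3")))
  expect_error(omics_table(v2, samples), "s3")
  v3 <- matrix(c(-1, 1, 1, 1), 2, 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(omics_table(v3, samples), ">= 0")
})

test_that("pipeline config round-trips and rejects unknown keys", {
  cfg <- pipeline_config(out_dir = "x", seed = 9, stages = c("synth"),
                         fdr = "two-stage", grid_points = 5)
  path <- tempfile()
  write_pipeline_config(cfg, path)
  cfg2 <- read_pipeline_config(path)
  expect_equal(cfg2[names(cfg2) != "out_dir"],
               cfg[names(cfg) != "out_dir"])
  expect_error(pipeline_config(out_dir = "x", nonsense = 1), "unknown")
  expect_error(pipeline_config(out_dir = "x", stages = "frobnicate"),
               "unknown stage")
})

test_that("the pipeline writes expected artifacts and is idempotent", {
  out <- file.path(tempfile(), "run1")
  cfg <- pipeline_config(out_dir = out, seed = 3, grid_points = 3)
  run_pipeline(cfg)
  expected <- c("proteomics_values.tsv", "lipidomics_values.tsv",
                "ogtt.tsv", "cohort_vmax.tsv", "flux_scans.tsv",
                "fcc_animals.tsv", "fcc_groups.tsv", "indices.tsv",
                "differential_young.tsv", "differential_old.tsv",
                "scatter_lipids.tsv", "scatter_proteins.tsv",
                "lipid_misi_correlations.tsv", "manifest.json")
  for (f in expected) expect_true(file.exists(file.path(out, f)), label = f)
  idx <- read_table(file.path(out, "indices.tsv"))
  expect_equal(nrow(idx), 32)

  # rerun with the same config: byte-identical numeric outputs
  out2 <- file.path(tempfile(), "run2")
  run_pipeline(pipeline_config(out_dir = out2, seed = 3, grid_points = 3))
  for (f in c("indices.tsv", "flux_scans.tsv", "differential_old.tsv"))
    expect_identical(readLines(file.path(out, f)),
                     readLines(file.path(out2, f)))

  # disabling the lipidomics stage leaves other stages untouched
  out3 <- file.path(tempfile(), "run3")
  run_pipeline(pipeline_config(
    out_dir = out3, seed = 3, grid_points = 3,
    stages = c("synth", "parameterize", "fit-ogtt")))
  expect_false(file.exists(file.path(out3, "differential_old.tsv")))
  expect_true(file.exists(file.path(out3, "indices.tsv")))
  expect_identical(readLines(file.path(out, "indices.tsv")),
                   readLines(file.path(out3, "indices.tsv")))
})

test_that("CLI subcommands cover the pipeline and report proper exit codes", {
  dir <- tempfile(); dir.create(dir)
  expect_equal(suppressMessages(mitoflex_cli("no-such-command")), 1L)
  expect_equal(suppressMessages(mitoflex_cli(character(0))), 1L)

  st <- suppressMessages(mitoflex_cli(c("synth", "--seed", "2", "--out",
                                        file.path(dir, "synth"))))
  expect_equal(st, 0L)
  expect_true(file.exists(file.path(dir, "synth", "ogtt.tsv")))

  # simulate on a written parameter file
  ppath <- file.path(dir, "base.params")
  write_parameter_file(bx_parameter_set(), ppath)
  st2 <- suppressMessages(mitoflex_cli(c(
    "simulate", "--params", ppath, "--points", "3", "--malonyl", "0.2",
    "--out", file.path(dir, "scan.tsv"))))
  expect_equal(st2, 0L)
  scan <- read_table(file.path(dir, "scan.tsv"))
  expect_equal(nrow(scan), 3)
  expect_true(all(scan$malonylCoA_uM == 0.2))

  st3 <- suppressMessages(mitoflex_cli(c(
    "fit-ogtt", "--in", file.path(dir, "synth", "ogtt.tsv"),
    "--out", file.path(dir, "idx.tsv"))))
  expect_equal(st3, 0L)
  expect_equal(nrow(read_table(file.path(dir, "idx.tsv"))), 32)

  # validation failure (missing file) exits 1, not 2
  st4 <- suppressMessages(mitoflex_cli(c(
    "simulate", "--params", file.path(dir, "absent.params"),
    "--out", file.path(dir, "x.tsv"))))
  expect_equal(st4, 1L)
})
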