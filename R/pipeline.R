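# Umbrella pipeline: synth -> parameterize -> simulate/fcc -> fit-ogtt ->
# lipidiff -> report, with a run manifest for provenance.

.bx_all_stages <- function() {
  c("synth", "parameterize", "simulate", "fcc", "fit-ogtt", "lipidiff",
    "scatter", "correlate")
}

#' Pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Cohort seed.
#' @param stages Stages to run, a subset of
#'   synth/parameterize/simulate/fcc/fit-ogtt/lipidiff/scatter/correlate
#'   (dependencies are enforced: everything downstream consumes the synth
#'   stage's artifacts in `out_dir`).
#' @param fdr FDR variant for the differential stage.
#' @param grid_points Substrate grid size for the simulate/fcc stages.
#' @param malonyl Malonyl-CoA levels (muM) for the simulate/fcc stages.
#' @param insulin_factor mU/L per ng/mL for the index stage.
#' @param ... Unknown keys are rejected.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = .bx_all_stages(),
                            fdr = "bh", grid_points = 9L,
                            malonyl = c(0, 0.2), insulin_factor = 25,
                            ...) {
  extra <- list(...)
  if (length(extra))
    .verror("unknown pipeline config key(s): ",
            paste(names(extra), collapse = ", "))
  bad <- setdiff(stages, .bx_all_stages())
  if (length(bad))
    .verror("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!fdr %in% c("bh", "two-stage")) .verror("fdr must be bh or two-stage")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, fdr = fdr,
                 grid_points = as.integer(grid_points),
                 malonyl = as.numeric(malonyl),
                 insulin_factor = as.numeric(insulin_factor)),
            class = "pipeline_config")
}

#' Serialize a pipeline configuration to key=value text
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pipeline_config <- function(config, path) {
  lines <- c(paste("out_dir =", config$out_dir),
             paste("seed =", config$seed),
             paste("stages =", paste(config$stages, collapse = ",")),
             paste("fdr =", config$fdr),
             paste("grid_points =", config$grid_points),
             paste("malonyl =", paste(config$malonyl, collapse = ",")),
             paste("insulin_factor =", config$insulin_factor))
  writeLines(lines, path)
  invisible(path)
}

#' Read a pipeline configuration
#' @param path File written by [write_pipeline_config()].
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) .verror("config file not found: ", path)
  kv <- strsplit(readLines(path), " = | =|= |=")
  store <- stats::setNames(lapply(kv, function(x) x[2]),
                           vapply(kv, `[`, "", 1))
  known <- c("out_dir", "seed", "stages", "fdr", "grid_points", "malonyl",
             "insulin_factor")
  bad <- setdiff(names(store), known)
  if (length(bad))
    .verror("unknown pipeline config key(s): ", paste(bad, collapse = ", "))
  pipeline_config(out_dir = store$out_dir,
                  seed = as.integer(store$seed),
                  stages = strsplit(store$stages, ",")[[1]],
                  fdr = store$fdr,
                  grid_points = as.integer(store$grid_points),
                  malonyl = as.numeric(strsplit(store$malonyl, ",")[[1]]),
                  insulin_factor = as.numeric(store$insulin_factor))
}

#' Run the end-to-end pipeline on a synthetic cohort
#'
#' Executes the enabled stages in dependency order, writing all artifacts
#' as delimited text under `out_dir` plus a JSON run manifest (seed,
#' configuration, config hash, package version). Identical configurations
#' give byte-identical numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of the written artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  grid <- substrate_grid(config$grid_points)

  cc <- cohort_config(seed = config$seed)
  cohort <- stage("synth", {
    ch <- generate_cohort(cc)
    if ("synth" %in% config$stages) {
      paths$proteomics <- write_omics_table(ch$proteomics, out,
                                             "proteomics")
      paths$lipidomics <- write_omics_table(ch$lipidomics, out,
                                             "lipidomics")
      std <- attr(ch$lipidomics, "class_standards")
      paths$standards <- write_table(
        data.frame(class = names(std), intensity = unname(std)),
        file.path(out, "lipid_class_standards.tsv"))
      paths$ogtt <- write_ogtt(ch$ogtt, file.path(out, "ogtt.tsv"))
    }
    ch
  })

  params <- NULL
  if (any(c("parameterize", "simulate", "fcc") %in% config$stages)) {
    params <- stage("parameterize", {
      ref <- liver_reference()
      kc <- estimate_kcats(
        stats::setNames(ref$vmax_umol_min_mg, ref$enzyme),
        stats::setNames(ref$conc_fmol_ug, ref$enzyme))
      ps <- cohort_parameters(cohort$proteomics, kc)
      pdir <- file.path(out, "params")
      dir.create(pdir, showWarnings = FALSE)
      for (an in names(ps))
        write_parameter_file(ps[[an]], file.path(pdir,
                                                 paste0(an, ".params")))
      vm <- t(vapply(ps, function(p) p$vmax, numeric(length(bx_enzymes()))))
      paths$vmax_summary <- write_table(
        data.frame(sample = names(ps), vm, check.names = FALSE),
        file.path(out, "cohort_vmax.tsv"),
        comment = "per-animal Vmax, umol/min/mg total protein")
      ps
    })
  }

  if ("simulate" %in% config$stages) stage("simulate", {
    rows <- do.call(rbind, lapply(names(params), function(an) {
      do.call(rbind, lapply(config$malonyl, function(M) {
        sc <- flux_scan(params[[an]], grid = grid, M = M)
        cbind(animal = an, sc)
      }))
    }))
    paths$flux <- write_table(rows, file.path(out, "flux_scans.tsv"),
                               comment = "steady-state CPT1B flux, umol/min/mg")
  })

  if ("fcc" %in% config$stages) stage("fcc", {
    sim <- cohort_simulation(params, cohort$samples, grid = grid,
                             M_levels = config$malonyl)
    paths$fcc_animals <- write_table(sim$animals,
                                      file.path(out, "fcc_animals.tsv"))
    paths$fcc_groups <- write_table(sim$groups,
                                     file.path(out, "fcc_groups.tsv"))
  })

  indices <- NULL
  if (any(c("fit-ogtt", "correlate") %in% config$stages)) {
    indices <- stage("fit-ogtt", {
      rows <- do.call(rbind, lapply(cohort$ogtt, function(s) {
        gf <- fit_ogtt(s, "glucose")
        mi <- misi(gf, s, insulin_unit_factor = config$insulin_factor)
        h <- homa_ir(s$glucose[1],
                     insulin_to_mUL(s$insulin[1], s$insulin_unit,
                                    config$insulin_factor))
        data.frame(animal = s$animal, C_b = gf$C_b, C_1 = gf$C_1,
                   C_2 = gf$C_2, k_a = gf$k_a, k_e1 = gf$k_e1,
                   k_e2 = gf$k_e2, rss = gf$rss,
                   converged = gf$converged, misi = mi$misi,
                   mean_insulin_mUL = mi$mean_insulin, homa_ir = h)
      }))
      if ("fit-ogtt" %in% config$stages)
        paths$indices <- write_table(rows, file.path(out, "indices.tsv"),
                                      comment = "MISI: mM/min per mU/L")
      rows
    })
  }

  lip <- NULL
  if (any(c("lipidiff", "scatter", "correlate") %in% config$stages))
    lip <- normalize_to_class_standard(
      cohort$lipidomics, attr(cohort$lipidomics, "class_standards"))

  if ("lipidiff" %in% config$stages) stage("lipidiff", {
    for (a in c("young", "old")) {
      d <- differential(lip, a, fdr = config$fdr)
      paths[[paste0("differential_", a)]] <- write_table(
        d, file.path(out, paste0("differential_", a, ".tsv")),
        comment = paste("FDR method:", attr(d, "fdr_method")))
    }
  })

  if ("scatter" %in% config$stages) stage("scatter", {
    paths$scatter_lipids <- write_table(
      diet_response_scatter(lip), file.path(out, "scatter_lipids.tsv"))
    paths$scatter_proteins <- write_table(
      diet_response_scatter(cohort$proteomics),
      file.path(out, "scatter_proteins.tsv"))
  })

  if ("correlate" %in% config$stages) stage("correlate", {
    idx <- stats::setNames(indices$misi, indices$animal)
    paths$correlations <- write_table(
      correlate_with_index(lip, idx),
      file.path(out, "lipid_misi_correlations.tsv"))
  })

  cfg_path <- file.path(out, "pipeline_config.txt")
  write_pipeline_config(config, cfg_path)
  manifest <- list(
    package = "mitoflex",
    version = as.character(utils::packageVersion("mitoflex")),
    seed = config$seed,
    stages = config$stages,
    config_hash = unname(tools::md5sum(cfg_path)),
    artifacts = unlist(paths, use.names = FALSE))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  paths$manifest <- file.path(out, "manifest.json")
  invisible(paths)
}
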