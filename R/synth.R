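# Seeded synthetic cohort generator. Emulates the data layout the
# analysis consumes — a 2x2 age x diet mouse cohort with targeted
# proteomics (16 beta-oxidation + 31 glucose-metabolism proteins),
# untargeted lipidomics (443 species with class annotations and class
# internal standards) and 8-point glucose / 6-point insulin OGTT curves —
# with planted group effects so that every downstream stage's recovery
# can be tested without external data. Effect sizes are generator knobs
# chosen to make the qualitative published contrasts recoverable at the
# study's sample sizes; they are synthetic, not estimates of real data.

#' Cohort generator configuration
#'
#' @param seed Integer seed; fixed seed implies full reproducibility of
#'   all three generators.
#' @param n_young,n_old Animals per diet group within each age (defaults
#'   6 young / 10 old per diet).
#' @param cv Coefficients of variation of the multiplicative log-normal
#'   noise per data type: `proteomics`, `lipidomics`, `glucose`,
#'   `insulin`.
#' @param effects Planted multipliers: `cpt1b_age` (old vs young CPT1B,
#'   default 0.6), `cpt1b_diet_young` (HFD effect on CPT1B in young only,
#'   default 1.3), `betaox_hfd` (HFD effect on 14/16 beta-oxidation
#'   proteins, default 1.5), `glyco_age` (old effect on lower-glycolysis
#'   proteins, default 0.8), `glyco_diet_young` (young-only HFD effect on
#'   the same, default 1.2), `lipid_block` (old-HFD accumulation of the
#'   planted lipid block, default 2; must clear the 1.5 fold-change gate
#'   in expectation under noise).
#' @param lipid_block_size Number of planted accumulating lipid species
#'   (default 58).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1L, n_young = 6L, n_old = 10L,
                          cv = list(proteomics = 0.15, lipidomics = 0.25,
                                    glucose = 0.05, insulin = 0.15),
                          effects = list(cpt1b_age = 0.6,
                                         cpt1b_diet_young = 1.3,
                                         betaox_hfd = 1.5,
                                         glyco_age = 0.8,
                                         glyco_diet_young = 1.2,
                                         lipid_block = 2.0),
                          lipid_block_size = 58L) {
  defaults_cv <- list(proteomics = 0.15, lipidomics = 0.25,
                      glucose = 0.05, insulin = 0.15)
  defaults_eff <- list(cpt1b_age = 0.6, cpt1b_diet_young = 1.3,
                       betaox_hfd = 1.5, glyco_age = 0.8,
                       glyco_diet_young = 1.2, lipid_block = 2.0)
  cv <- utils::modifyList(defaults_cv, cv)
  effects <- utils::modifyList(defaults_eff, effects)
  if (n_young < 2 || n_old < 2) stop("need >= 2 animals per group")
  if (any(unlist(effects) <= 0)) stop("effect multipliers must be > 0")
  if (any(unlist(cv) < 0)) stop("noise CVs must be >= 0")
  structure(list(seed = as.integer(seed), n_young = as.integer(n_young),
                 n_old = as.integer(n_old), cv = cv, effects = effects,
                 lipid_block_size = as.integer(lipid_block_size)),
            class = "cohort_config")
}

#' Sample sheet for a synthetic cohort
#' @param config A [cohort_config()].
#' @return data.frame `sample`, `age`, `diet`.
#' @export
cohort_samples <- function(config) {
  mk <- function(age, diet, n) {
    tag <- paste0(ifelse(age == "young", "Y", "O"), "_", diet)
    data.frame(sample = paste0(tag, "_", seq_len(n)), age = age,
               diet = diet, stringsAsFactors = FALSE)
  }
  rbind(mk("young", "LFD", config$n_young), mk("young", "HFD", config$n_young),
        mk("old", "LFD", config$n_old), mk("old", "HFD", config$n_old))
}

# run code under a derived seed without disturbing the caller's RNG
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# lognormal noise with unit mean and given CV
.ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdl^2 / 2, sdl))
}

.bx_protein_panel <- function() {
  list(
    betaox = c(CPT1B = 1.0, CPT2 = 4.0, SLC25A20 = 2.0, ACADVL = 6.0,
               ACADL = 3.0, ACADM = 6.0, ACADS = 6.0, ECHS1 = 15,
               HADHA = 20, HADHB = 8, HADH = 10, ACAA2 = 4.8, ETFA = 5,
               ETFB = 5, ETFDH = 2, CRAT = 3),
    glyco = c(HK1 = 2, HK2 = 3, GPI1 = 20, PFKM = 30, ALDOA = 50,
              TPI1 = 45, GAPDH = 60, PGK1 = 40, PGAM2 = 35, ENO1 = 10,
              ENO3 = 45, PKM1 = 50, PKM2 = 8, LDHA = 30, LDHB = 10,
              PGM1 = 8, PGM2 = 4, UGP2 = 5, GYS1 = 6, GBE1 = 3,
              PYGM = 25, PHKA1 = 4, PHKB = 4, CALM1 = 12, PPP1CA = 6,
              G6PD = 2, PGD = 3, TKT = 5, TALDO1 = 4, RPIA = 2, RPE = 1.5)
  )
}

# proteins carrying the broad HFD upregulation (14 of the 16
# beta-oxidation targets; CPT1B has its own age/diet pattern, CRAT none)
.bx_hfd_responsive <- function() {
  setdiff(names(.bx_protein_panel()$betaox), c("CPT1B", "CRAT"))
}

# lower-glycolysis subset: reduced in old, diet-responsive in young only
.bx_lower_glycolysis <- function() {
  c("GAPDH", "PGK1", "PGAM2", "ENO1", "ENO3", "PKM1", "PKM2", "LDHA",
    "LDHB")
}

#' Generate a synthetic targeted-proteomics table
#'
#' 16 beta-oxidation + 31 glucose-metabolism proteins (fmol per ug total
#' protein) with multiplicative log-normal noise and planted effects:
#' CPT1B lower in old and HFD-responsive only in young; most other
#' beta-oxidation proteins upregulated by the HFD in both ages;
#' lower-glycolysis proteins lower in old and diet-responsive only in
#' young.
#'
#' @param config A [cohort_config()].
#' @return An [omics_table()] (no class annotation).
#' @export
generate_proteomics <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  samples <- cohort_samples(config)
  panel <- .bx_protein_panel()
  base <- c(panel$betaox, panel$glyco)
  eff <- config$effects
  mult <- matrix(1, nrow = length(base), ncol = nrow(samples),
                 dimnames = list(names(base), samples$sample))
  old <- samples$age == "old"; hfd <- samples$diet == "HFD"
  mult["CPT1B", old] <- eff$cpt1b_age
  mult["CPT1B", !old & hfd] <- mult["CPT1B", !old & hfd] *
    eff$cpt1b_diet_young
  mult[.bx_hfd_responsive(), hfd] <- mult[.bx_hfd_responsive(), hfd] *
    eff$betaox_hfd
  lg <- .bx_lower_glycolysis()
  mult[lg, old] <- mult[lg, old] * eff$glyco_age
  mult[lg, !old & hfd] <- mult[lg, !old & hfd] * eff$glyco_diet_young
  vals <- .with_seed(config$seed + 101L, {
    noise <- matrix(.ln_noise(length(mult), config$cv$proteomics),
                    nrow = nrow(mult))
    base * mult * noise
  })
  omics_table(vals, samples)
}

.bx_lipid_panel <- function() {
  # class composition following the detected-species category counts
  counts <- c(TG = 143, PC = 80, LPC = 15, PL = 30, PE = 45, LPE = 10,
              SM = 25, DG = 30, CER = 20, FA = 15, PR = 5, CL = 10,
              MG = 4, LPI = 4, AC = 7)
  curated <- list(
    AC = c("CAR(14:0)", "CAR(16:0)", "CAR(18:0)", "CAR(20:0)",
           "CAR(16:0-OH)", "CAR(18:0-OH)", "CAR(18:1-OH)"),
    CER = c("Cer(d18:1/18:0)", "Cer(d18:1/22:0)", "Cer(d18:1/16:0)",
            "Cer(d18:1/24:1)"),
    DG = c("DG(16:0_18:0)", "DG(18:0_20:4)", "DG(36:2)", "DG(18:0_18:1)"),
    TG = c("TG(18:0_18:0_18:1)", "TG(16:0_18:0_18:0)", "TG(18:0_18:1_18:1)")
  )
  species <- character(0); cls <- character(0)
  for (cn in names(counts)) {
    cur <- curated[[cn]]
    n_extra <- counts[[cn]] - length(cur)
    sp <- c(cur, sprintf("%s_%02d", cn, seq_len(n_extra)))
    species <- c(species, sp)
    cls <- c(cls, rep(cn, counts[[cn]]))
  }
  list(species = species, classes = stats::setNames(cls, species))
}

# the planted old-HFD accumulation block: C18:0-tagged Cer/DG/TG
# exemplars, the long-chain acylcarnitines, and TG padding
.bx_lipid_block <- function(panel, size) {
  core <- c("CAR(14:0)", "CAR(16:0)", "CAR(18:0)", "CAR(20:0)",
            "CAR(16:0-OH)", "CAR(18:0-OH)", "CAR(18:1-OH)",
            "Cer(d18:1/18:0)", "Cer(d18:1/22:0)",
            "DG(16:0_18:0)", "DG(18:0_20:4)", "DG(36:2)",
            "TG(18:0_18:0_18:1)", "TG(16:0_18:0_18:0)",
            "TG(18:0_18:1_18:1)")
  pad_pool <- setdiff(panel$species[panel$classes %in%
                                      c("TG", "DG", "CER")], core)
  c(core, pad_pool[seq_len(max(0, size - length(core)))])
}

#' Generate a synthetic lipidomics table
#'
#' 443 lipid species across the detected classes with multiplicative
#' log-normal noise, a planted old-HFD-only accumulation block (default
#' 58 species including C18:0-tagged ceramide/DG/TG exemplars and the
#' long-chain acylcarnitines) and per-class internal-standard intensities
#' (one class, PR, deliberately lacks a standard to exercise the
#' fallback).
#'
#' @param config A [cohort_config()].
#' @return An [omics_table()] with class annotation. The planted species
#'   are in `attr(, "planted_species")` and the class standards in
#'   `attr(, "class_standards")`.
#' @export
generate_lipidomics <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  samples <- cohort_samples(config)
  panel <- .bx_lipid_panel()
  block <- .bx_lipid_block(panel, config$lipid_block_size)
  vals <- .with_seed(config$seed + 202L, {
    base <- stats::setNames(
      exp(stats::runif(length(panel$species), log(1e4), log(1e7))),
      panel$species)
    mult <- matrix(1, nrow = length(base), ncol = nrow(samples),
                   dimnames = list(panel$species, samples$sample))
    oldhfd <- samples$age == "old" & samples$diet == "HFD"
    mult[block, oldhfd] <- config$effects$lipid_block
    noise <- matrix(.ln_noise(length(mult), config$cv$lipidomics),
                    nrow = nrow(mult))
    base * mult * noise
  })
  tab <- omics_table(vals, samples, classes = panel$classes)
  standards <- stats::setNames(
    c(2e5, 1e5, 5e4, 8e4, 1.2e5, 4e4, 6e4, 7e4, 5e4, 9e4, 1.1e5, 3e4,
      2.5e4, 1.5e5),
    c("TG", "PC", "LPC", "PL", "PE", "LPE", "SM", "DG", "CER", "FA",
      "CL", "MG", "LPI", "AC"))  # PR intentionally absent
  attr(tab, "planted_species") <- block
  attr(tab, "class_standards") <- standards
  tab
}

# group-wise generating parameters for the OGTT curves; chosen so that
# MISI orders young-LFD > young-HFD > old-LFD > old-HFD with roughly
# 2-3x separation between neighbours, and fasting glucose/insulin rise
# in the opposite order (HOMA-IR reversed)
.bx_ogtt_group_params <- function() {
  list(
    young.LFD = list(g = list(C_b = 5.0, C_1 = 10, C_2 = 0.5, k_a = 0.15,
                              k_e1 = 0.035, k_e2 = 0.01),
                     i = list(C_b = 0.32, C_1 = 1.0, C_2 = 0, k_a = 0.2,
                              k_e1 = 0.03, k_e2 = 0.005)),
    young.HFD = list(g = list(C_b = 5.5, C_1 = 10, C_2 = 0.5, k_a = 0.15,
                              k_e1 = 0.025, k_e2 = 0.01),
                     i = list(C_b = 0.60, C_1 = 2.0, C_2 = 0, k_a = 0.2,
                              k_e1 = 0.03, k_e2 = 0.005)),
    old.LFD = list(g = list(C_b = 5.5, C_1 = 10, C_2 = 0.5, k_a = 0.15,
                            k_e1 = 0.018, k_e2 = 0.01),
                   i = list(C_b = 1.00, C_1 = 2.5, C_2 = 0, k_a = 0.2,
                            k_e1 = 0.03, k_e2 = 0.005)),
    old.HFD = list(g = list(C_b = 6.5, C_1 = 10, C_2 = 0.5, k_a = 0.15,
                            k_e1 = 0.012, k_e2 = 0.01),
                   i = list(C_b = 2.40, C_1 = 5.0, C_2 = 0, k_a = 0.2,
                            k_e1 = 0.03, k_e2 = 0.005))
  )
}

#' Generate synthetic OGTT series
#'
#' Glucose sampled at 0, 5, 15, 30, 45, 60, 90, 120 min and insulin at
#' 0, 5, 15, 30, 60, 120 min from group-dependent curves of the fitted
#' family (so the fitter is well-specified), with multiplicative noise.
#' Insulin is emitted in ng/mL, the ELISA unit.
#'
#' @param config A [cohort_config()].
#' @return Named list of [ogtt_series()], one per animal, with the
#'   generating parameters in `attr(, "true_params")`.
#' @export
generate_ogtt <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  samples <- cohort_samples(config)
  gp <- .bx_ogtt_group_params()
  g_times <- c(0, 5, 15, 30, 45, 60, 90, 120)
  i_times <- c(0, 5, 15, 30, 60, 120)
  out <- .with_seed(config$seed + 303L, {
    lapply(seq_len(nrow(samples)), function(k) {
      key <- paste(samples$age[k], samples$diet[k], sep = ".")
      pars <- gp[[key]]
      glu <- ogtt_curve(pars$g, g_times) *
        .ln_noise(length(g_times), config$cv$glucose)
      ins <- ogtt_curve(pars$i, i_times) *
        .ln_noise(length(i_times), config$cv$insulin)
      ogtt_series(samples$sample[k], g_times, glu, i_times, ins,
                  insulin_unit = "ng/mL")
    })
  })
  names(out) <- samples$sample
  attr(out, "true_params") <- gp
  out
}

#' Generate a full synthetic cohort
#'
#' @param config A [cohort_config()].
#' @return List with `samples`, `proteomics`, `lipidomics`, `ogtt`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  list(samples = cohort_samples(config),
       proteomics = generate_proteomics(config),
       lipidomics = generate_lipidomics(config),
       ogtt = generate_ogtt(config))
}
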