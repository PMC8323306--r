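#' @useDynLib mitoflex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical enzyme and chain metadata ---------------------------------------

#' Enzymes of the beta-oxidation model
#'
#' The model tracks nine maximal-rate-bearing enzymatic steps plus a
#' first-order acetyl-CoA sink: CPT1B (entry, malonyl-CoA inhibited),
#' the lumped CACT/CPT2 import step, four acyl-CoA dehydrogenases
#' (VLCAD, LCAD, MCAD, SCAD), a lumped enoyl-CoA hydratase + 3-hydroxyacyl-CoA
#' dehydrogenase step, and two 3-ketoacyl-CoA thiolases (MTP long-chain,
#' MCKAT medium-chain).
#'
#' @return Character vector of enzyme identifiers, in canonical order.
#' @export
bx_enzymes <- function() {
  c("CPT1B", "CACT_CPT2", "VLCAD", "LCAD", "MCAD", "SCAD",
    "HYD_HAD", "MTP", "MCKAT")
}

#' Acyl chain lengths tracked by the model
#' @return Integer vector: 16, 14, 12, 10, 8, 6, 4.
#' @export
bx_chains <- function() c(16L, 14L, 12L, 10L, 8L, 6L, 4L)

# Chain-specificity mask: which chain lengths each enzyme acts on.
# Standard substrate ranges; data, not code - overridable through Km entries.
.bx_masks <- function() {
  list(
    CPT1B     = 16L,
    CACT_CPT2 = 16L,
    VLCAD     = c(16L, 14L, 12L),
    LCAD      = c(16L, 14L, 12L, 10L, 8L),
    MCAD      = c(12L, 10L, 8L, 6L),
    SCAD      = c(6L, 4L),
    HYD_HAD   = c(16L, 14L, 12L, 10L, 8L, 6L, 4L),
    MTP       = c(16L, 14L, 12L, 10L, 8L),
    MCKAT     = c(12L, 10L, 8L, 6L, 4L)
  )
}

.bx_species_names <- function() {
  ch <- bx_chains()
  c("palmitoylCoA_cyt", "malonylCoA", "acylcarnitine_C16",
    paste0("acylCoA_C", ch), paste0("enoylCoA_C", ch),
    paste0("ketoacylCoA_C", ch), "acetylCoA", "CoA_free", "carnitine_free")
}

.bx_reaction_names <- function() {
  m <- .bx_masks()
  unlist(c("CPT1B.C16", "CACT_CPT2.C16",
           lapply(c("VLCAD", "LCAD", "MCAD", "SCAD", "HYD_HAD", "MTP", "MCKAT"),
                  function(e) paste0(e, ".C", m[[e]])),
           "SINK"), use.names = FALSE)
}

# Parameter set ---------------------------------------------------------------

#' Construct a beta-oxidation parameter set
#'
#' Bundles per-enzyme maximal rates, Michaelis constants per (enzyme, chain
#' length), the CPT1B malonyl-CoA inhibition constant, conserved moiety
#' totals and solver/unit options into a validated object.
#'
#' Units: `vmax` in umol min^-1 (mg total protein)^-1; all concentrations
#' and Km in muM; `k_sink` in min^-1. `vol_factor` converts per-mg-protein
#' rates into muM min^-1 (default 1e6, i.e. 1 uL matrix water per mg
#' protein); it rescales time only and cancels out of all flux-control
#' coefficients.
#'
#' @param vmax Named numeric, maximal rates for (a subset of) [bx_enzymes()].
#'   Unnamed defaults are filled in.
#' @param km Named list enzyme -> named numeric vector of Km per chain
#'   (names like "C16"). Defaults to one documented Km per enzyme across
#'   its chain-specificity mask.
#' @param ki_malonyl Malonyl-CoA inhibition constant of CPT1B, muM.
#' @param ki_acylcarnitine Product-inhibition constant of CPT1B by
#'   C16-acylcarnitine, muM; provides the back-pressure through which
#'   downstream saturation is communicated to the pathway entry.
#' @param km_carnitine CPT1B Km for free carnitine, muM.
#' @param km_coa_import,km_coa_thiolase Km for free CoA of the import step
#'   and of the thiolases, muM.
#' @param coa_total,carnitine_total Conserved moiety totals, muM.
#' @param k_sink First-order acetyl-CoA drain constant, min^-1, defined
#'   at the reference volume factor (1e6); changing `vol_factor` rescales
#'   all steps, including the sink, by the same factor.
#' @param vol_factor Unit bridge, muM min^-1 per umol min^-1 mg^-1.
#' @return Object of class `bx_parameter_set`.
#' @examples
#' ps <- bx_parameter_set()
#' ps$vmax[["CPT1B"]]
#' @export
bx_parameter_set <- function(vmax = NULL, km = NULL,
                             ki_malonyl = 0.05,
                             ki_acylcarnitine = 2,
                             km_carnitine = 125,
                             km_coa_import = 150,
                             km_coa_thiolase = 2,
                             coa_total = 500,
                             carnitine_total = 500,
                             k_sink = 50,
                             vol_factor = 1e6) {
  enz <- bx_enzymes()
  vm <- .bx_default_vmax()
  if (!is.null(vmax)) {
    if (is.null(names(vmax)) || !all(names(vmax) %in% enz))
      stop("vmax must be named with enzyme identifiers from bx_enzymes()")
    vm[names(vmax)] <- vmax
  }
  kms <- .bx_default_km()
  if (!is.null(km)) {
    if (is.null(names(km)) || !all(names(km) %in% enz))
      stop("km must be a named list keyed by enzyme")
    for (e in names(km)) kms[[e]][names(km[[e]])] <- km[[e]]
  }
  ps <- structure(list(
    vmax = vm, km = kms, ki_malonyl = ki_malonyl,
    ki_acylcarnitine = ki_acylcarnitine,
    km_carnitine = km_carnitine, km_coa_import = km_coa_import,
    km_coa_thiolase = km_coa_thiolase, coa_total = coa_total,
    carnitine_total = carnitine_total, k_sink = k_sink,
    vol_factor = vol_factor), class = "bx_parameter_set")
  bx_validate_params(ps)
  ps
}

# Defaults: order-of-magnitude choices for mouse quadriceps homogenate.
# Capacities are staged so that CPT1B dominates flux control at low
# palmitoyl-CoA while thiolytic capacity (MCKAT carries the C6/C4 cleavages
# exclusively) becomes co-limiting under substrate overload; acylcarnitine
# product inhibition of CPT1B communicates that saturation smoothly back
# to the entry step. Thiolases bind CoA with high affinity while the
# import step binds it weakly, so CoA depletion throttles import before
# cleavage (a stabilising negative feedback).
.bx_default_vmax <- function() {
  c(CPT1B = 1.0e-3, CACT_CPT2 = 4.0e-3, VLCAD = 3.0e-3, LCAD = 1.5e-3,
    MCAD = 3.0e-3, SCAD = 3.0e-3, HYD_HAD = 1.0e-2, MTP = 2.0e-3,
    MCKAT = 1.2e-3)
}

.bx_default_km <- function() {
  base <- c(CPT1B = 5, CACT_CPT2 = 10, VLCAD = 5, LCAD = 10, MCAD = 10,
            SCAD = 10, HYD_HAD = 10, MTP = 10, MCKAT = 15)
  m <- .bx_masks()
  out <- lapply(names(m), function(e) {
    v <- rep(base[[e]], length(m[[e]]))
    names(v) <- paste0("C", m[[e]])
    v
  })
  names(out) <- names(m)
  out
}

#' Validate a parameter set
#'
#' Checks completeness (every modelled enzyme has vmax and Km entries over
#' its chain mask), non-negativity of vmax and strict positivity of Km,
#' inhibition and moiety constants. Errors name the offending enzyme.
#'
#' @param ps A `bx_parameter_set`.
#' @return Invisibly, `ps`.
#' @export
bx_validate_params <- function(ps) {
  enz <- bx_enzymes()
  missing_vm <- setdiff(enz, names(ps$vmax))
  if (length(missing_vm))
    stop("missing vmax for enzyme(s): ", paste(missing_vm, collapse = ", "))
  if (any(!is.finite(ps$vmax)) || any(ps$vmax < 0))
    stop("vmax must be finite and >= 0 for: ",
         paste(names(ps$vmax)[!is.finite(ps$vmax) | ps$vmax < 0],
               collapse = ", "))
  m <- .bx_masks()
  for (e in enz) {
    need <- paste0("C", m[[e]])
    have <- names(ps$km[[e]])
    if (is.null(have) || !all(need %in% have))
      stop("missing Km entries for enzyme ", e, ": ",
           paste(setdiff(need, have), collapse = ", "))
    if (any(ps$km[[e]][need] <= 0))
      stop("Km must be > 0 for enzyme ", e)
  }
  scalars <- c("ki_malonyl", "ki_acylcarnitine", "km_carnitine", "km_coa_import",
               "km_coa_thiolase", "coa_total", "carnitine_total",
               "k_sink", "vol_factor")
  for (s in scalars)
    if (!is.numeric(ps[[s]]) || length(ps[[s]]) != 1 || ps[[s]] <= 0)
      stop("parameter '", s, "' must be a single positive number")
  invisible(ps)
}

# Pack into the flat structure the C++ core consumes.
.bx_pack <- function(ps) {
  bx_validate_params(ps)
  enz <- bx_enzymes()
  ch <- bx_chains()
  km <- matrix(Inf, nrow = length(enz), ncol = length(ch),
               dimnames = list(enz, paste0("C", ch)))
  m <- .bx_masks()
  for (e in enz) km[e, paste0("C", m[[e]])] <- ps$km[[e]][paste0("C", m[[e]])]
  list(vmax = unname(ps$vmax[enz]), km = unname(km),
       ki_malonyl = ps$ki_malonyl, ki_acylcarnitine = ps$ki_acylcarnitine,
       km_carnitine = ps$km_carnitine,
       km_coa_import = ps$km_coa_import, km_coa_thiolase = ps$km_coa_thiolase,
       coa_total = ps$coa_total, carnitine_total = ps$carnitine_total,
       k_sink = ps$k_sink, vol_factor = ps$vol_factor)
}

#' @export
print.bx_parameter_set <- function(x, ...) {
  cat("<bx_parameter_set>\n")
  cat("  vmax (umol/min/mg):\n")
  print(signif(x$vmax, 4))
  cat("  ki_malonyl:", x$ki_malonyl, "uM | CoA_total:", x$coa_total,
      "uM | carnitine_total:", x$carnitine_total, "uM\n")
  cat("  k_sink:", x$k_sink, "/min | vol_factor:", x$vol_factor, "\n")
  invisible(x)
}

# Parameter file I/O ----------------------------------------------------------

#' Write a parameter set to a flat key-value file
#'
#' Sections `[vmax]`, `[km]`, `[conserved]`, `[options]`; lines of the form
#' `key = value`. Km keys are `ENZYME.C<len>`; kinetic scalars
#' (`ki_malonyl`, `km_carnitine`, `km_coa_import`, `km_coa_thiolase`) live
#' in `[km]`.
#'
#' @param ps A `bx_parameter_set`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_parameter_file <- function(ps, path) {
  bx_validate_params(ps)
  fmt <- function(x) format(x, digits = 17, scientific = NA, trim = TRUE)
  lines <- c("# beta-oxidation model parameters",
             "# units: vmax umol/min/mg; Km, concentrations uM; k_sink 1/min",
             "[vmax]",
             paste(names(ps$vmax), "=", fmt(ps$vmax)),
             "[km]",
             unlist(lapply(names(ps$km), function(e)
               paste0(e, ".", names(ps$km[[e]]), " = ", fmt(ps$km[[e]])))),
             paste("ki_malonyl =", fmt(ps$ki_malonyl)),
             paste("ki_acylcarnitine =", fmt(ps$ki_acylcarnitine)),
             paste("km_carnitine =", fmt(ps$km_carnitine)),
             paste("km_coa_import =", fmt(ps$km_coa_import)),
             paste("km_coa_thiolase =", fmt(ps$km_coa_thiolase)),
             "[conserved]",
             paste("coa_total =", fmt(ps$coa_total)),
             paste("carnitine_total =", fmt(ps$carnitine_total)),
             "[options]",
             paste("k_sink =", fmt(ps$k_sink)),
             paste("vol_factor =", fmt(ps$vol_factor)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a parameter set from a flat key-value file
#'
#' @param path File written by [write_parameter_file()] (or hand-edited in
#'   the same schema).
#' @return A `bx_parameter_set`.
#' @export
read_parameter_file <- function(path) {
  if (!file.exists(path)) .verror("parameter file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- NA_character_
  store <- list(vmax = list(), km = list(), conserved = list(),
                options = list())
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (!section %in% names(store))
        stop("unknown parameter-file section: [", section, "]")
      next
    }
    if (is.na(section)) stop("key before any section header: ", ln)
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed line in parameter file: ", ln)
    key <- trimws(kv[1]); val <- suppressWarnings(as.numeric(trimws(kv[2])))
    if (is.na(val)) stop("non-numeric value for key '", key, "'")
    store[[section]][[key]] <- val
  }
  kmkeys <- names(store$km)
  is_pair <- grepl("\\.", kmkeys)
  km <- list()
  for (k in kmkeys[is_pair]) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    km[[parts[1]]] <- c(km[[parts[1]]],
                        stats::setNames(store$km[[k]], parts[2]))
  }
  scal <- store$km[!is_pair]
  bx_parameter_set(
    vmax = unlist(store$vmax), km = km,
    ki_malonyl = scal$ki_malonyl %||% 0.05,
    ki_acylcarnitine = scal$ki_acylcarnitine %||% 2,
    km_carnitine = scal$km_carnitine %||% 125,
    km_coa_import = scal$km_coa_import %||% 150,
    km_coa_thiolase = scal$km_coa_thiolase %||% 2,
    coa_total = store$conserved$coa_total %||% 500,
    carnitine_total = store$conserved$carnitine_total %||% 500,
    k_sink = store$options$k_sink %||% 50,
    vol_factor = store$options$vol_factor %||% 1e6)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
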