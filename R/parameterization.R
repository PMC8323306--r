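# Per-animal parameterization of the beta-oxidation model from targeted
# proteomics: catalytic constants are anchored on a liver reference
# (published liver Vmax over liver enzyme concentration) and applied to
# each animal's measured quadriceps concentrations, Vmax = kcat x E.

#' Default protein-to-enzyme mapping
#'
#' Maps targeted-proteomics protein identifiers onto the model's enzymatic
#' steps. CPT2 abundance proxies the lumped CACT/CPT2 import step; HADHA
#' (the MTP hydratase/HAD subunit) proxies the lumped hydratase+HAD step;
#' HADHB is the MTP long-chain thiolase; ACAA2 is MCKAT.
#'
#' @return Named character vector: names are protein identifiers, values
#'   are model enzymes.
#' @export
default_enzyme_map <- function() {
  c(CPT1B = "CPT1B", CPT2 = "CACT_CPT2", ACADVL = "VLCAD", ACADL = "LCAD",
    ACADM = "MCAD", ACADS = "SCAD", HADHA = "HYD_HAD", HADHB = "MTP",
    ACAA2 = "MCKAT")
}

#' Load the bundled liver reference table
#'
#' A SYNTHETIC stand-in for previously published liver data (per-enzyme
#' maximal rates and protein concentrations) used to anchor catalytic
#' constants. Values are order-of-magnitude plausible but NOT the
#' published ones; supply your own file for real analyses.
#'
#' @param path Optional path to a user-supplied tab-delimited file with
#'   columns `enzyme`, `vmax_umol_min_mg`, `conc_fmol_ug`.
#' @return data.frame with those three columns.
#' @export
liver_reference <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "liver_reference_synthetic.tsv",
                        package = "mitoflex", mustWork = TRUE)
  ref <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("enzyme", "vmax_umol_min_mg", "conc_fmol_ug")
  if (!all(need %in% names(ref)))
    stop("liver reference must have columns: ", paste(need, collapse = ", "))
  ref
}

#' Estimate catalytic constants from a liver reference
#'
#' kcat_e = liver Vmax_e / liver concentration_e, elementwise over a
#' common enzyme set. A zero liver Vmax yields kcat 0 with a warning (the
#' enzyme is effectively absent); a non-positive liver concentration is an
#' error.
#'
#' @param liver_vmax Named numeric, umol min^-1 mg^-1 per enzyme.
#' @param liver_conc Named numeric, fmol per ug total protein per enzyme.
#' @return Named numeric of class `kcat_table`:
#'   umol min^-1 mg^-1 per (fmol ug^-1).
#' @export
estimate_kcats <- function(liver_vmax, liver_conc) {
  if (is.null(names(liver_vmax)) || is.null(names(liver_conc)))
    stop("liver_vmax and liver_conc must be named by enzyme")
  if (!setequal(names(liver_vmax), names(liver_conc)))
    stop("enzyme sets differ between liver Vmax and concentrations: ",
         paste(union(setdiff(names(liver_vmax), names(liver_conc)),
                     setdiff(names(liver_conc), names(liver_vmax))),
               collapse = ", "))
  liver_conc <- liver_conc[names(liver_vmax)]
  bad <- names(liver_conc)[liver_conc <= 0]
  if (length(bad))
    stop("non-positive liver concentration for enzyme(s): ",
         paste(bad, collapse = ", "))
  zero <- names(liver_vmax)[liver_vmax == 0]
  if (length(zero))
    warning("liver Vmax is zero for ", paste(zero, collapse = ", "),
            "; kcat set to 0 (enzyme effectively absent)")
  if (any(liver_vmax < 0)) stop("liver Vmax must be >= 0")
  structure(liver_vmax / liver_conc, class = "kcat_table")
}

#' Compute per-animal maximal rates from catalytic constants
#'
#' Vmax_e = kcat_e x E_e for one animal's measured enzyme concentrations.
#'
#' @param kcats A [estimate_kcats()] result (or named numeric).
#' @param conc Named numeric, measured concentrations (fmol ug^-1) keyed
#'   by enzyme (after any protein-to-enzyme mapping).
#' @param impute Either `"error"` (default: a missing enzyme stops) or a
#'   named numeric of fallback concentrations (e.g. cohort means) used
#'   with a message.
#' @return Named numeric Vmax, umol min^-1 mg^-1.
#' @export
compute_vmax <- function(kcats, conc, impute = "error") {
  enz <- names(kcats)
  if (is.null(enz)) stop("kcats must be named by enzyme")
  missing <- setdiff(enz, names(conc)[!is.na(conc[enz])])
  missing <- union(missing, enz[is.na(conc[enz])])
  if (length(missing)) {
    if (identical(impute, "error"))
      stop("missing concentration for enzyme(s): ",
           paste(missing, collapse = ", "),
           " (supply impute= to fall back)")
    if (!all(missing %in% names(impute)))
      stop("imputation values missing for: ",
           paste(setdiff(missing, names(impute)), collapse = ", "))
    message("imputing concentrations for: ", paste(missing, collapse = ", "))
    conc[missing] <- impute[missing]
  }
  if (any(conc[enz] < 0)) stop("concentrations must be >= 0")
  stats::setNames(as.numeric(kcats) * as.numeric(conc[enz]), enz)
}

#' Build one animal's parameter set from a proteomics table
#'
#' Maps protein rows to model enzymes, computes Vmax via [compute_vmax()]
#' and overlays them on a base parameter set (kinetic constants unchanged:
#' only maximal rates are animal-specific).
#'
#' @param proteomics An [omics_table()] of protein concentrations
#'   (fmol ug^-1).
#' @param sample Sample (column) identifier.
#' @param kcats Named kcat vector, see [estimate_kcats()].
#' @param base Base [bx_parameter_set()] supplying kinetic constants.
#' @param map Protein-to-enzyme map, see [default_enzyme_map()].
#' @param impute Passed to [compute_vmax()].
#' @return A [bx_parameter_set()] with animal-specific Vmax.
#' @export
animal_parameters <- function(proteomics, sample, kcats,
                              base = bx_parameter_set(),
                              map = default_enzyme_map(),
                              impute = "error") {
  if (!sample %in% colnames(proteomics$values))
    stop("sample '", sample, "' not found in proteomics table")
  col <- proteomics$values[, sample]
  present <- intersect(names(map), rownames(proteomics$values))
  conc <- stats::setNames(col[present], unname(map[present]))
  vm <- compute_vmax(kcats[unname(map[present])], conc, impute = impute)
  need <- setdiff(bx_enzymes(), names(vm))
  if (length(need))
    stop("proteomics table lacks proteins for enzyme(s): ",
         paste(need, collapse = ", "))
  base$vmax[names(vm)] <- vm
  bx_validate_params(base)
  base
}

#' Build parameter sets for a whole cohort
#'
#' @inheritParams animal_parameters
#' @return Named list of [bx_parameter_set()], one per sample column.
#' @export
cohort_parameters <- function(proteomics, kcats,
                              base = bx_parameter_set(),
                              map = default_enzyme_map(),
                              impute = "error") {
  samples <- colnames(proteomics$values)
  out <- lapply(samples, function(s)
    animal_parameters(proteomics, s, kcats, base = base, map = map,
                      impute = impute))
  stats::setNames(out, samples)
}

#' Collapse peptide-level quantification to protein concentrations
#'
#' Each peptide's concentration is (endogenous area / standard area) x
#' known standard amount; a protein's concentration is the unweighted mean
#' of its surviving peptides. Peptides with a zero standard area are
#' dropped with a warning; proteins with no surviving peptide get NA.
#'
#' @param peptide_areas data.frame with columns `protein`, `peptide`,
#'   `area_endogenous`, `area_standard` (summed transition peak areas).
#' @param standard_amounts Named numeric, standard amount per peptide,
#'   fmol per ug injected total protein.
#' @return data.frame `protein`, `conc_fmol_ug`.
#' @export
peptide_to_protein <- function(peptide_areas, standard_amounts) {
  need <- c("protein", "peptide", "area_endogenous", "area_standard")
  if (!all(need %in% names(peptide_areas)))
    stop("peptide_areas must have columns: ", paste(need, collapse = ", "))
  missing <- setdiff(peptide_areas$peptide, names(standard_amounts))
  if (length(missing))
    stop("no standard amount for peptide(s): ",
         paste(missing, collapse = ", "))
  drop <- peptide_areas$area_standard <= 0
  if (any(drop)) {
    warning("dropping peptide(s) with zero standard area: ",
            paste(peptide_areas$peptide[drop], collapse = ", "))
    peptide_areas <- peptide_areas[!drop, , drop = FALSE]
  }
  conc <- with(peptide_areas,
               area_endogenous / area_standard *
                 standard_amounts[peptide])
  agg <- tapply(conc, peptide_areas$protein, mean)
  out <- data.frame(protein = names(agg), conc_fmol_ug = as.numeric(agg),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Correct a mitochondrial-preparation rate for enrichment
#'
#' Converts a rate per mg mitochondrial protein to a rate per mg tissue
#' protein using the citrate synthase enrichment ratio
#' R = CS_mito / CS_homogenate: corrected = rate / R.
#'
#' @param rate_mito Rate per mg mitochondrial protein.
#' @param cs_mito,cs_homog Citrate synthase activities in the
#'   mitochondrial preparation and the total homogenate (same units, > 0).
#' @return Rate per mg tissue protein.
#' @examples
#' enrichment_correct(100, cs_mito = 10, cs_homog = 1)  # 10
#' @export
enrichment_correct <- function(rate_mito, cs_mito, cs_homog) {
  if (any(cs_mito <= 0) || any(cs_homog <= 0))
    stop("citrate synthase activities must be > 0")
  rate_mito * cs_homog / cs_mito
}
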