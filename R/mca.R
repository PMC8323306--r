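# Metabolic control analysis over the beta-oxidation model.
#
# The flux-control coefficient (FCC) of an enzyme is the fractional change
# of the steady-state pathway flux per fractional change of that enzyme's
# maximal rate. It is estimated by the scaled forward finite difference
#   FCC ~= (dJ / dVmax) * (Vmax / J),  dVmax = Vmax * 1e-6,
# and the summation theorem (sum of FCCs over all rate-scaling steps = 1)
# is used as a global consistency check.

.bx_steps <- function(include_sink = TRUE) {
  c(bx_enzymes(), if (include_sink) "SINK")
}

.bx_perturb <- function(params, step, delta_rel) {
  if (step == "SINK") {
    dV <- params$k_sink * delta_rel
    params$k_sink <- params$k_sink + dV
  } else {
    dV <- params$vmax[[step]] * delta_rel
    params$vmax[[step]] <- params$vmax[[step]] + dV
  }
  list(params = params, dV = dV)
}

.bx_step_value <- function(params, step) {
  if (step == "SINK") params$k_sink else params$vmax[[step]]
}

#' Flux-control coefficient of one enzyme
#'
#' Forward finite-difference estimator with a relative perturbation of the
#' enzyme's maximal rate (default 1e-6). When the resulting flux change is
#' within 100x of the solver's residual tolerance, the estimate is
#' recomputed with a 1e-5 perturbation to step over differencing noise.
#'
#' @param params A [bx_parameter_set()].
#' @param enzyme One of [bx_enzymes()], or `"SINK"` for the acetyl-CoA
#'   drain.
#' @param S_cyt,M Clamped cytosolic palmitoyl-CoA and malonyl-CoA, muM.
#' @param delta_rel Relative perturbation of Vmax.
#' @param base Optional precomputed base [steady_state()] result (must
#'   match `params`, `S_cyt`, `M`).
#' @return The FCC (dimensionless scalar).
#' @export
fcc <- function(params, enzyme, S_cyt, M = 0, delta_rel = 1e-6,
                base = NULL) {
  steps <- .bx_steps(TRUE)
  if (!enzyme %in% steps)
    stop("unknown enzyme '", enzyme, "'; expected one of: ",
         paste(steps, collapse = ", "))
  if (.bx_step_value(params, enzyme) <= 0)
    stop("FCC undefined: Vmax of ", enzyme, " is not positive")
  if (is.null(base)) base <- .bx_solve_robust(params, S_cyt, M)
  if (!base$converged)
    stop("steady state did not converge at S_cyt = ", S_cyt,
         ", M = ", M)
  if (base$flux <= 0)
    stop("FCC undefined: steady-state flux is zero at S_cyt = ", S_cyt)
  est <- .bx_fcc_once(params, enzyme, S_cyt, M, delta_rel, base)
  # differencing-noise guard: retry with a 10x larger step if the flux
  # change is too close to the solver's noise floor
  noise <- 100 * max(base$residual, 1e-13) / params$vol_factor
  if (abs(est$dJ) < noise)
    est <- .bx_fcc_once(params, enzyme, S_cyt, M, delta_rel * 10, base)
  est$fcc
}

.bx_fcc_once <- function(params, enzyme, S_cyt, M, delta_rel, base) {
  pert <- .bx_perturb(params, enzyme, delta_rel)
  res <- .bx_solve_robust(pert$params, S_cyt, M, warm = base)
  if (!res$converged)
    stop("perturbed steady state did not converge for ", enzyme,
         " at S_cyt = ", S_cyt)
  dJ <- res$flux - base$flux
  list(fcc = (dJ / pert$dV) * .bx_step_value(params, enzyme) / base$flux,
       dJ = dJ)
}

# Robust solve: warm-started fast path; if the solver fails or lands on
# the spurious fully-sequestered fixed point (zero flux at S > 0 with a
# positive entry capacity), re-integrate from the empty state with a
# bounded pseudo-time step so that the physical attractor is followed.
.bx_solve_robust <- function(params, S_cyt, M, warm = NULL, rtol = 1e-9) {
  res <- steady_state(params, S_cyt, M, warm_start = warm, rtol = rtol)
  degenerate <- S_cyt > 0 && params$vmax[["CPT1B"]] > 0 &&
    res$flux < 1e-12
  if (!res$converged || degenerate) {
    ws <- NULL
    pack <- .bx_pack(params)
    raw <- .bx_steady_cpp(pack, S_cyt, M, ws, rtol, 200000L, 1.0)
    res2 <- structure(list(
      state = stats::setNames(c(S_cyt, M, raw$state), .bx_species_names()),
      flux = raw$flux, acylcarnitine_C16 = raw$acylcarnitine_C16,
      residual = raw$residual, converged = raw$converged,
      iterations = raw$iterations, S_cyt = S_cyt, M = M),
      class = "bx_steady_result")
    if (res2$converged && (res2$flux > res$flux || !res$converged))
      res <- res2
  }
  res
}

#' FCC-versus-substrate control profile
#'
#' Computes the steady-state flux and the FCC of each requested enzyme at
#' every point of a substrate grid, together with the summation-theorem
#' check over all rate-scaling steps.
#'
#' @param params A [bx_parameter_set()].
#' @param enzymes Character vector of enzymes to report (default CPT1B and
#'   MCKAT, the entry and cleavage candidates for flux control).
#' @param grid Substrate grid, muM.
#' @param M Malonyl-CoA, muM.
#' @param include_sink Whether the acetyl-CoA sink counts as a
#'   rate-scaling step in the summation check (default TRUE; the theorem
#'   only sums to 1 over all flux-scaling steps).
#' @param delta_rel Relative Vmax perturbation, see [fcc()].
#' @param summation_tol Tolerance for the summation check.
#' @return data.frame of class `bx_control_profile` with one row per
#'   (grid point, enzyme): `S_cyt_uM`, `malonylCoA_uM`, `flux`, `enzyme`,
#'   `fcc`. The per-point summation check is in `attr(, "summation")`.
#' @export
fcc_profile <- function(params, enzymes = c("CPT1B", "MCKAT"),
                        grid = substrate_grid(), M = 0,
                        include_sink = TRUE, delta_rel = 1e-6,
                        summation_tol = 0.02) {
  steps <- .bx_steps(include_sink)
  bad <- setdiff(enzymes, .bx_steps(TRUE))
  if (length(bad)) stop("unknown enzymes: ", paste(bad, collapse = ", "))
  rows <- vector("list", length(grid))
  sums <- numeric(length(grid))
  warm <- NULL
  for (i in seq_along(grid)) {
    S <- grid[i]
    base <- .bx_solve_robust(params, S, M, warm = warm)
    if (!base$converged)
      stop("steady state did not converge at grid point S_cyt = ", S)
    warm <- base
    allf <- vapply(steps, function(e)
      fcc(params, e, S, M, delta_rel = delta_rel, base = base), numeric(1))
    sums[i] <- sum(allf)
    want <- allf[intersect(enzymes, steps)]
    extra <- setdiff(enzymes, steps)  # e.g. SINK when excluded from sum
    if (length(extra))
      want <- c(want, vapply(extra, function(e)
        fcc(params, e, S, M, delta_rel = delta_rel, base = base),
        numeric(1)))
    rows[[i]] <- data.frame(S_cyt_uM = S, malonylCoA_uM = M,
                            flux = base$flux, enzyme = names(want),
                            fcc = unname(want), row.names = NULL)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("bx_control_profile", class(out))
  attr(out, "summation") <- data.frame(
    S_cyt_uM = grid, sum_fcc = sums,
    ok = abs(sums - 1) <= summation_tol)
  attr(out, "summation_steps") <- steps
  out
}

#' Cohort-level flux and control simulation
#'
#' Runs [flux_scan()] and [fcc_profile()] for each animal's parameter set
#' and summarises flux and FCCs per (age, diet) group as mean +/- SEM at
#' every grid point and malonyl-CoA level.
#'
#' @param cohort Named list of [bx_parameter_set()] objects, one per
#'   animal.
#' @param samples data.frame with columns `sample`, `age`, `diet` covering
#'   every cohort entry; at least one animal per group.
#' @param enzymes Enzymes whose FCCs are summarised.
#' @param grid Substrate grid, muM.
#' @param M_levels Malonyl-CoA levels to simulate, muM.
#' @return List with `animals` (per-animal long table of flux and FCCs)
#'   and `groups` (group mean and SEM per grid point, level, enzyme; the
#'   `enzyme` value `"flux"` carries the flux summary).
#' @export
cohort_simulation <- function(cohort, samples,
                              enzymes = c("CPT1B", "MCKAT"),
                              grid = substrate_grid(), M_levels = c(0, 0.2)) {
  if (!length(cohort)) stop("empty cohort")
  if (is.null(names(cohort)) ||
      !all(names(cohort) %in% samples$sample))
    stop("cohort must be named and covered by the sample sheet")
  samples <- samples[match(names(cohort), samples$sample), , drop = FALSE]
  groups <- interaction(samples$age, samples$diet, drop = FALSE)
  if (any(table(interaction(samples$age, samples$diet)) < 1))
    stop("every age x diet group needs at least one animal")
  per <- lapply(seq_along(cohort), function(i) {
    an <- names(cohort)[i]
    do.call(rbind, lapply(M_levels, function(M) {
      prof <- fcc_profile(cohort[[i]], enzymes = enzymes, grid = grid,
                          M = M)
      flux_rows <- unique(prof[, c("S_cyt_uM", "malonylCoA_uM", "flux")])
      rbind(
        data.frame(animal = an, age = samples$age[i], diet = samples$diet[i],
                   S_cyt_uM = flux_rows$S_cyt_uM,
                   malonylCoA_uM = flux_rows$malonylCoA_uM,
                   enzyme = "flux", value = flux_rows$flux),
        data.frame(animal = an, age = samples$age[i], diet = samples$diet[i],
                   S_cyt_uM = prof$S_cyt_uM,
                   malonylCoA_uM = prof$malonylCoA_uM,
                   enzyme = prof$enzyme, value = prof$fcc))
    }))
  })
  animals <- do.call(rbind, per)
  agg <- stats::aggregate(
    value ~ age + diet + S_cyt_uM + malonylCoA_uM + enzyme, data = animals,
    FUN = function(x) c(mean = mean(x),
                        sem = stats::sd(x) / sqrt(length(x)),
                        n = length(x)))
  groups_df <- cbind(agg[, c("age", "diet", "S_cyt_uM", "malonylCoA_uM",
                             "enzyme")],
                     as.data.frame(agg$value))
  groups_df$sem[is.na(groups_df$sem)] <- 0  # single-animal groups
  list(animals = animals, groups = groups_df)
}
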