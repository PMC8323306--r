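# Kinetic model of mitochondrial long-chain fatty-acid beta-oxidation.
#
# Palmitoyl-CoA (C16) enters through CPT1B (competitively inhibited by
# malonyl-CoA), is imported as C16-acylcarnitine by the lumped CACT/CPT2
# step, and is then chain-shortened by repeated dehydrogenation
# (VLCAD/LCAD/MCAD/SCAD), hydration + oxidation (lumped hydratase/HAD) and
# thiolysis (MTP long-chain, MCKAT medium/short-chain), releasing one
# acetyl-CoA per cycle (two in the final C4 cleavage). Acetyl-CoA drains
# through a first-order sink regenerating free CoA. CoA and carnitine
# moieties are conserved, which provides the physiological negative
# feedback: when downstream capacity saturates, ester pools sequester free
# CoA/carnitine and throttle entry.

#' Construct a model state
#'
#' A named concentration vector (muM) over all model species, including the
#' clamped boundary species (cytosolic palmitoyl-CoA and malonyl-CoA). Free
#' CoA and free carnitine default to the moiety totals minus the ester
#' pools.
#'
#' @param params A [bx_parameter_set()] supplying moiety totals.
#' @param palmitoylCoA_cyt Clamped cytosolic palmitoyl-CoA, muM.
#' @param malonylCoA Clamped malonyl-CoA, muM.
#' @param ... Named concentrations for individual species (see
#'   `bx_species()`), e.g. `acylCoA_C16 = 1`.
#' @return Named numeric vector of class `bx_state`.
#' @export
model_state <- function(params = bx_parameter_set(), palmitoylCoA_cyt = 0,
                        malonylCoA = 0, ...) {
  nm <- .bx_species_names()
  y <- stats::setNames(numeric(length(nm)), nm)
  y["palmitoylCoA_cyt"] <- palmitoylCoA_cyt
  y["malonylCoA"] <- malonylCoA
  extra <- list(...)
  if (length(extra)) {
    bad <- setdiff(names(extra), nm)
    if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
    y[names(extra)] <- unlist(extra)
  }
  if (!"CoA_free" %in% names(extra)) {
    esters <- sum(y[grep("^(acyl|enoyl|ketoacyl)CoA_C", nm)]) + y["acetylCoA"]
    y["CoA_free"] <- params$coa_total - esters
  }
  if (!"carnitine_free" %in% names(extra))
    y["carnitine_free"] <- params$carnitine_total - y["acylcarnitine_C16"]
  if (any(y < 0))
    stop("negative concentration for: ",
         paste(names(y)[y < 0], collapse = ", "))
  structure(y, class = c("bx_state", "numeric"))
}

#' Model species names
#' @return Character vector of all species, clamped boundaries first.
#' @export
bx_species <- function() .bx_species_names()

.bx_dynamic <- function(state) {
  # strip the two clamped entries; order matches the C++ layout
  unname(state[.bx_species_names()[-(1:2)]])
}

#' Elementary reaction rates
#'
#' Evaluates every (enzyme, chain-length) rate at a given state, muM/min.
#' CPT1B uses competitive malonyl-CoA inhibition (malonyl-CoA enters the
#' acyl-CoA binding denominator via M/Ki); every multi-substrate enzyme
#' shares one competitive denominator 1 + sum_l S_l/Km over its chain mask;
#' any rate with a zero substrate is zero.
#'
#' @param state A [model_state()].
#' @param params A [bx_parameter_set()].
#' @return Named numeric vector of reaction rates (names `ENZYME.C<len>`,
#'   plus `SINK`).
#' @export
reaction_rates <- function(state, params) {
  state <- .bx_check_state(state)
  v <- .bx_rates_cpp(.bx_dynamic(state), state[["palmitoylCoA_cyt"]],
                     state[["malonylCoA"]], .bx_pack(params))
  stats::setNames(v, .bx_reaction_names())
}

#' Time derivatives of all species
#'
#' Stoichiometric assembly of [reaction_rates()]: each cycle consumes an
#' acyl-CoA and produces the two-carbon-shorter acyl-CoA plus acetyl-CoA;
#' the sink drains acetyl-CoA and regenerates free CoA. Clamped boundary
#' species have zero derivative; the derivatives of each conserved moiety
#' sum to zero.
#'
#' @inheritParams reaction_rates
#' @return Named numeric vector, muM/min, one entry per species.
#' @export
time_derivatives <- function(state, params) {
  state <- .bx_check_state(state)
  dy <- .bx_deriv_cpp(.bx_dynamic(state), state[["palmitoylCoA_cyt"]],
                      state[["malonylCoA"]], .bx_pack(params))
  stats::setNames(c(0, 0, dy), .bx_species_names())
}

.bx_check_state <- function(state) {
  nm <- .bx_species_names()
  if (is.null(names(state)) || !all(nm %in% names(state)))
    stop("state must be a named vector covering all species in bx_species()")
  if (any(state[nm] < 0))
    stop("negative concentration for: ",
         paste(nm[state[nm] < 0], collapse = ", "))
  state
}

#' Integrate the model in time
#'
#' Classical RK4 on the full (non-reduced) system; intended for trajectory
#' inspection and conservation checks, not for steady-state computation
#' (use [steady_state()]).
#'
#' @inheritParams reaction_rates
#' @param times Numeric vector of output times (min), starting at 0.
#' @param substeps RK4 substeps per output interval.
#' @return Matrix, one row per time, one column per species (including the
#'   clamped boundaries, repeated).
#' @export
integrate_model <- function(state, params, times, substeps = 50) {
  state <- .bx_check_state(state)
  stopifnot(length(times) >= 2, !is.unsorted(times))
  out <- .bx_traj_cpp(.bx_dynamic(state), state[["palmitoylCoA_cyt"]],
                      state[["malonylCoA"]], .bx_pack(params), times,
                      as.integer(substeps))
  full <- cbind(palmitoylCoA_cyt = state[["palmitoylCoA_cyt"]],
                malonylCoA = state[["malonylCoA"]], out)
  colnames(full) <- .bx_species_names()
  rownames(full) <- format(times)
  full
}

#' Solve for the steady state of the beta-oxidation model
#'
#' Pseudo-transient continuation (adaptive implicit Euler in the reduced,
#' moiety-conserving coordinates) down to a relative derivative norm below
#' `rtol`, followed by a damped Newton polish towards machine-level
#' residuals. The steady-state CPT1 rate is the pathway flux readout.
#'
#' @param params A [bx_parameter_set()].
#' @param S_cyt Clamped cytosolic palmitoyl-CoA, muM (>= 0).
#' @param M Clamped malonyl-CoA, muM (>= 0).
#' @param warm_start Optional state (full or reduced vector) used as the
#'   starting point, e.g. a neighbouring steady state.
#' @param rtol Relative derivative-norm tolerance (of the rate scale).
#' @return Object of class `bx_steady_result`: `state` (a full
#'   [model_state()]-style vector), `flux` (steady-state CPT1 rate,
#'   umol min^-1 mg^-1), `acylcarnitine_C16` (muM), `residual`,
#'   `converged`, `iterations`.
#' @export
steady_state <- function(params, S_cyt, M = 0, warm_start = NULL,
                         rtol = 1e-9) {
  if (!is.numeric(S_cyt) || length(S_cyt) != 1 || S_cyt < 0)
    stop("S_cyt must be a single non-negative concentration (muM)")
  if (!is.numeric(M) || length(M) != 1 || M < 0)
    stop("M must be a single non-negative concentration (muM)")
  ws <- NULL
  if (!is.null(warm_start)) {
    ws <- if (inherits(warm_start, "bx_steady_result"))
      .bx_dynamic(warm_start$state) else as.numeric(warm_start)
  }
  res <- .bx_steady_cpp(.bx_pack(params), S_cyt, M, ws, rtol)
  y <- stats::setNames(c(S_cyt, M, res$state), .bx_species_names())
  structure(list(state = y, flux = res$flux,
                 acylcarnitine_C16 = res$acylcarnitine_C16,
                 residual = res$residual, converged = res$converged,
                 iterations = res$iterations,
                 S_cyt = S_cyt, M = M),
            class = "bx_steady_result")
}

#' @export
print.bx_steady_result <- function(x, ...) {
  cat("<bx_steady_result> S_cyt =", x$S_cyt, "uM, malonyl-CoA =", x$M,
      "uM\n  flux J =", signif(x$flux, 6),
      "umol/min/mg | C16-acylcarnitine =",
      signif(x$acylcarnitine_C16, 6), "uM\n  converged:", x$converged,
      "| residual:", format(x$residual, digits = 3), "\n")
  invisible(x)
}

#' Default logarithmic substrate grid
#' @param n Number of points.
#' @param from,to Grid limits, muM.
#' @return Numeric vector, log-spaced.
#' @export
substrate_grid <- function(n = 25, from = 0.1, to = 10) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Steady-state flux scan over a substrate grid
#'
#' Solves the steady state at each cytosolic palmitoyl-CoA level (warm
#' starting each point from its predecessor) and reports the CPT1 flux and
#' the C16-acylcarnitine level.
#'
#' @param params A [bx_parameter_set()].
#' @param grid Substrate grid, muM; default log-spaced over [0.1, 10].
#' @param M Clamped malonyl-CoA, muM.
#' @param rtol Solver tolerance, see [steady_state()].
#' @return data.frame with columns `S_cyt_uM`, `malonylCoA_uM`, `flux`,
#'   `acylcarnitine_C16_uM`, `converged`.
#' @export
flux_scan <- function(params, grid = substrate_grid(), M = 0, rtol = 1e-9) {
  if (any(grid < 0)) stop("substrate grid values must be >= 0")
  out <- vector("list", length(grid))
  prev <- NULL
  for (i in seq_along(grid)) {
    res <- steady_state(params, grid[i], M, warm_start = prev, rtol = rtol)
    if (!res$converged)
      warning("steady state did not converge at S_cyt = ", grid[i], " uM")
    out[[i]] <- data.frame(S_cyt_uM = grid[i], malonylCoA_uM = M,
                           flux = res$flux,
                           acylcarnitine_C16_uM = res$acylcarnitine_C16,
                           converged = res$converged)
    prev <- res
  }
  do.call(rbind, out)
}
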