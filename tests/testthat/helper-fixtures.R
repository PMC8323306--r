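# Shared fixtures and independent oracles.

# parameter set in which every step downstream of CPT1B is effectively
# non-limiting (1e4-fold capacity excess)
nonlimiting_params <- function(factor = 1e4) {
  ps <- bx_parameter_set()
  downstream <- setdiff(bx_enzymes(), "CPT1B")
  ps$vmax[downstream] <- ps$vmax[downstream] * factor
  ps$k_sink <- ps$k_sink * factor
  ps
}

# closed-form CPT1B rate at the clamped boundary (umol/min/mg): the
# inhibited Michaelis-Menten form with a saturating carnitine pool
cpt1_closed_form <- function(ps, S, M, carn_free = ps$carnitine_total) {
  s <- S / ps$km$CPT1B[["C16"]]
  den <- 1 + s + M / ps$ki_malonyl  # acylcarnitine ~ 0 in this limit
  fcarn <- carn_free / (ps$km_carnitine + carn_free)
  ps$vmax[["CPT1B"]] * (s / den) * fcarn
}

# multiplicative log-normal jitter on all maximal rates; the stated
# "random parameter set" for numeric validation (CV 10%)
random_params <- function() {
  ps <- bx_parameter_set()
  ps$vmax <- ps$vmax * exp(stats::rnorm(length(ps$vmax), 0, 0.1))
  ps
}

# independent central-difference FCC oracle (relative step 1e-4)
fcc_central_oracle <- function(ps, enzyme, S, M = 0) {
  v0 <- if (enzyme == "SINK") ps$k_sink else ps$vmax[[enzyme]]
  dv <- v0 * 1e-4
  bump <- function(delta) {
    p <- ps
    if (enzyme == "SINK") p$k_sink <- p$k_sink + delta
    else p$vmax[[enzyme]] <- p$vmax[[enzyme]] + delta
    steady_state(p, S, M)$flux
  }
  j0 <- steady_state(ps, S, M)$flux
  (bump(dv) - bump(-dv)) / (2 * dv) * v0 / j0
}

# tiny omics table: planted matrix + labels
tiny_omics <- function(values, ages, diets, classes = NULL) {
  samples <- data.frame(sample = colnames(values), age = ages, diet = diets,
                        stringsAsFactors = FALSE)
  omics_table(values, samples, classes)
}

# noiseless curve from the fitted family
make_ogtt_points <- function(pars, times) {
  vapply(times, function(t)
    pars$C_b + pars$C_1 * (exp(-pars$k_e1 * t) - exp(-pars$k_a * t)) +
      pars$C_2 * exp(-pars$k_e2 * t), numeric(1))
}
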