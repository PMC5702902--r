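# Cortisol-driven nuclear-receptor control of hepatic CYP3A4.
#
# Cortisol binds three receptors with affinities spanning four orders of
# magnitude (Kd ~ 1 nM MR, 10 nM GR, 10 uM PXR), so different receptor sets
# engage at different cortisol levels. The module implements the minimal
# motif set: rapid-equilibrium ligand binding, activated-GR repression of GR
# synthesis (negative feedback), activated-GR induction of PXR synthesis
# (positive feedforward), and saturable CYP3A4 induction by activated PXR
# (plus a weaker activated-GR term), with first-order degradations tuned to
# hours-scale responses. MR is carried in the affinity ladder for occupancy
# calculations but has no downstream edge here. Synthesis rates are
# back-calculated so that the unperturbed system rests exactly at the
# homeostatic reference state (705 nM total liver CYP3A4).

#' Receptor occupancy at rapid binding equilibrium
#'
#' @param ligand Ligand concentration (nM).
#' @param kd Equilibrium dissociation constant (nM).
#' @return Occupied fraction `ligand / (ligand + kd)` in `[0, 1]`.
#' @export
receptor_occupancy <- function(ligand, kd) {
  stopifnot(all(ligand >= 0), all(kd >= 0))
  ifelse(ligand == 0, 0, ligand / (ligand + kd))
}

#' Linear CYP3A4-to-metabolism coupling
#'
#' The phase-I metabolism rate scales directly with the relative CYP3A4
#' level: a 10% increase in CYP3A4 (705 -> 775 nM) gives a 10% faster
#' conversion of parent drug to metabolite.
#'
#' @param cyp3a4 Current total liver CYP3A4 (nM).
#' @param cyp3a4_ref Homeostatic reference level (nM), default 705.
#' @return Dimensionless scale `cyp3a4 / cyp3a4_ref`.
#' @export
cyp3a4_scale <- function(cyp3a4, cyp3a4_ref = 705) {
  stopifnot(cyp3a4_ref > 0, all(cyp3a4 >= 0))
  cyp3a4 / cyp3a4_ref
}

#' Gene-regulatory network parameters
#'
#' All concentrations in nM, rates in 1/h. Defaults give hours-scale
#' dynamics and, by construction, a steady state at the reference levels
#' under baseline cortisol (synthesis rates are back-calculated from the
#' degradation rates at the reference state).
#'
#' @param kd_mr,kd_gr,kd_pxr Cortisol dissociation constants (nM); the
#'   default ladder is 1 nM (MR), 10 nM (GR), 1e4 nM = 10 uM (PXR).
#' @param gr_ref,pxr_ref Total receptor reference levels (nM).
#' @param cyp3a4_ref Homeostatic total liver CYP3A4 (nM).
#' @param k_deg_gr,k_deg_pxr,k_deg_cyp First-order degradation rates (1/h).
#' @param fb_k Activated-GR level (nM) halving GR synthesis (negative
#'   feedback strength).
#' @param ff_gain,ff_k Maximal fold-stimulation and half-saturation (nM) of
#'   PXR synthesis by activated GR (positive feedforward).
#' @param w_gr,w_pxr Weights of activated GR/PXR in the CYP3A4 induction
#'   drive.
#' @param k_cyp Half-saturation (nM) of the CYP3A4 induction function.
#' @param cortisol_baseline Homeostatic plasma cortisol (nM).
#' @param stress_multiplier Sustained fold-elevation of cortisol under
#'   chronic stress.
#' @return A `grn_parameters` object.
#' @export
grn_parameters <- function(kd_mr = 1, kd_gr = 10, kd_pxr = 1e4,
                           gr_ref = 200, pxr_ref = 100, cyp3a4_ref = 705,
                           k_deg_gr = 0.2, k_deg_pxr = 0.2, k_deg_cyp = 0.1,
                           fb_k = 100, ff_gain = 2, ff_k = 500,
                           w_gr = 0.2, w_pxr = 1, k_cyp = 50,
                           cortisol_baseline = 100, stress_multiplier = 5) {
  stopifnot(kd_mr >= 0, kd_gr >= 0, kd_pxr >= 0, cyp3a4_ref > 0,
            k_deg_gr >= 0, k_deg_pxr >= 0, k_deg_cyp >= 0, fb_k > 0,
            ff_gain >= 0, ff_k > 0, k_cyp > 0, cortisol_baseline >= 0,
            stress_multiplier >= 1, gr_ref > 0, pxr_ref > 0)
  p <- list(kd_mr = kd_mr, kd_gr = kd_gr, kd_pxr = kd_pxr,
            gr_ref = gr_ref, pxr_ref = pxr_ref, cyp3a4_ref = cyp3a4_ref,
            k_deg_gr = k_deg_gr, k_deg_pxr = k_deg_pxr, k_deg_cyp = k_deg_cyp,
            fb_k = fb_k, ff_gain = ff_gain, ff_k = ff_k,
            w_gr = w_gr, w_pxr = w_pxr, k_cyp = k_cyp,
            cortisol_baseline = cortisol_baseline,
            stress_multiplier = stress_multiplier)
  # back-calculate synthesis rates so baseline cortisol holds the reference
  a_gr0 <- gr_ref * receptor_occupancy(cortisol_baseline, kd_gr)
  a_pxr0 <- pxr_ref * receptor_occupancy(cortisol_baseline, kd_pxr)
  p$k_syn_gr <- k_deg_gr * gr_ref * (1 + a_gr0 / fb_k)
  p$k_syn_pxr <- k_deg_pxr * pxr_ref /
    (1 + ff_gain * a_gr0 / (a_gr0 + ff_k))
  drive0 <- w_pxr * a_pxr0 + w_gr * a_gr0
  p$k_syn_cyp <- k_deg_cyp * cyp3a4_ref * (k_cyp + drive0) / drive0
  structure(p, class = "grn_parameters")
}

#' Reference (homeostatic) GRN state
#' @param params A `grn_parameters` object.
#' @return Named vector `gr`, `pxr`, `cyp3a4` (total pools, nM).
#' @export
grn_init_state <- function(params) {
  c(gr = params$gr_ref, pxr = params$pxr_ref, cyp3a4 = params$cyp3a4_ref)
}

#' Ligand-bound (activated) receptor pools
#'
#' @param state Named vector with `gr`, `pxr` total pools (nM).
#' @param params A `grn_parameters` object.
#' @param cortisol Cortisol concentration (nM).
#' @return Named vector `mr_occupancy`, `a_gr`, `a_pxr`.
#' @export
grn_activated <- function(state, params, cortisol) {
  c(mr_occupancy = receptor_occupancy(cortisol, params$kd_mr),
    a_gr = unname(state[["gr"]] * receptor_occupancy(cortisol, params$kd_gr)),
    a_pxr = unname(state[["pxr"]] *
                     receptor_occupancy(cortisol, params$kd_pxr)))
}

#' GRN state derivatives
#'
#' GR synthesis repressed by activated GR; PXR synthesis induced by
#' activated GR; CYP3A4 synthesis a saturating function of the weighted
#' activated-receptor drive; first-order degradation of all three pools.
#'
#' @param state Named vector `gr`, `pxr`, `cyp3a4` (nM).
#' @param t Time (h); unused except for the deSolve signature.
#' @param params A `grn_parameters` object.
#' @param cortisol Cortisol input (nM) at time `t`.
#' @return List whose first element is the derivative vector.
#' @export
grn_derivatives <- function(state, t, params, cortisol) {
  y <- pmax(state, 0)
  act <- grn_activated(y, params, cortisol)
  a_gr <- act[["a_gr"]]; a_pxr <- act[["a_pxr"]]
  drive <- params$w_pxr * a_pxr + params$w_gr * a_gr
  d <- c(
    gr = params$k_syn_gr / (1 + a_gr / params$fb_k) -
      params$k_deg_gr * y[["gr"]],
    pxr = params$k_syn_pxr *
      (1 + params$ff_gain * a_gr / (a_gr + params$ff_k)) -
      params$k_deg_pxr * y[["pxr"]],
    cyp3a4 = params$k_syn_cyp * drive / (params$k_cyp + drive) -
      params$k_deg_cyp * y[["cyp3a4"]])
  list(d)
}

#' Cortisol input schedule
#'
#' @param kind `"homeostatic"` (constant baseline) or `"chronic_stress"`
#'   (sustained elevation at `stress_multiplier` times baseline, optionally
#'   with exponentially decaying boluses on top).
#' @param params A `grn_parameters` object.
#' @param bolus_times,bolus_amplitude,bolus_decay Optional bolus train for
#'   the chronic-stress schedule (times h, amplitude nM, decay 1/h).
#' @return Function of time `t` (h) returning cortisol (nM).
#' @export
cortisol_schedule <- function(kind = c("homeostatic", "chronic_stress"),
                              params, bolus_times = numeric(0),
                              bolus_amplitude = 0, bolus_decay = 1) {
  kind <- match.arg(kind)
  base <- params$cortisol_baseline
  if (kind == "homeostatic") return(function(t) rep(base, length(t)))
  mult <- params$stress_multiplier
  function(t) {
    out <- rep(base * mult, length(t))
    for (tb in bolus_times)
      out <- out + ifelse(t >= tb,
                          bolus_amplitude * exp(-bolus_decay * (t - tb)), 0)
    out
  }
}

#' Simulate the GRN alone
#'
#' @param params A `grn_parameters` object.
#' @param t_grid Strictly increasing times (h).
#' @param cortisol_input Function of time returning cortisol (nM); defaults
#'   to the homeostatic schedule.
#' @param state0 Optional initial state (default: homeostatic reference).
#' @return Data frame `time`, `gr`, `pxr`, `cyp3a4`, `cortisol`,
#'   `cyp3a4_scale`.
#' @export
grn_simulate <- function(params, t_grid, cortisol_input = NULL,
                         state0 = NULL) {
  stopifnot(all(diff(t_grid) > 0))
  if (is.null(cortisol_input))
    cortisol_input <- cortisol_schedule("homeostatic", params)
  y0 <- if (is.null(state0)) grn_init_state(params) else state0
  sol <- deSolve::lsoda(y0, t_grid,
                        function(t, y, p) grn_derivatives(y, t, params,
                                                          cortisol_input(t)),
                        parms = NULL, rtol = 1e-8, atol = 1e-8)
  out <- as.data.frame(sol)
  names(out)[1] <- "time"
  out$cortisol <- cortisol_input(out$time)
  out$cyp3a4_scale <- cyp3a4_scale(out$cyp3a4, params$cyp3a4_ref)
  out
}
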