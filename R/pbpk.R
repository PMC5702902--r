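# Whole-body perfusion-limited PBPK model for a parent drug and its toxic
# metabolite. Amounts are tracked in mg (metabolite in parent mass
# equivalents, 1:1 formation stoichiometry); concentrations in mg/L; flows
# in L/h; time in h. The liver holds the two molecular processes: phase-I
# conversion of parent to metabolite, scaled by the relative CYP3A4 level,
# and glutathione (GSH) conjugation of the metabolite, scaled by the
# GSH-availability factor computed from the metabolic network.

.pbpk_tissues <- c("lung", "adipose", "bone", "brain", "gut", "heart",
                   "kidney", "liver", "muscle", "skin", "spleen", "rest")

default_pbpk_physiology <- function() {
  co <- 390  # cardiac output, L/h (70 kg adult)
  frac <- c(adipose = 0.05, bone = 0.05, brain = 0.12, gut = 0.15,
            heart = 0.04, kidney = 0.19, liver = 0.065, muscle = 0.17,
            skin = 0.05, spleen = 0.03, rest = 0.085)
  vols <- c(lung = 0.5, adipose = 18.2, bone = 10.5, brain = 1.45,
            gut = 1.65, heart = 0.33, kidney = 0.31, liver = 1.8,
            muscle = 29.0, skin = 3.41, spleen = 0.15, rest = 4.0,
            arterial = 1.7, venous = 3.4)
  list(cardiac_output = co,
       flows = c(lung = co, frac * co),   # liver entry is hepatic artery only
       volumes = vols)
}

#' PBPK model parameters
#'
#' A 14-compartment perfusion-limited human (12 tissues plus arterial and
#' venous blood; lung in series with the heart), with an example drug
#' metabolised in the liver by CYP3A4 to a toxic metabolite that is cleared
#' by GSH conjugation. Physiological volumes/flows default to a standard
#' 70-kg adult; drug parameters are example values within physiological
#' ranges and every value can be overridden.
#'
#' @param volumes Named vector of compartment volumes (L).
#' @param flows Named vector of tissue blood flows (L/h); `lung` equals
#'   cardiac output; liver inflow is hepatic artery + gut + spleen outflow.
#' @param kp,kp_met Tissue:plasma partition coefficients (single number or
#'   named per-tissue vector) for parent and metabolite.
#' @param fup,fup_met Fraction unbound in plasma (0 < fup <= 1).
#' @param bp,bp_met Blood:plasma concentration ratios.
#' @param cl_phase1 Phase-I (CYP3A4) intrinsic clearance of the parent at
#'   the reference enzyme level (L/h).
#' @param clmet GSH-conjugation intrinsic clearance of the metabolite (L/h).
#' @param cl_renal Renal clearance of the parent (L/h).
#' @param mw Molar mass (g/mol), used to convert liver concentrations to
#'   molar units for enzyme-inhibition links.
#' @param dosing List: `route` (`"iv_bolus"`, `"iv_infusion"` or `"oral"`),
#'   `dose` (mg), `times` (h), `ka` (1/h, oral), `duration` (h, infusion).
#' @param solver List of integrator settings (`rtol`, `atol`, `hmax`).
#' @return A `pbpk_parameters` object.
#' @export
pbpk_parameters <- function(volumes = NULL, flows = NULL,
                            kp = 1, kp_met = 1,
                            fup = 0.3, fup_met = 0.3,
                            bp = 1, bp_met = 1,
                            cl_phase1 = 30, clmet = 12, cl_renal = 0,
                            mw = 151.2,
                            dosing = list(route = "iv_bolus", dose = 500,
                                          times = 0),
                            solver = list(rtol = 1e-8, atol = 1e-8,
                                          hmax = NULL)) {
  phys <- default_pbpk_physiology()
  v <- phys$volumes; if (!is.null(volumes)) v[names(volumes)] <- volumes
  q <- phys$flows; if (!is.null(flows)) q[names(flows)] <- flows
  stopifnot(all(v > 0), all(q > 0), fup > 0, fup <= 1, fup_met > 0,
            fup_met <= 1)
  expand_kp <- function(kp) {
    tissues <- .pbpk_tissues
    out <- stats::setNames(rep(1, length(tissues)), tissues)
    if (length(kp) == 1L && is.null(names(kp))) out[] <- kp
    else out[names(kp)] <- kp
    out
  }
  dosing <- utils::modifyList(list(route = "iv_bolus", dose = 500, times = 0,
                                   ka = 1, duration = 1), dosing)
  stopifnot(dosing$route %in% c("iv_bolus", "iv_infusion", "oral"))
  solver <- utils::modifyList(list(rtol = 1e-8, atol = 1e-8, hmax = NULL),
                              solver)
  structure(list(topology = "whole_body", volumes = v, flows = q,
                 kp = expand_kp(kp), kp_met = expand_kp(kp_met),
                 fup = fup, fup_met = fup_met, bp = bp, bp_met = bp_met,
                 cl_phase1 = cl_phase1, clmet = clmet, cl_renal = cl_renal,
                 mw = mw, dosing = dosing, solver = solver),
            class = "pbpk_parameters")
}

#' Reduced one-compartment parameterisation
#'
#' Collapses the PBPK distribution topology to a single well-stirred volume
#' with the same liver biochemistry (phase-I formation, GSH conjugation) and
#' dosing machinery. Used for verification against closed-form kinetics:
#' with only phase-I clearance active the parent follows
#' `C(t) = C0 exp(-(fup CL / V) t)`.
#'
#' @param volume Compartment volume (L).
#' @inheritParams pbpk_parameters
#' @return A `pbpk_parameters` object with `topology = "one_compartment"`.
#' @export
pbpk_parameters_onecomp <- function(volume = 42, fup = 1, fup_met = 1,
                                    cl_phase1 = 10, clmet = 12,
                                    mw = 151.2,
                                    dosing = list(route = "iv_bolus",
                                                  dose = 100, times = 0),
                                    solver = list(rtol = 1e-10, atol = 1e-10,
                                                  hmax = NULL)) {
  p <- pbpk_parameters(fup = fup, fup_met = fup_met, cl_phase1 = cl_phase1,
                       clmet = clmet, mw = mw, dosing = dosing,
                       solver = solver)
  p$topology <- "one_compartment"
  p$volume <- volume
  p
}

#' GSH conjugation rate of the toxic metabolite
#'
#' `rate = SF * CLmet * (Atox / Vli) * fup`: intrinsic clearance times the
#' unbound liver concentration of the metabolite, scaled by the
#' GSH-availability factor `SF` computed from maximal GSH production of the
#' liver network. `SF = 0` (GSH production abolished) shuts conjugation
#' down entirely.
#'
#' @param sf Scaling factor (>= 0), dimensionless.
#' @param clmet Intrinsic conjugation clearance (L/h).
#' @param atox Amount of toxic metabolite in the liver (mg).
#' @param vli Liver volume (L).
#' @param fup Fraction unbound in plasma.
#' @return Elimination rate (mg/h).
#' @export
gsh_conjugation_rate <- function(sf, clmet, atox, vli, fup) {
  stopifnot(sf >= 0, clmet >= 0, atox >= 0, vli > 0, fup >= 0)
  sf * clmet * (atox / vli) * fup
}

pbpk_state_names <- function(params) {
  if (params$topology == "one_compartment")
    c("depot", "p_central", "m_central", "cum_formed", "cum_elim_met",
      "cum_elim_parent")
  else
    c("depot", paste0("p_", c("venous", "arterial", .pbpk_tissues)),
      paste0("m_", c("venous", "arterial", .pbpk_tissues)),
      "cum_formed", "cum_elim_met", "cum_elim_parent")
}

#' Initial (drug-free) PBPK state
#' @param params A `pbpk_parameters` object.
#' @return Named numeric vector of amounts (mg), all zero.
#' @export
pbpk_init_state <- function(params) {
  stats::setNames(numeric(length(pbpk_state_names(params))),
                  pbpk_state_names(params))
}

# infusion input rate into venous blood at time t (mg/h)
infusion_rate <- function(t, dosing) {
  if (dosing$route != "iv_infusion") return(0)
  on <- vapply(dosing$times, function(t0)
    t >= t0 && t < t0 + dosing$duration, logical(1))
  sum(on) * dosing$dose / dosing$duration
}

#' PBPK state derivatives
#'
#' Perfusion-limited mass balances. In the liver, the parent is converted to
#' the toxic metabolite at `cyp3a4_scale * CL_phaseI * Cu` (`Cu` = unbound
#' plasma-equivalent liver concentration) with 1:1 mass stoichiometry, and
#' the metabolite is eliminated at [gsh_conjugation_rate()] with
#' `SF = gsh_scale`. Negative state excursions from the integrator are
#' clipped to zero.
#'
#' @param state Named numeric vector of amounts (mg).
#' @param t Time (h).
#' @param params A `pbpk_parameters` object.
#' @param cyp3a4_scale Relative CYP3A4 level (1 = reference).
#' @param gsh_scale GSH-availability scaling factor (1 = wild type).
#' @return List whose first element is the derivative vector (deSolve
#'   convention).
#' @export
pbpk_derivatives <- function(state, t, params, cyp3a4_scale = 1,
                             gsh_scale = 1) {
  stopifnot(cyp3a4_scale >= 0, gsh_scale >= 0)
  y <- pmax(state, 0)
  d <- stats::setNames(numeric(length(y)), names(y))
  dsg <- params$dosing
  rin <- infusion_rate(t, dsg)
  if (params$topology == "one_compartment") {
    V <- params$volume
    cu_p <- params$fup * y[["p_central"]] / V
    cu_m <- params$fup_met * y[["m_central"]] / V
    form <- cyp3a4_scale * params$cl_phase1 * cu_p
    elim <- gsh_conjugation_rate(gsh_scale, params$clmet, y[["m_central"]],
                                 V, params$fup_met)
    ka_in <- if (dsg$route == "oral") dsg$ka * y[["depot"]] else 0
    d[["depot"]] <- -ka_in
    d[["p_central"]] <- rin + ka_in - form -
      params$cl_renal * cu_p
    d[["m_central"]] <- form - elim
    d[["cum_formed"]] <- form
    d[["cum_elim_met"]] <- elim
    d[["cum_elim_parent"]] <- params$cl_renal * cu_p
    return(list(d))
  }
  v <- params$volumes; q <- params$flows
  ql_in <- q[["liver"]] + q[["gut"]] + q[["spleen"]]
  one_species <- function(prefix, kp, bp, fup) {
    A <- function(cmp) y[[paste0(prefix, "_", cmp)]]
    conc_out <- function(cmp) A(cmp) / v[[cmp]] / (kp[[cmp]] / bp)
    dd <- stats::setNames(numeric(14), c("venous", "arterial", .pbpk_tissues))
    c_ven <- A("venous") / v[["venous"]]
    c_art <- A("arterial") / v[["arterial"]]
    dd[["lung"]] <- q[["lung"]] * (c_ven - conc_out("lung"))
    dd[["arterial"]] <- q[["lung"]] * conc_out("lung") -
      sum(q[c("adipose", "bone", "brain", "gut", "heart", "kidney", "liver",
              "muscle", "skin", "spleen", "rest")]) * c_art
    for (tis in c("adipose", "bone", "brain", "heart", "kidney", "muscle",
                  "skin", "rest"))
      dd[[tis]] <- q[[tis]] * (c_art - conc_out(tis))
    dd[["gut"]] <- q[["gut"]] * (c_art - conc_out("gut"))
    dd[["spleen"]] <- q[["spleen"]] * (c_art - conc_out("spleen"))
    dd[["liver"]] <- q[["liver"]] * c_art + q[["gut"]] * conc_out("gut") +
      q[["spleen"]] * conc_out("spleen") - ql_in * conc_out("liver")
    dd[["venous"]] <- sum(vapply(c("adipose", "bone", "brain", "heart",
                                   "kidney", "muscle", "skin", "rest"),
                                 function(tis) q[[tis]] * conc_out(tis),
                                 numeric(1))) +
      ql_in * conc_out("liver") - q[["lung"]] * c_ven
    dd
  }
  dp <- one_species("p", params$kp, params$bp, params$fup)
  dm <- one_species("m", params$kp_met, params$bp_met, params$fup_met)
  # liver biochemistry
  cu_li_p <- params$fup * (y[["p_liver"]] / v[["liver"]]) / params$kp[["liver"]]
  form <- cyp3a4_scale * params$cl_phase1 * cu_li_p
  elim <- gsh_conjugation_rate(gsh_scale, params$clmet, y[["m_liver"]],
                               v[["liver"]], params$fup_met)
  dp[["liver"]] <- dp[["liver"]] - form
  dm[["liver"]] <- dm[["liver"]] + form - elim
  # renal elimination of parent
  cu_ki_p <- params$fup * (y[["p_kidney"]] / v[["kidney"]]) /
    params$kp[["kidney"]]
  ren <- params$cl_renal * cu_ki_p
  dp[["kidney"]] <- dp[["kidney"]] - ren
  ka_in <- if (dsg$route == "oral") dsg$ka * y[["depot"]] else 0
  dp[["gut"]] <- dp[["gut"]] + ka_in
  dp[["venous"]] <- dp[["venous"]] + rin
  d[["depot"]] <- -ka_in
  for (cmp in names(dp)) d[[paste0("p_", cmp)]] <- dp[[cmp]]
  for (cmp in names(dm)) d[[paste0("m_", cmp)]] <- dm[[cmp]]
  d[["cum_formed"]] <- form
  d[["cum_elim_met"]] <- elim
  d[["cum_elim_parent"]] <- ren
  list(d)
}

bolus_events <- function(params, t_max) {
  dsg <- params$dosing
  if (!dsg$route %in% c("iv_bolus", "oral")) return(NULL)
  times <- dsg$times[dsg$times <= t_max]
  if (!length(times)) return(NULL)
  var <- if (dsg$route == "oral") "depot"
         else if (params$topology == "one_compartment") "p_central"
         else "p_venous"
  data.frame(var = var, time = times, value = dsg$dose, method = "add",
             stringsAsFactors = FALSE)
}

#' Total administered dose up to time t
#' @param params A `pbpk_parameters` object.
#' @param t Time (h).
#' @return mg administered over `[0, t]`.
#' @export
administered_dose <- function(params, t) {
  dsg <- params$dosing
  if (dsg$route %in% c("iv_bolus", "oral"))
    return(sum(dsg$times <= t) * dsg$dose)
  sum(pmin(pmax(t - dsg$times, 0), dsg$duration) / dsg$duration * dsg$dose)
}

#' Simulate the PBPK model
#'
#' Deterministic integration (deSolve, `lsoda`) over a strictly increasing
#' time grid. `scale_series` applies piecewise-constant CYP3A4 and GSH
#' scaling factors: each row holds from its `time` until the next row's,
#' honoured exactly at the boundaries (the integrator is restarted there).
#'
#' @param params A `pbpk_parameters` object.
#' @param t_grid Strictly increasing output times (h), starting at the
#'   simulation start.
#' @param scale_series Optional data frame `time`, `cyp3a4_scale`,
#'   `gsh_scale`; default holds both scales at 1.
#' @param state0 Optional initial state (default drug-free).
#' @return A `pbpk_trajectory`: data frame of amounts per compartment plus
#'   liver concentrations `c_liver_parent`, `c_liver_met` (mg/L) and a
#'   `mass_balance_error` column (fraction of administered dose).
#' @export
pbpk_simulate <- function(params, t_grid, scale_series = NULL,
                          state0 = NULL) {
  stopifnot(length(t_grid) >= 2, all(diff(t_grid) > 0))
  if (is.null(scale_series))
    scale_series <- data.frame(time = t_grid[1], cyp3a4_scale = 1,
                               gsh_scale = 1)
  stopifnot(all(c("time", "cyp3a4_scale", "gsh_scale") %in%
                  names(scale_series)))
  y <- if (is.null(state0)) pbpk_init_state(params) else state0
  ev <- bolus_events(params, max(t_grid))
  brk <- sort(unique(c(t_grid[1], scale_series$time, max(t_grid))))
  brk <- brk[brk >= t_grid[1] & brk <= max(t_grid)]
  out_rows <- list()
  deriv_fn <- function(t, y, parms)
    pbpk_derivatives(y, t, params, parms$cyp, parms$gsh)
  for (k in seq_len(length(brk) - 1L)) {
    t0 <- brk[k]; t1 <- brk[k + 1L]
    i <- findInterval(t0, scale_series$time)
    sc <- list(cyp = scale_series$cyp3a4_scale[max(i, 1)],
               gsh = scale_series$gsh_scale[max(i, 1)])
    ev_k <- if (!is.null(ev)) ev[ev$time >= t0 & ev$time < t1, , drop = FALSE]
    # doses falling exactly on the segment start are applied to the state
    # directly; the integrator handles strictly interior ones
    if (!is.null(ev_k) && nrow(ev_k)) {
      at_start <- ev_k$time == t0
      for (r in which(at_start)) y[[ev_k$var[r]]] <- y[[ev_k$var[r]]] + ev_k$value[r]
      ev_k <- ev_k[!at_start, , drop = FALSE]
    }
    tt <- sort(unique(c(t0, t_grid[t_grid > t0 & t_grid < t1],
                        if (!is.null(ev_k)) ev_k$time, t1)))
    args <- list(y = y, times = tt, func = deriv_fn, parms = sc,
                 rtol = params$solver$rtol, atol = params$solver$atol)
    if (!is.null(params$solver$hmax)) args$hmax <- params$solver$hmax
    if (!is.null(ev_k) && nrow(ev_k)) args$events <- list(data = ev_k)
    sol <- do.call(deSolve::lsoda, args)
    y <- stats::setNames(as.numeric(sol[nrow(sol), -1]), names(y))
    keep <- sol[, 1] %in% t_grid & (k == length(brk) - 1L | sol[, 1] < t1)
    out_rows[[k]] <- sol[keep, , drop = FALSE]
  }
  out <- as.data.frame(do.call(rbind, out_rows))
  names(out)[1] <- "time"
  if (min(as.matrix(out[-1])) < -1e-6)
    warning("integrator produced negative amounts; clipped in derivatives")
  vli <- if (params$topology == "one_compartment") params$volume
         else params$volumes[["liver"]]
  pcol <- if (params$topology == "one_compartment") "p_central" else "p_liver"
  mcol <- if (params$topology == "one_compartment") "m_central" else "m_liver"
  out$c_liver_parent <- out[[pcol]] / vli
  out$c_liver_met <- out[[mcol]] / vli
  in_body <- rowSums(out[, grep("^(depot|p_|m_)", names(out)), drop = FALSE])
  recovered <- in_body + out$cum_elim_met + out$cum_elim_parent
  # output rows that coincide exactly with a bolus time are ambiguous
  # (pre- or post-event state); accept whichever convention reconciles
  dose_le <- vapply(out$time, administered_dose, numeric(1), params = params)
  dose_lt <- vapply(out$time - 1e-9, administered_dose, numeric(1),
                    params = params)
  err <- pmin(abs(recovered - dose_le), abs(recovered - dose_lt))
  out$mass_balance_error <- ifelse(dose_le > 0, err / dose_le, 0)
  attr(out, "params") <- params
  class(out) <- c("pbpk_trajectory", "data.frame")
  out
}
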