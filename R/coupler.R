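# Quasi-steady-state multiscale loop. Intracellular metabolism is much
# faster than drug distribution and gene regulation, so within each
# coupling step the metabolic network is assumed to be at steady state:
#   step 1  feedforward: tissue concentrations tighten GSMN flux bounds;
#   step 2  FBA re-optimises the objective (maximal GSH production);
#   step 3  feedback: the objective value is mapped to a PBPK scaling
#           factor (SF) through a scaling table;
#   step 4  the PBPK and GRN ODEs advance by one time step Dt.
# Bounds are always rescaled from the stored wild-type bounds, never from
# the previous step's (non-compounding). Under feedback-only coupling the
# bounds never change, so the LP is evaluated once and its value reused.

#' Relative activity of a competitively inhibited reaction
#'
#' For a Michaelis-Menten reaction at substrate concentration equal to Km,
#' competitive inhibition at inhibitor concentration `i` reduces the rate to
#' `1 / (1 + i / (2 ki))` of the uninhibited rate. Maps any non-negative
#' concentration into `(0, 1]`.
#'
#' @param i Inhibitor concentration (same units as `ki`, typically mM).
#' @param ki Inhibition constant (> 0).
#' @return Activity in `(0, 1]`.
#' @export
competitive_inhibition_activity <- function(i, ki) {
  stopifnot(all(i >= 0), ki > 0)
  1 / (1 + i / (2 * ki))
}

#' Feedforward link: PBPK concentration -> GSMN flux bound
#'
#' @param reaction Target reaction id in the network.
#' @param source PBPK species/compartment supplying the inhibitor
#'   concentration: `"metabolite_liver"` or `"parent_liver"`.
#' @param ki Inhibition constant in mM (competitive inhibition at S = Km),
#'   or `NULL` when a custom `transform` is given.
#' @param transform Optional function mapping concentration (mM) to an
#'   activity in `(0, 1]`; overrides `ki`.
#' @return A `feedforward_link` object.
#' @export
feedforward_link <- function(reaction, source = "metabolite_liver",
                             ki = 50, transform = NULL) {
  stopifnot(source %in% c("metabolite_liver", "parent_liver"))
  if (is.null(transform)) {
    stopifnot(is.numeric(ki), ki > 0)
    force(ki)
    transform <- function(conc) competitive_inhibition_activity(conc, ki)
  }
  structure(list(reaction = reaction, source = source, ki = ki,
                 transform = transform),
            class = "feedforward_link")
}

#' Scaling table: FBA objective value -> PBPK scaling factor
#'
#' Proportional mode returns `SF = z / z_ref` (scaling factor proportional
#' to maximal GSH availability); lookup mode interpolates a breakpoint
#' table, either stepwise or piecewise-linearly. SF is clamped at 0.
#'
#' @param mode `"proportional"` or `"lookup"`.
#' @param z_ref Reference (wild-type) objective value for proportional mode.
#' @param breakpoints Data frame `z`, `sf` (sorted by `z`) for lookup mode.
#' @param interpolation `"linear"` or `"step"` (left-continuous step).
#' @return A `scaling_table` object.
#' @export
scaling_table <- function(mode = c("proportional", "lookup"), z_ref = NULL,
                          breakpoints = NULL,
                          interpolation = c("linear", "step")) {
  mode <- match.arg(mode)
  interpolation <- match.arg(interpolation)
  if (mode == "proportional") {
    stopifnot(is.numeric(z_ref), z_ref > 0)
  } else {
    stopifnot(is.data.frame(breakpoints),
              all(c("z", "sf") %in% names(breakpoints)),
              !is.unsorted(breakpoints$z), all(breakpoints$sf >= 0))
  }
  structure(list(mode = mode, z_ref = z_ref, breakpoints = breakpoints,
                 interpolation = interpolation),
            class = "scaling_table")
}

#' Evaluate a scaling table
#' @param table A [scaling_table()].
#' @param z Objective value(s).
#' @return Scaling factor(s), `>= 0`, monotone non-decreasing in `z`.
#' @export
scaling_factor <- function(table, z) {
  stopifnot(inherits(table, "scaling_table"))
  if (table$mode == "proportional") return(pmax(z / table$z_ref, 0))
  bp <- table$breakpoints
  if (table$interpolation == "step")
    return(bp$sf[pmax(findInterval(z, bp$z), 1L)])
  pmax(stats::approx(bp$z, bp$sf, xout = z, rule = 2)$y, 0)
}

#' Feedback link: FBA objective -> PBPK parameter
#'
#' @param table A [scaling_table()].
#' @param target PBPK scale to drive; currently `"gsh_scale"`.
#' @return A `feedback_link` object.
#' @export
feedback_link <- function(table, target = "gsh_scale") {
  stopifnot(inherits(table, "scaling_table"),
            target %in% "gsh_scale")
  structure(list(table = table, target = target), class = "feedback_link")
}

#' Coupling configuration
#'
#' @param dt Coupling time step (h); default 5 minutes, short relative to
#'   the pharmacokinetic timescale.
#' @param mode `"full"`, `"feedforward_only"` (objective value logged but
#'   not fed back) or `"feedback_only"` (bounds never modified).
#' @param uniqueness_check Run [uniqueness_guard()] on the coupled
#'   reactions each step.
#' @param uniqueness_tolerance Flux-range width flagged as non-unique.
#' @param strict Escalate a fired uniqueness guard from warning to error.
#' @return A `coupling_config` object.
#' @export
coupling_config <- function(dt = 5 / 60,
                            mode = c("full", "feedforward_only",
                                     "feedback_only"),
                            uniqueness_check = FALSE,
                            uniqueness_tolerance = 1e-6, strict = FALSE) {
  mode <- match.arg(mode)
  stopifnot(dt > 0)
  structure(list(dt = dt, mode = mode, uniqueness_check = uniqueness_check,
                 uniqueness_tolerance = uniqueness_tolerance,
                 strict = strict),
            class = "coupling_config")
}

# inhibitor concentration (mM) seen by a feedforward link
link_concentration <- function(link, pbpk_state, pbpk_params) {
  onec <- pbpk_params$topology == "one_compartment"
  vli <- if (onec) pbpk_params$volume else pbpk_params$volumes[["liver"]]
  amt <- switch(link$source,
    metabolite_liver = pbpk_state[[if (onec) "m_central" else "m_liver"]],
    parent_liver = pbpk_state[[if (onec) "p_central" else "p_liver"]])
  (amt / vli) / pbpk_params$mw  # (mg/L) / (g/mol) = mmol/L = mM
}

#' Apply feedforward links to a network
#'
#' Each link's activity multiplies the *wild-type* bounds of its target
#' reaction (upper bound scaled; a negative lower bound scaled
#' symmetrically), so repeated application never compounds.
#'
#' @param network Network whose bounds to modify.
#' @param links List of [feedforward_link()] objects.
#' @param pbpk_state Current PBPK state vector.
#' @param pbpk_params The `pbpk_parameters` in force.
#' @param wildtype_network Network providing the reference bounds (default:
#'   `network` itself).
#' @return `list(network, activities)` with named activity vector.
#' @export
apply_feedforward <- function(network, links, pbpk_state, pbpk_params,
                              wildtype_network = network) {
  acts <- stats::setNames(numeric(0), character(0))
  for (link in links) {
    stopifnot(inherits(link, "feedforward_link"))
    idx <- match(link$reaction, wildtype_network$reactions$id)
    if (is.na(idx))
      stop("feedforward link targets unknown reaction '", link$reaction, "'")
    conc <- link_concentration(link, pbpk_state, pbpk_params)
    act <- link$transform(conc)
    if (!is.finite(act) || act < 0 || act > 1)
      stop("feedforward transform returned invalid activity ", act)
    lb <- wildtype_network$reactions$lower_bound[idx]
    ub <- wildtype_network$reactions$upper_bound[idx]
    network <- set_bounds(network, link$reaction,
                          if (lb < 0) lb * act else lb, ub * act)
    acts[link$reaction] <- act
  }
  list(network = network, activities = acts)
}

#' Alternative-optima guard for coupled fluxes
#'
#' Runs flux variability at the optimum for the coupled reactions and flags
#' any whose range width exceeds the tolerance. When a model is
#' insufficiently constrained, the LP solver is free to flip between
#' alternative flux distributions with the same objective value; feeding
#' such fluxes into an ODE layer would make its trajectory discontinuous.
#' (Objective-*value* feedback is immune: the LP optimum is unique.)
#'
#' @param network A `metabolic_network`.
#' @param objective An [fba_objective()].
#' @param reactions Coupled reaction ids to check.
#' @param tolerance Width above which a flux is flagged.
#' @param strict Raise an error instead of a warning when flagged.
#' @return Data frame `reaction_id`, `min`, `max`, `width`, `degenerate`
#'   (invisible attribute `ok`).
#' @export
uniqueness_guard <- function(network, objective, reactions,
                             tolerance = 1e-6, strict = FALSE) {
  fv <- flux_variability(network, objective, optimality_fraction = 1,
                         reactions = reactions)
  fv$width <- fv$max - fv$min
  fv$degenerate <- fv$width > tolerance
  if (any(fv$degenerate, na.rm = TRUE)) {
    msg <- paste0("alternative optima on coupled flux(es): ",
                  paste(fv$reaction_id[fv$degenerate], collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  attr(fv, "ok") <- !any(fv$degenerate, na.rm = TRUE)
  fv
}

#' Assemble a multiscale model
#'
#' @param network A `metabolic_network` (typically the liver GSMN).
#' @param objective The FBA objective (e.g. GSH production).
#' @param pbpk A `pbpk_parameters` object.
#' @param grn Optional `grn_parameters`; when given, liver CYP3A4 is
#'   governed by the GRN and scales phase-I metabolism.
#' @param feedforward List of [feedforward_link()] objects.
#' @param feedback A [feedback_link()] or `NULL`; the default maps the
#'   objective proportionally against the wild-type optimum.
#' @param config A [coupling_config()].
#' @param cortisol Cortisol schedule function or kind string.
#' @return A `multiscale_model` object.
#' @export
multiscale_model <- function(network, objective, pbpk, grn = NULL,
                             feedforward = list(), feedback = NULL,
                             config = coupling_config(),
                             cortisol = "homeostatic") {
  stopifnot(inherits(network, "metabolic_network"),
            inherits(objective, "fba_objective"),
            inherits(pbpk, "pbpk_parameters"),
            inherits(config, "coupling_config"))
  wt <- fba(network, objective)
  if (wt$status != "optimal")
    stop("wild-type FBA must be optimal to build a multiscale model (status ",
         wt$status, ")")
  if (is.null(feedback)) {
    zr <- if (wt$z > 0) wt$z else 1
    feedback <- feedback_link(scaling_table("proportional", z_ref = zr))
  }
  if (!is.null(grn) && is.character(cortisol))
    cortisol <- cortisol_schedule(cortisol, grn)
  structure(list(network = network, objective = objective, pbpk = pbpk,
                 grn = grn, feedforward = feedforward, feedback = feedback,
                 config = config, cortisol = cortisol,
                 z_wildtype = wt$z),
            class = "multiscale_model")
}

multiscale_init_bundle <- function(model) {
  list(time = 0,
       pbpk_state = pbpk_init_state(model$pbpk),
       grn_state = if (!is.null(model$grn)) grn_init_state(model$grn),
       gsh_scale = 1,
       z_cache = NULL,
       step = 0L)
}

# advance PBPK (+GRN, same integrator call) by dt with fixed gsh scale
advance_ode <- function(model, bundle, dt) {
  p <- model$pbpk
  np <- length(bundle$pbpk_state)
  has_grn <- !is.null(model$grn)
  y0 <- c(bundle$pbpk_state, if (has_grn) bundle$grn_state)
  deriv <- function(t, y, parms) {
    yp <- y[seq_len(np)]
    cyp <- if (has_grn)
      cyp3a4_scale(max(y[[np + 3L]], 0), model$grn$cyp3a4_ref) else 1
    dp <- pbpk_derivatives(yp, t, p, cyp3a4_scale = cyp,
                           gsh_scale = bundle$gsh_scale)[[1]]
    dg <- if (has_grn)
      grn_derivatives(y[(np + 1L):(np + 3L)], t, model$grn,
                      model$cortisol(t))[[1]]
    list(c(dp, dg))
  }
  t0 <- bundle$time; t1 <- t0 + dt
  ev <- bolus_events(p, t1)
  if (!is.null(ev)) ev <- ev[ev$time >= t0 & ev$time < t1, , drop = FALSE]
  if (!is.null(ev) && nrow(ev)) {
    at_start <- ev$time == t0
    for (r in which(at_start)) y0[[ev$var[r]]] <- y0[[ev$var[r]]] + ev$value[r]
    ev <- ev[!at_start, , drop = FALSE]
  }
  tt <- sort(unique(c(t0, if (!is.null(ev)) ev$time, t1)))
  args <- list(y = y0, times = tt, func = deriv, parms = NULL,
               rtol = p$solver$rtol, atol = p$solver$atol)
  if (!is.null(ev) && nrow(ev)) args$events <- list(data = ev)
  sol <- do.call(deSolve::lsoda, args)
  yend <- stats::setNames(as.numeric(sol[nrow(sol), -1]), names(y0))
  bundle$pbpk_state <- yend[seq_len(np)]
  if (has_grn) bundle$grn_state <- yend[(np + 1L):(np + 3L)]
  bundle$time <- t1
  bundle
}

#' One quasi-steady-state coupling step
#'
#' Executes the four-step loop (bounds from concentrations; FBA; scaling
#' factor from objective; ODE advance) restricted to the steps enabled by
#' the coupling mode, and returns the updated state bundle plus a one-row
#' record of diagnostics.
#'
#' @param model A [multiscale_model()].
#' @param bundle State bundle as produced by previous steps (internal
#'   structure: time, PBPK state, GRN state, current gsh scale, LP cache).
#' @return `list(bundle, record)`.
#' @export
qss_step <- function(model, bundle) {
  cfg <- model$config
  net <- model$network
  acts <- stats::setNames(rep(1, length(model$feedforward)),
                          vapply(model$feedforward,
                                 function(l) l$reaction, character(1)))
  # step 1: feedforward bounds (skipped in feedback-only mode)
  ff_active <- cfg$mode != "feedback_only" && length(model$feedforward) > 0
  if (ff_active) {
    ff <- apply_feedforward(net, model$feedforward, bundle$pbpk_state,
                            model$pbpk, wildtype_network = model$network)
    net <- ff$network
    acts[names(ff$activities)] <- ff$activities
  }
  # step 2: FBA (cached when the bounds cannot have changed)
  if (!ff_active && !is.null(bundle$z_cache)) {
    z <- bundle$z_cache
  } else {
    sol <- fba(net, model$objective)
    if (sol$status != "optimal")
      stop("FBA ", sol$status, " at coupling step ", bundle$step + 1L,
           " (t = ", bundle$time, " h); bounds snapshot: ",
           paste(sprintf("%s[%g,%g]", net$reactions$id,
                         net$reactions$lower_bound,
                         net$reactions$upper_bound), collapse = " "))
    z <- sol$z
    if (!ff_active) bundle$z_cache <- z
  }
  guard_ok <- NA
  if (isTRUE(cfg$uniqueness_check) && length(model$feedforward)) {
    gd <- uniqueness_guard(net, model$objective, names(acts),
                           tolerance = cfg$uniqueness_tolerance,
                           strict = cfg$strict)
    guard_ok <- attr(gd, "ok")
  }
  # step 3: feedback of the objective value (skipped in feedforward-only)
  if (cfg$mode != "feedforward_only" && !is.null(model$feedback))
    bundle$gsh_scale <- scaling_factor(model$feedback$table, z)
  # step 4: ODE advance
  bundle <- advance_ode(model, bundle, cfg$dt)
  bundle$step <- bundle$step + 1L
  rec <- data.frame(time = bundle$time, z = z, sf = bundle$gsh_scale,
                    guard_ok = guard_ok)
  for (rid in names(acts)) rec[[paste0("activity_", rid)]] <- acts[[rid]]
  list(bundle = bundle, record = rec)
}

#' Run a multiscale simulation
#'
#' Iterates [qss_step()] from a drug-free initial state over the requested
#' duration. Deterministic for fixed inputs.
#'
#' @param model A [multiscale_model()].
#' @param duration Simulated time (h).
#' @return A `multiscale_trajectory`: data frame with one row per coupling
#'   step holding the PBPK liver concentrations, venous concentrations, GRN
#'   state (if present), objective value `z`, scaling factor `sf` and
#'   per-link activities; full PBPK state matrix in attribute
#'   `"pbpk_states"`.
#' @export
simulate_multiscale <- function(model, duration) {
  stopifnot(duration > 0)
  n_steps <- ceiling(duration / model$config$dt)
  bundle <- multiscale_init_bundle(model)
  recs <- vector("list", n_steps)
  states <- matrix(NA_real_, n_steps, length(bundle$pbpk_state),
                   dimnames = list(NULL, names(bundle$pbpk_state)))
  onec <- model$pbpk$topology == "one_compartment"
  vli <- if (onec) model$pbpk$volume else model$pbpk$volumes[["liver"]]
  for (k in seq_len(n_steps)) {
    out <- qss_step(model, bundle)
    bundle <- out$bundle
    rec <- out$record
    st <- bundle$pbpk_state
    rec$c_liver_parent <- st[[if (onec) "p_central" else "p_liver"]] / vli
    rec$c_liver_met <- st[[if (onec) "m_central" else "m_liver"]] / vli
    if (!onec) {
      rec$c_venous_parent <- st[["p_venous"]] / model$pbpk$volumes[["venous"]]
      rec$c_venous_met <- st[["m_venous"]] / model$pbpk$volumes[["venous"]]
    }
    if (!is.null(model$grn)) {
      rec$cyp3a4 <- bundle$grn_state[["cyp3a4"]]
      rec$cortisol <- model$cortisol(bundle$time)
      rec$cyp3a4_scale <- cyp3a4_scale(rec$cyp3a4, model$grn$cyp3a4_ref)
    }
    recs[[k]] <- rec
    states[k, ] <- st
  }
  out <- do.call(rbind, recs)
  attr(out, "pbpk_states") <- states
  attr(out, "model_z_wildtype") <- model$z_wildtype
  class(out) <- c("multiscale_trajectory", "data.frame")
  out
}
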