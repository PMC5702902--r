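# YAML run configuration for the multiscale simulator. Validation is
# strict: unknown keys are rejected and all problems are reported at once.

.config_schema <- list(
  seed = NULL,
  model = c("path", "format", "externals", "objective", "bounds",
            "bounds_reduction", "restrict_to_listed", "knockout_reactions",
            "knockout_genes", "fixture"),
  pbpk = c("fup", "fup_met", "bp", "bp_met", "cl_phase1", "clmet",
           "cl_renal", "mw", "kp", "kp_met", "volumes", "flows", "dosing",
           "solver"),
  grn = c("enabled", "kd_mr", "kd_gr", "kd_pxr", "gr_ref", "pxr_ref",
          "cyp3a4_ref", "k_deg_gr", "k_deg_pxr", "k_deg_cyp", "fb_k",
          "ff_gain", "ff_k", "w_gr", "w_pxr", "k_cyp", "cortisol_baseline",
          "stress_multiplier", "stress"),
  coupling = c("dt", "mode", "duration", "uniqueness_check",
               "uniqueness_tolerance", "strict", "feedforward", "feedback"),
  output = c("dir")
)

#' Read and validate a run configuration
#'
#' @param path YAML file with sections `model`, `pbpk`, `grn`, `coupling`,
#'   `output` and a top-level `seed`. Unknown keys anywhere are rejected;
#'   validation reports every problem in one error.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  problems <- character(0)
  unknown_top <- setdiff(names(cfg), names(.config_schema))
  if (length(unknown_top))
    problems <- c(problems, paste0("unknown top-level key(s): ",
                                   paste(unknown_top, collapse = ", ")))
  for (sec in intersect(names(cfg), names(.config_schema))) {
    allowed <- .config_schema[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[sec]]), allowed)
    if (length(bad))
      problems <- c(problems, paste0("unknown key(s) in [", sec, "]: ",
                                     paste(bad, collapse = ", ")))
  }
  if (is.null(cfg$model) ||
      (is.null(cfg$model$path) && is.null(cfg$model$fixture)))
    problems <- c(problems, "[model] needs 'path' or 'fixture'")
  if (!is.null(cfg$coupling$mode) &&
      !cfg$coupling$mode %in% c("full", "feedforward_only", "feedback_only"))
    problems <- c(problems, paste0("invalid coupling mode '",
                                   cfg$coupling$mode, "'"))
  if (!is.null(cfg$grn$stress) &&
      !cfg$grn$stress %in% c("homeostatic", "chronic_stress"))
    problems <- c(problems, paste0("invalid stress schedule '",
                                   cfg$grn$stress, "'"))
  if (!is.null(cfg$model$path) && !file.exists(cfg$model$path))
    problems <- c(problems, paste0("model file not found: ", cfg$model$path))
  if (length(problems))
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  class(cfg) <- "run_config"
  cfg
}

config_load_network <- function(mcfg) {
  if (!is.null(mcfg$fixture)) {
    fx <- switch(mcfg$fixture,
                 fig1_like = make_fig1_like(),
                 mini_liver = make_mini_liver(),
                 linear_chain = make_linear_chain(),
                 parallel_paths = make_parallel_paths(),
                 stop("unknown fixture '", mcfg$fixture, "'"))
    net <- fx$network; obj <- fx$objective
  } else {
    fmt <- mcfg$format
    if (is.null(fmt))
      fmt <- if (grepl("\\.(xml|sbml)$", mcfg$path)) "sbml" else "tabular"
    net <- if (fmt == "sbml") read_sbml_fbc(mcfg$path)
           else read_tabular(mcfg$path,
                             externals = as.character(mcfg$externals))
    obj <- attr(net, "objective")
  }
  if (!is.null(mcfg$objective)) {
    oc <- unlist(mcfg$objective)
    if (is.null(names(oc)) || any(!nzchar(names(oc))))
      oc <- stats::setNames(rep(1, length(oc)), as.character(oc))
    obj <- fba_objective(oc)
  }
  if (is.null(obj))
    stop("no objective: supply [model] objective or use a model that declares one")
  if (!is.null(mcfg$bounds)) {
    red <- if (is.null(mcfg$bounds_reduction)) "none" else mcfg$bounds_reduction
    bt <- read_bounds_csv(mcfg$bounds, reduction = red)
    net <- apply_exchange_bounds(net, bt,
                                 restrict_to_listed =
                                   isTRUE(mcfg$restrict_to_listed))
  }
  if (length(mcfg$knockout_reactions))
    net <- knockout_reactions(net, as.character(mcfg$knockout_reactions))
  if (length(mcfg$knockout_genes))
    net <- gene_knockout(net, as.character(mcfg$knockout_genes))
  list(network = net, objective = obj)
}

#' Build a multiscale model from a run configuration
#'
#' @param cfg A validated [read_run_config()] result.
#' @param mode,stress Optional overrides of `[coupling] mode` and
#'   `[grn] stress`.
#' @return A [multiscale_model()].
#' @export
config_to_model <- function(cfg, mode = NULL, stress = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  mdl <- config_load_network(cfg$model)
  pb <- do.call(pbpk_parameters, cfg$pbpk %||% list())
  grn <- NULL
  if (!isFALSE(cfg$grn$enabled) && !is.null(cfg$grn)) {
    gargs <- cfg$grn
    gargs$enabled <- NULL; gargs$stress <- NULL
    grn <- do.call(grn_parameters, gargs)
  }
  ccfg <- cfg$coupling %||% list()
  config <- coupling_config(
    dt = ccfg$dt %||% (5 / 60),
    mode = mode %||% ccfg$mode %||% "full",
    uniqueness_check = isTRUE(ccfg$uniqueness_check),
    uniqueness_tolerance = ccfg$uniqueness_tolerance %||% 1e-6,
    strict = isTRUE(ccfg$strict))
  links <- lapply(ccfg$feedforward %||% list(), function(l)
    feedforward_link(reaction = l$reaction,
                     source = l$source %||% "metabolite_liver",
                     ki = l$ki %||% 50))
  fb <- NULL
  if (!is.null(ccfg$feedback)) {
    fcfg <- ccfg$feedback
    tab <- if ((fcfg$mode %||% "proportional") == "lookup")
      scaling_table("lookup",
                    breakpoints = data.frame(z = unlist(fcfg$breakpoints$z),
                                             sf = unlist(fcfg$breakpoints$sf)),
                    interpolation = fcfg$interpolation %||% "linear")
    else if (!is.null(fcfg$z_ref))
      scaling_table("proportional", z_ref = fcfg$z_ref)
    else NULL
    if (!is.null(tab)) fb <- feedback_link(tab)
  }
  schedule <- stress %||% cfg$grn$stress %||% "homeostatic"
  multiscale_model(mdl$network, mdl$objective, pb, grn = grn,
                   feedforward = links, feedback = fb, config = config,
                   cortisol = schedule)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
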