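# Build compartmental models: the single-compartment cylinder and the
# gradient-endowed multi-compartment model (d-lambda discretization of a
# morphology with the somato-apical parameter gradients).

#' Calcium-pool settings
#'
#' Single sub-membrane shell: T-type calcium influx is scaled into the shell
#' and relaxes back to the resting level with a single decay time constant.
#'
#' @param depth_um shell depth (um).
#' @param tau_ms decay time constant (ms).
#' @param rest_mM resting calcium (mM); 1e-4 mM = 100 nM.
#' @param cao_mM extracellular calcium (mM).
#' @export
ca_settings <- function(depth_um = 0.1, tau_ms = 30, rest_mM = 1e-4,
                        cao_mM = 2) {
  stopifnot(depth_um > 0, tau_ms > 0, rest_mM > 0, cao_mM > 0)
  list(depth_um = depth_um, tau_ms = tau_ms, rest_mM = rest_mM,
       cao_mM = cao_mM)
}

#' AC length constant at 100 Hz
#'
#' `lambda_f = (1/2) sqrt(diam / (pi f Ra Cm))` at `f` = 100 Hz, the space
#' constant that the d-lambda discretization rule is based on.
#'
#' @param diam_um compartment diameter (um).
#' @param ra axial resistivity (Ohm cm).
#' @param cm specific membrane capacitance (uF/cm^2).
#' @return length constant (um).
#' @export
lambda_100 <- function(diam_um, ra, cm) {
  if (any(diam_um <= 0) || any(ra <= 0) || any(cm <= 0)) {
    stop("lambda_100 needs strictly positive arguments", call. = FALSE)
  }
  d_cm <- diam_um * 1e-4
  cm_f <- cm * 1e-6
  1e4 * 0.5 * sqrt(d_cm / (pi * 100 * ra * cm_f))
}

#' Number of compartments for a section under the d-lambda rule
#'
#' The standard odd-compartment convention:
#' `n = 2 * floor((L / (d_lambda * lambda_100) + 0.9) / 2) + 1`.
#'
#' @param length_um section length (um).
#' @param lam lambda_100 of the section (um).
#' @param d_lambda rule fraction (default 0.1).
#' @return odd integer number of compartments.
#' @export
dlambda_nseg <- function(length_um, lam, d_lambda = 0.1) {
  as.integer(2 * floor((length_um / (d_lambda * lam) + 0.9) / 2) + 1)
}

#' Configuration for the gradient-endowed multi-compartment model
#'
#' Defaults are the somato-apical gradients of the reference CA1 model:
#' sigmoidally decreasing Rm (125 -> 85 kOhm cm^2, d = 300 um, k = 50 um) and
#' Ra (120 -> 70 Ohm cm, d = 300 um, k = 14 um), linearly increasing A-type
#' K+ (3.1 mS/cm^2 somatic, 8-fold per 100 um, proximal/distal model switch
#' at 100 um), sigmoidally increasing h (25 uS/cm^2, 12-fold, d = 320 um,
#' k = 50 um) with the piecewise-linear activation-V1/2 map (-82 -> -90 mV),
#' and sigmoidally increasing T-type Ca2+ (80 uS/cm^2, 30-fold, d = 350 um,
#' k = 50 um). Na+ and delayed-rectifier K+ densities are uniform. Basal
#' dendrites take somatic passive values and somatic densities (including
#' A-type K+); axonal compartments take somatic passive values with Na/KDR
#' only.
#'
#' @param cm specific membrane capacitance (uF/cm^2).
#' @param e_pas leak reversal (mV).
#' @param rm,ra [passive_gradient()]s (kOhm cm^2; Ohm cm).
#' @param gka [linear_gradient()] (S/cm^2).
#' @param gh,gcat [sigmoid_gradient()]s (S/cm^2).
#' @param gna,gkdr uniform densities (S/cm^2).
#' @param ka_switch_um proximal/distal A-type model boundary (um).
#' @param h_vhalf_prox,h_vhalf_dist,h_x0,h_x1 h-channel V1/2 map parameters.
#' @param d_lambda discretization fraction of lambda_100.
#' @param ca [ca_settings()].
#' @param registry channel registry (see [default_channels()]).
#' @export
trunk_config <- function(cm = 1, e_pas = -65,
                         rm = passive_gradient(125, 85, 300, 50),
                         ra = passive_gradient(120, 70, 300, 14),
                         gka = linear_gradient(3.1e-3, 8),
                         gh = sigmoid_gradient(25e-6, 12, 320, 50),
                         gcat = sigmoid_gradient(80e-6, 30, 350, 50),
                         gna = 16e-3, gkdr = 10e-3,
                         ka_switch_um = 100,
                         h_vhalf_prox = -82, h_vhalf_dist = -90,
                         h_x0 = 100, h_x1 = 300,
                         d_lambda = 0.1,
                         ca = ca_settings(),
                         registry = default_channels()) {
  list(cm = cm, e_pas = e_pas, rm = rm, ra = ra, gka = gka, gh = gh,
       gcat = gcat, gna = gna, gkdr = gkdr, ka_switch_um = ka_switch_um,
       h_vhalf_prox = h_vhalf_prox, h_vhalf_dist = h_vhalf_dist,
       h_x0 = h_x0, h_x1 = h_x1, d_lambda = d_lambda, ca = ca,
       registry = registry)
}

channel_names <- c("Na", "KDR", "KA_prox", "KA_dist", "h", "CaT")

#' Discretize a morphology into a compartmental model
#'
#' Splits every section into an odd number of equal compartments so that each
#' compartment is shorter than `d_lambda * lambda_100` (lambda computed with
#' the section's smallest diameter and its largest axial resistivity, so the
#' rule holds for every compartment individually), then evaluates all passive
#' and channel gradients at each compartment's midpoint path distance from
#' the soma.
#'
#' @param morph a `neuron_morphology`.
#' @param config a [trunk_config()].
#' @return an object of class `cable_model`.
#' @export
discretize <- function(morph, config = trunk_config()) {
  validate_morphology(morph)
  s <- morph$sections
  x0 <- section_path_start(morph)
  comp_rows <- list()
  first_comp <- integer(nrow(s))
  last_comp <- integer(nrow(s))
  n_done <- 0L
  for (i in seq_len(nrow(s))) {
    on_apical <- s$type[i] == "apical"
    xs <- if (on_apical) x0[i] else 0
    xe <- if (on_apical) x0[i] + s$length_um[i] else 0
    ra_max <- max(passive_at(config$ra, xs), passive_at(config$ra, xe))
    lam <- lambda_100(min(s$diam0[i], s$diam1[i]), ra_max, config$cm)
    n <- dlambda_nseg(s$length_um[i], lam, config$d_lambda)
    # the rounding convention can leave a single compartment up to 10% over
    # the bound; enforce the bound strictly, keeping the count odd
    while (s$length_um[i] / n >= config$d_lambda * lam) n <- n + 2L
    len <- s$length_um[i] / n
    mid_frac <- (seq_len(n) - 0.5) / n
    diam <- s$diam0[i] + (s$diam1[i] - s$diam0[i]) * mid_frac
    x_mid <- if (on_apical) x0[i] + mid_frac * s$length_um[i] else
      rep(0, n)
    parent <- c(if (s$parent[i] == 0) 0L else
                  last_comp[match(s$parent[i], s$section)],
                n_done + seq_len(n - 1))
    comp_rows[[i]] <- data.frame(
      comp = n_done + seq_len(n), parent = parent, section = s$section[i],
      type = s$type[i], x_um = x_mid, length_um = len, diam_um = diam)
    first_comp[i] <- n_done + 1L
    last_comp[i] <- n_done + n
    n_done <- n_done + n
  }
  comp <- do.call(rbind, comp_rows)
  x <- comp$x_um
  grad_x <- ifelse(comp$type == "apical", x, 0)
  comp$area_cm2 <- pi * comp$diam_um * comp$length_um * 1e-8
  comp$cm_uF <- config$cm
  comp$rm_kohm <- passive_at(config$rm, grad_x)
  comp$ra_ohm <- passive_at(config$ra, grad_x)
  dens <- matrix(0, nrow(comp), length(channel_names),
                 dimnames = list(NULL, channel_names))
  apical <- comp$type == "apical"
  somatic <- comp$type %in% c("soma", "basal")
  axonal <- comp$type == "axon"
  dens[, "Na"] <- config$gna
  dens[, "KDR"] <- config$gkdr
  ka <- ka_density_at(config$gka, grad_x)
  ka_model <- ka_model_at(grad_x, config$ka_switch_um)
  dens[somatic, "KA_prox"] <- ka[somatic]
  dens[apical & ka_model == "KA_prox", "KA_prox"] <-
    ka[apical & ka_model == "KA_prox"]
  dens[apical & ka_model == "KA_dist", "KA_dist"] <-
    ka[apical & ka_model == "KA_dist"]
  dens[!axonal, "h"] <- sigmoid_density_at(config$gh, grad_x)[!axonal]
  dens[!axonal, "CaT"] <- sigmoid_density_at(config$gcat, grad_x)[!axonal]
  h_shift <- h_vhalf_at(grad_x, config$h_vhalf_prox, config$h_vhalf_dist,
                        config$h_x0, config$h_x1) - config$h_vhalf_prox
  h_shift[!apical] <- 0
  new_cable_model(comp, dens, config$registry,
                  gate_vshift = list(h = h_shift),
                  e_pas = config$e_pas, ca = config$ca,
                  id = morph$id, config = config)
}

new_cable_model <- function(comp, dens, registry, gate_vshift, e_pas, ca,
                            id, config = NULL) {
  stopifnot(nrow(dens) == nrow(comp))
  if (any(dens < 0)) stop("channel densities must be non-negative",
                          call. = FALSE)
  if (any(comp$rm_kohm <= 0) || any(comp$ra_ohm <= 0)) {
    stop("passive values must be positive", call. = FALSE)
  }
  structure(list(comp = comp, dens = dens, registry = registry,
                 gate_vshift = gate_vshift, e_pas = e_pas, ca = ca,
                 id = id, config = config),
            class = "cable_model")
}

#' @export
print.cable_model <- function(x, ...) {
  cat("<cable_model>", x$id, "-", nrow(x$comp), "compartments\n")
  act <- colnames(x$dens)[colSums(x$dens) > 0]
  cat("  channels:", if (length(act)) paste(act, collapse = ", ") else
    "(passive)", "\n")
  invisible(x)
}

#' Number of compartments of a cable model
#' @param model a `cable_model`.
#' @export
n_compartments <- function(model) nrow(model$comp)

#' Build the single-compartment model
#'
#' One cylinder (defaults: length = diameter = 60 um, Rm = 11 kOhm cm^2,
#' Cm = 1 uF/cm^2, Ra = 100 Ohm cm) whose lateral surface (no end caps) gives
#' a passive input resistance Rm/(pi d L) of ~97 MOhm. Channel densities are
#' supplied as a named vector; sweep modifiers are applied by passing a
#' modified registry (see [modify_gate()]).
#'
#' @param channels named density vector (S/cm^2), e.g. `c(CaT = 80e-6)`.
#' @param length_um,diam_um cylinder dimensions (um).
#' @param rm specific membrane resistance (kOhm cm^2).
#' @param cm specific membrane capacitance (uF/cm^2).
#' @param ra axial resistivity (Ohm cm).
#' @param e_pas leak reversal (mV).
#' @param ca [ca_settings()].
#' @param registry channel registry.
#' @return a `cable_model` with one compartment.
#' @export
build_single_compartment <- function(channels = c(CaT = 80e-6),
                                     length_um = 60, diam_um = 60,
                                     rm = 11, cm = 1, ra = 100,
                                     e_pas = -65, ca = ca_settings(),
                                     registry = default_channels()) {
  stopifnot(length_um > 0, diam_um > 0, rm > 0, cm > 0, ra > 0)
  bad <- setdiff(names(channels), channel_names)
  if (length(bad)) stop("unknown channels: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  comp <- data.frame(comp = 1L, parent = 0L, section = 1L, type = "soma",
                     x_um = 0, length_um = length_um, diam_um = diam_um,
                     area_cm2 = pi * diam_um * length_um * 1e-8,
                     cm_uF = cm, rm_kohm = rm, ra_ohm = ra)
  dens <- matrix(0, 1, length(channel_names),
                 dimnames = list(NULL, channel_names))
  dens[1, names(channels)] <- channels
  new_cable_model(comp, dens, registry, gate_vshift = list(),
                  e_pas = e_pas, ca = ca, id = "single-compartment")
}

#' Build the gradient-endowed somato-apical trunk model
#'
#' Convenience wrapper: generate (or accept) a morphology and discretize it
#' with the default gradients.
#'
#' @param morph a `neuron_morphology`; default the synthetic ~425 um trunk.
#' @param config a [trunk_config()].
#' @return a `cable_model`.
#' @export
build_trunk_model <- function(morph = make_trunk(), config = trunk_config()) {
  discretize(morph, config)
}

#' Passive input resistance of a model, closed form
#'
#' For a single compartment: `Rm / area`. Used as the analytic cross-check of
#' the simulated DC input resistance.
#'
#' @param model a `cable_model` with one compartment.
#' @return input resistance (MOhm).
#' @export
input_resistance_closed_form <- function(model) {
  stopifnot(nrow(model$comp) == 1)
  model$comp$rm_kohm[1] * 1000 / model$comp$area_cm2[1] / 1e6
}
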