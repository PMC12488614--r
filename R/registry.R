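# Channel registry: load named kinetic parameter sets from YAML and apply
# sweep modifiers.

registry_env <- new.env(parent = emptyenv())

#' Load a channel registry
#'
#' Reads a structured-text (YAML) registry, one document section per channel,
#' into a named list of [channel_spec()] objects. The packaged registry
#' (`inst/extdata/channels.yaml`) holds the default CA1 kinetic schemes;
#' substituting an alternative published scheme is a registry edit, not a code
#' change.
#'
#' @param path registry file; default the packaged registry.
#' @return named list of `channel_spec` objects (densities zero; densities are
#'   assigned by the model builders).
#' @export
load_channel_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "channels.yaml", package = "calres",
                        mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    ch <- raw[[nm]]
    gates <- lapply(ch$gates, function(g) {
      gate_spec(name = g$name, ss = g$ss, tau = g$tau,
                exponent = g$exponent %||% 1L,
                q10 = g$q10 %||% 1, tref = g$tref %||% 34)
    })
    channel_spec(name = nm, current = ch$current, gates = gates,
                 erev = ch$erev %||% NA_real_,
                 valence = ch$valence %||% 2)
  })
  names(out) <- names(raw)
  out
}

#' Default channel registry (cached)
#' @return named list of `channel_spec` objects.
#' @export
default_channels <- function() {
  if (is.null(registry_env$channels)) {
    registry_env$channels <- load_channel_registry()
  }
  registry_env$channels
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply sweep modifiers to one gate of one channel
#'
#' The hooks the parameter sweeps use: translate a gate's voltage dependence
#' (`v_half_shift`, mV), scale its time constant (`tau_scale`,
#' multiplicative) or offset it (`tau_offset`, ms, the additive alternative).
#'
#' @param channels named list of [channel_spec()] objects.
#' @param channel channel name.
#' @param gate gate name within that channel.
#' @param v_half_shift,tau_scale,tau_offset modifier values; `NULL` leaves the
#'   current value unchanged.
#' @return the modified channel list.
#' @export
modify_gate <- function(channels, channel, gate, v_half_shift = NULL,
                        tau_scale = NULL, tau_offset = NULL) {
  if (is.null(channels[[channel]])) stop("no channel ", channel, call. = FALSE)
  gi <- which(vapply(channels[[channel]]$gates, `[[`, "", "name") == gate)
  if (length(gi) != 1) stop("no gate ", gate, " in ", channel, call. = FALSE)
  g <- channels[[channel]]$gates[[gi]]
  if (!is.null(v_half_shift)) g$v_half_shift <- v_half_shift
  if (!is.null(tau_scale)) {
    if (tau_scale <= 0) stop("tau_scale must be > 0", call. = FALSE)
    g$tau_scale <- tau_scale
  }
  if (!is.null(tau_offset)) g$tau_offset <- tau_offset
  channels[[channel]]$gates[[gi]] <- g
  channels
}
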