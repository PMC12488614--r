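# Deterministic parameter-sweep grids for the single-compartment experiments.

sweep_kinds <- c("gcat", "tau_act", "tau_inact", "v12_act_cat",
                 "v12_inact_cat", "gh", "v12_h", "tau_h", "gka",
                 "v12_act_ka", "v12_inact_ka", "ka_tau_act", "ka_tau_inact",
                 "ca_decay_tau", "rm", "cm")

#' Parameter-sweep grid
#'
#' Deterministic documented grids: multiplicative factors 0.25x-4x in 9
#' log-spaced steps for conductances and time constants, and -15 to +15 mV
#' in 2.5 mV steps for V1/2 shifts. Every grid contains the unmodified
#' default point (factor 1 / shift 0).
#'
#' @param kind one of `r paste(sweep_kinds, collapse = ", ")`.
#' @param n_factors number of steps for multiplicative grids.
#' @param shift_range,shift_step V1/2 shift grid parameters (mV).
#' @return data.frame with `kind`, `value` (factor or shift in mV) and
#'   `is_default`.
#' @export
sweep_grid <- function(kind, n_factors = 9, shift_range = 15,
                       shift_step = 2.5) {
  if (!kind %in% sweep_kinds) {
    stop("unknown sweep kind: ", kind, call. = FALSE)
  }
  if (grepl("^v12_", kind)) {
    value <- seq(-shift_range, shift_range, by = shift_step)
    is_default <- value == 0
  } else {
    value <- 4^seq(-1, 1, length.out = n_factors)
    value[(n_factors + 1) / 2] <- 1  # exact default member
    is_default <- value == 1
  }
  data.frame(kind = kind, value = value, is_default = is_default)
}
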