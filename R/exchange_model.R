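## Labeling chemistry parameters and per-residue exchange kinetics.

#' Exchange model parameters
#'
#' Constants of the labeling chemistry: the D2O fraction of the labeling
#' buffer caps achievable deuteration, the recovery factor models deuterium
#' retained through quench/digestion/LC back-exchange, and the mass shift is
#' mass(2H) - mass(1H).
#'
#' @param buffer_d_fraction Deuterium fraction of the labeling buffer, in
#'   (0, 1]. Default 0.80.
#' @param recovery Fraction of incorporated deuterium surviving
#'   back-exchange, in (0, 1]. Default 0.70.
#' @param intrinsic_rate_range Log-uniform bounds (per second) for sampled
#'   residue intrinsic exchange rates.
#' @param deuterium_mass_shift Da per incorporated deuterium.
#' @return An object of class `exchange_model`.
#' @export
exchange_model <- function(buffer_d_fraction = 0.80, recovery = 0.70,
                           intrinsic_rate_range = c(1e-4, 1e-1),
                           deuterium_mass_shift = 1.00628) {
  stopifnot(buffer_d_fraction > 0, buffer_d_fraction <= 1,
            recovery > 0, recovery <= 1,
            length(intrinsic_rate_range) == 2L, intrinsic_rate_range[1] > 0,
            intrinsic_rate_range[2] >= intrinsic_rate_range[1],
            deuterium_mass_shift > 0)
  structure(list(buffer_d_fraction = buffer_d_fraction, recovery = recovery,
                 intrinsic_rate_range = intrinsic_rate_range,
                 deuterium_mass_shift = deuterium_mass_shift),
            class = "exchange_model")
}

#' Per-residue deuteration probability under first-order kinetics
#'
#' A residue with intrinsic rate k and protection factor P exchanges with
#' observed rate k/P; the plateau is the buffer deuterium fraction:
#' d(t) = f * (1 - exp(-(k/P) t)).
#'
#' @param residue_rate Intrinsic exchange rate, per second (> 0).
#' @param protection Protection factor (>= 1; 1 = fully exposed).
#' @param time Labeling time in seconds (>= 0); vectorised.
#' @param model An [exchange_model()].
#' @return Deuteration probability in \[0, buffer_d_fraction\].
#' @export
simulate_residue_deuteration <- function(residue_rate, protection, time,
                                         model = exchange_model()) {
  if (any(time < 0)) stop("labeling time must be non-negative")
  stopifnot(all(residue_rate > 0), all(protection >= 1))
  model$buffer_d_fraction * (1 - exp(-(residue_rate / protection) * time))
}
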