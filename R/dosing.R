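#' Individualized stimulation current
#'
#' Exploits the linearity between applied current and induced E-field:
#' `I_individualized = I_applied / E_generated * E_target`. Currents above
#' the safety cap are clipped and flagged (typical tES currents are
#' 1-4 mA); the cap is never applied silently.
#'
#' @param e_generated peak E-field strength (V/m) generated by
#'   `i_applied`, from MRI-informed simulation or a model prediction.
#' @param e_target desired peak E-field strength (V/m).
#' @param i_applied reference current in mA (default 1).
#' @param max_current safety cap in mA (default 4; `Inf` disables).
#' @return data frame with `current` (mA) and logical `clipped`.
#' @export
individualized_current <- function(e_generated, e_target = 0.1,
                                   i_applied = 1, max_current = 4) {
  if (any(!is.finite(e_generated)) || any(e_generated <= 0))
    stop("dose error: E_generated must be positive and finite (offending ",
         "indices: ", paste(which(!(e_generated > 0)), collapse = ", "), ")",
         call. = FALSE)
  if (e_target <= 0 || i_applied <= 0 || max_current <= 0)
    stop("dose error: e_target, i_applied and max_current must be positive",
         call. = FALSE)
  current <- i_applied / e_generated * e_target
  clipped <- current > max_current
  current[clipped] <- max_current
  data.frame(current = current, clipped = clipped)
}

#' Realized peak E-fields under standardized dosing
#'
#' Each participant receives the individualized current computed from the
#' model prediction at the 1 mA reference; by linearity the realized field
#' is `true_E * I_individualized`. With perfect predictions every realized
#' value equals `e_target` exactly.
#'
#' @param true_e actual peak E-field per mA for each participant (V/m).
#' @param predicted_e model-predicted peak E-field per mA (V/m).
#' @param e_target target peak E-field (V/m).
#' @param max_current safety cap passed to [individualized_current()]
#'   (default `Inf`: the comparison protocol applies no cap).
#' @return numeric vector of realized peak E-fields (V/m).
#' @export
standardized_distribution <- function(true_e, predicted_e, e_target = 0.1,
                                      max_current = Inf) {
  stopifnot(length(true_e) == length(predicted_e))
  dose <- individualized_current(predicted_e, e_target = e_target,
                                 i_applied = 1, max_current = max_current)
  true_e * dose$current
}

#' Realized peak E-fields under fixed dosing
#'
#' All participants receive one common current, chosen so the population
#' mean realized field equals `e_target`; the realized distribution is the
#' true per-mA distribution rescaled to that mean.
#'
#' @inheritParams standardized_distribution
#' @return numeric vector of realized peak E-fields (V/m).
#' @export
fixed_dose_distribution <- function(true_e, e_target = 0.1) {
  if (length(true_e) == 0L) stop("empty input", call. = FALSE)
  m <- mean(true_e)
  if (abs(m) < .Machine$double.eps)
    stop("degenerate input: zero mean E-field", call. = FALSE)
  true_e * (e_target / m)
}
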