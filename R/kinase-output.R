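## Mapping spectroscopic photostate to predicted autokinase output.
##
## Only the Pr form is autokinase active; the predicted active fraction of
## a sample is therefore its Pr fraction 1 - alpha. The mapping is linear
## (no dimer cooperativity): whether Pr/Pfr heterodimers retain activity
## is an open question and is not modelled.

#' Predicted active-autokinase fraction from the Pfr fraction
#'
#' Returns `1 - alpha`: darkness (alpha = 1, pure Pfr) switches the kinase
#' off; a far-red-clamped sample (alpha = 0, pure Pr) is fully active.
#'
#' @param alpha Pfr fraction(s) in `[0, 1]`.
#' @return the active kinase fraction(s), `1 - alpha`.
#' @export
activeKinaseFraction <- function(alpha) {
  if (any(!is.finite(alpha)) || any(alpha < -1e-12) || any(alpha > 1 + 1e-12))
    bsError("bs_domain_error", "alpha must lie in [0, 1]")
  1 - pmin(pmax(alpha, 0), 1)
}

#' Predicted kinase activity along a dark-reversion time course
#'
#' Evaluates the fitted dark-reversion model and maps each Pfr fraction to
#' the predicted active fraction. Activity is nonincreasing in time
#' whenever the fitted alpha(t) is nondecreasing.
#'
#' @param fit a [DarkReversionFit-class].
#' @param tEval evaluation times in s (>= 0).
#' @param condition free-text condition label attached to the report.
#' @return a data.frame with columns `time_s`, `alpha`, `pr_fraction`,
#'   `active_fraction`, `condition`.
#' @export
kinaseTimecourse <- function(fit, tEval, condition = "dark reversion") {
  stopifnot(methods::is(fit, "DarkReversionFit"))
  tEval <- as.numeric(tEval)
  if (any(!is.finite(tEval)) || any(tEval < 0))
    bsError("bs_domain_error", "evaluation times must be nonnegative")
  alpha <- reversionCurve(fit, tEval)
  data.frame(time_s = tEval, alpha = alpha, pr_fraction = 1 - alpha,
             active_fraction = activeKinaseFraction(alpha),
             condition = condition, stringsAsFactors = FALSE)
}
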