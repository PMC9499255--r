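#' @title Physiological flux accounting
#' @name fluxes
#' @description
#' Derived flux summaries of a simulation: the endogenous glucose
#' production (EGP) decomposition into hepatic/renal production and into
#' gluconeogenesis/glycogenolysis, organ-specific glucose uptake shares,
#' and the hepatic share of insulin clearance. Two bookkeeping identities
#' hold exactly at every output time: `EGP = HGP + RGP` and
#' `EGP = gluconeogenesis + glycogenolysis`.
NULL

#' Flux breakdown of a simulation
#'
#' @param sim a `"twin_sim"` from [simulate_twin()].
#' @return data.frame of class `"flux_breakdown"` with one row per output
#'   time: `time_h`, `HGP`, `RGP`, `EGP`, `gng`, `glycogenolysis`,
#'   `uptake_brain`, `uptake_muscle`, `uptake_liver`, `uptake_kidney`,
#'   `uptake_other` (all umol/kg/min), `ins_secretion`,
#'   `ins_clear_liver`, `ins_clear_periph` (pmol/min).
#' @export
flux_breakdown <- function(sim) {
  stopifnot(inherits(sim, "twin_sim"))
  f <- sim$flux
  out <- data.frame(
    time_h = sim$time_h,
    HGP = f$glycogenolysis_liver + f$gng_liver,
    RGP = f$glycogenolysis_kidney + f$gng_kidney,
    gng = f$gng_liver + f$gng_kidney,
    glycogenolysis = f$glycogenolysis_liver + f$glycogenolysis_kidney,
    uptake_brain = f$u_brain,
    uptake_muscle = f$u_muscle,
    uptake_liver = f$u_liver,
    uptake_kidney = f$u_kidney,
    uptake_other = f$u_other,
    ins_secretion = f$ins_secretion,
    ins_clear_liver = f$ins_clear_liver,
    ins_clear_periph = f$ins_clear_periph
  )
  out$EGP <- out$HGP + out$RGP
  class(out) <- c("flux_breakdown", "data.frame")
  out
}

.window_rows <- function(fx, window_h) {
  if (is.null(window_h)) return(rep(TRUE, nrow(fx)))
  fx$time_h >= window_h[1] - 1e-9 & fx$time_h <= window_h[2] + 1e-9
}

#' Gluconeogenic fraction of EGP
#'
#' Time-averaged (liver + kidney gluconeogenesis) / EGP over a window,
#' the study convention for the gluconeogenesis contribution to
#' endogenous glucose production.
#'
#' @param fluxes a [flux_breakdown()] (or a `"twin_sim"`, converted).
#' @param window_h length-2 window in hours, or `NULL` for the whole
#'   trajectory.
#' @return Fraction in `[0, 1]`.
#' @export
gng_fraction <- function(fluxes, window_h = NULL) {
  if (inherits(fluxes, "twin_sim")) fluxes <- flux_breakdown(fluxes)
  keep <- .window_rows(fluxes, window_h)
  if (!any(keep)) stop("window contains no output times")
  egp <- mean(fluxes$EGP[keep])
  if (egp <= 0) stop("EGP is zero over the window: fraction undefined")
  mean(fluxes$gng[keep]) / egp
}

#' Organ shares of glucose disposal
#'
#' Per-organ share of total glucose uptake, time-averaged over a window.
#'
#' @inheritParams gng_fraction
#' @return Named vector (brain, muscle, liver, kidney, other) summing
#'   to 1.
#' @export
organ_uptake_fractions <- function(fluxes, window_h = NULL) {
  if (inherits(fluxes, "twin_sim")) fluxes <- flux_breakdown(fluxes)
  keep <- .window_rows(fluxes, window_h)
  if (!any(keep)) stop("window contains no output times")
  u <- c(brain = mean(fluxes$uptake_brain[keep]),
         muscle = mean(fluxes$uptake_muscle[keep]),
         liver = mean(fluxes$uptake_liver[keep]),
         kidney = mean(fluxes$uptake_kidney[keep]),
         other = mean(fluxes$uptake_other[keep]))
  tot <- sum(u)
  if (tot <= 0) stop("total uptake is zero over the window")
  u / tot
}

#' Hepatic share of insulin clearance
#'
#' Liver insulin degradation divided by total degradation, time-averaged.
#'
#' @inheritParams gng_fraction
#' @return Share in `[0, 1]`.
#' @export
insulin_clearance_split <- function(fluxes, window_h = NULL) {
  if (inherits(fluxes, "twin_sim")) fluxes <- flux_breakdown(fluxes)
  keep <- .window_rows(fluxes, window_h)
  if (!any(keep)) stop("window contains no output times")
  liv <- mean(fluxes$ins_clear_liver[keep])
  tot <- liv + mean(fluxes$ins_clear_periph[keep])
  if (tot <= 0) stop("total insulin clearance is zero over the window")
  liv / tot
}

#' Map a simulation onto a study observable
#'
#' Returns the simulated counterpart of an observable kind in the units
#' of the corresponding study data.
#'
#' @param sim a `"twin_sim"`.
#' @param kind one of `"plasma_glucose"` (mmol/L), `"plasma_insulin"`
#'   (pmol/L), `"EGP"` (umol/kg/min), `"hepatic_glycogen"` (mmol/L of
#'   liver), `"gng_fraction_of_EGP"` (unitless, instantaneous), or
#'   `"glycogenolysis_contribution"` (unitless, instantaneous).
#' @return data.frame with `time_h`, `value`.
#' @export
observable_map <- function(sim, kind) {
  stopifnot(inherits(sim, "twin_sim"))
  kinds <- c("plasma_glucose", "plasma_insulin", "EGP", "hepatic_glycogen",
             "gng_fraction_of_EGP", "glycogenolysis_contribution")
  if (!kind %in% kinds)
    stop("unknown observable kind: ", kind)
  fx <- flux_breakdown(sim)
  value <- switch(kind,
    plasma_glucose = sim$state[, "glc_plasma"],
    plasma_insulin = sim$state[, "ins_plasma"],
    EGP = fx$EGP,
    hepatic_glycogen = sim$state[, "glycogen_liver"],
    gng_fraction_of_EGP = ifelse(fx$EGP > 0, fx$gng / fx$EGP, NA_real_),
    glycogenolysis_contribution =
      ifelse(fx$EGP > 0, fx$glycogenolysis / fx$EGP, NA_real_))
  data.frame(time_h = sim$time_h, value = value)
}
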