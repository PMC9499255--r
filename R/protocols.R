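#' @title Protocol runners
#' @name protocols
#' @description
#' Pre-built runners for the experimental designs the model is used for:
#' multi-day fasts, the protein-tolerance-test/fast/protein-tolerance-
#' test design, and the three-week diet-comparison protocol (week 1
#' standard diet to reach a daily rhythm, week 2 diet switch, week 3
#' analysed).
NULL

#' Run a plain fast
#'
#' Simulates `hours` of fasting from a fed basal state and summarises
#' glycogen, glucose and the gluconeogenic fraction.
#'
#' @param twin a [digital_twin()].
#' @param hours fast length; above 72 h is outside the supported range
#'   and triggers a warning.
#' @param init_glycogen starting hepatic glycogen (fed default 275).
#' @return List of class `"protocol_result"` with `sim`, `fluxes` and
#'   `summary`.
#' @export
run_fast <- function(twin, hours = 48, init_glycogen = 275) {
  if (hours > 72)
    warning("fasts beyond 72 h are outside the supported range")
  sim <- twin_simulate(twin, diet_schedule(), t_span_h = c(0, hours),
                       init_glycogen = init_glycogen)
  fx <- flux_breakdown(sim)
  g <- sim$state[, "glc_plasma"]
  gl <- sim$state[, "glycogen_liver"]
  summary <- list(
    glucose_start = g[1], glucose_end = g[length(g)],
    glycogen_start = gl[1], glycogen_end = gl[length(gl)],
    gng_fraction_start = gng_fraction(fx, c(0, min(2, hours))),
    gng_fraction_end = gng_fraction(fx, c(max(0, hours - 2), hours)))
  structure(list(sim = sim, fluxes = fx, summary = summary,
                 protocol = sprintf("%g h fast", hours)),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol result> %s\n", x$protocol))
  str(x$summary, give.attr = FALSE)
  invisible(x)
}

#' Run the tolerance-test / fast / tolerance-test protocol
#'
#' Three standard diet days; on day 3 a regular dinner at 19:00 and a
#' protein bolus at 23:00 (fed state); then a 48 h fast; then the same
#' bolus again, followed by a 6 h observation window. Summaries report
#' the fed-state and post-fast peak glucose rises above the pre-bolus
#' level within 2 h, the fasting glucose decline, and how long the
#' post-fast response stays above its pre-bolus level.
#'
#' @param twin a [digital_twin()].
#' @param bolus a [meal_event()] template for the tolerance test (start
#'   time ignored); default the 132.5 kcal protein bolus (25.55 g
#'   protein, 2.6 g carbohydrate).
#' @param fast_h fast length between the two boluses.
#' @param daily_kcal energy of the standard lead-in days.
#' @param noticeable_mM threshold below which a fed-state rise counts as
#'   negligible (documented default 0.5 mmol/L).
#' @return `"protocol_result"` with `sim`, `fluxes` and `summary`
#'   (fed_rise_mM, post_fast_rise_mM, sustained_h, fast_decline_mM,
#'   fed_negligible).
#' @export
run_optt_fast_optt <- function(twin,
                               bolus = meal_from_energy(132.5,
                                                        carb_g = 2.6,
                                                        protein_g = 25.55,
                                                        duration_min = 10),
                               fast_h = 48, daily_kcal = 2000,
                               noticeable_mM = 0.5) {
  t_bolus1 <- 3 * 24 - 1           # 23:00 on day 3
  t_bolus2 <- t_bolus1 + fast_h
  t_end <- t_bolus2 + 6
  b1 <- as.data.frame(bolus); b1$start_h <- t_bolus1
  b2 <- as.data.frame(bolus); b2$start_h <- t_bolus2
  sched <- concat_schedules(standard_diet(daily_kcal, days = 3),
                            diet_schedule(b1), diet_schedule(b2))
  sim <- twin_simulate(twin, sched, t_span_h = c(0, t_end))
  g <- sim$state[, "glc_plasma"]; th <- sim$time_h

  pre1 <- g[max(which(th <= t_bolus1))]
  rise1 <- max(g[th >= t_bolus1 & th <= t_bolus1 + 2]) - pre1
  pre2 <- g[max(which(th <= t_bolus2))]
  rise2 <- max(g[th >= t_bolus2 & th <= t_bolus2 + 2]) - pre2
  w <- th >= t_bolus2 + 0.2 & th <= t_end
  below <- which(g[w] <= pre2)
  sustained <- if (length(below)) th[w][min(below)] - t_bolus2 else
    t_end - t_bolus2
  decline <- g[max(which(th <= t_bolus1 + 0.5))] - pre2

  summary <- list(fed_rise_mM = rise1, post_fast_rise_mM = rise2,
                  sustained_h = sustained, fast_decline_mM = decline,
                  fed_negligible = rise1 < noticeable_mM,
                  pre_fed = pre1, pre_fast_end = pre2)
  structure(list(sim = sim, fluxes = flux_breakdown(sim),
                 summary = summary,
                 protocol = sprintf("OPTT / %g h fast / OPTT", fast_h)),
            class = "protocol_result")
}

#' Run the three-week diet comparison
#'
#' Week 1 runs the standard diet to establish a daily rhythm; the new
#' diet starts with week 2; the third week is summarised: mean plasma
#' glucose, mean insulin, mean hepatic glycogen, mean gluconeogenesis
#' and mean EGP.
#'
#' @param twin a [digital_twin()].
#' @param schedules named list of [diet_schedule()]s covering at least
#'   14 days each (they are placed after the standard week).
#' @param daily_kcal energy of the standard lead-in week.
#' @param grid_min output resolution (summaries are insensitive to it
#'   within 1%).
#' @return data.frame of class `"diet_comparison"`, one row per diet:
#'   `diet`, `mean_glucose`, `mean_insulin`, `mean_glycogen`, `mean_gng`,
#'   `mean_egp`, `weekly_kcal`.
#' @export
run_diet_comparison <- function(twin, schedules, daily_kcal = 2000,
                                grid_min = 4) {
  if (is.null(names(schedules)))
    names(schedules) <- vapply(schedules, function(s)
      attr(s, "scheme"), "")
  rows <- lapply(names(schedules), function(nm) {
    s <- schedules[[nm]]
    if (max(s$start_h) < 13 * 24)
      stop("schedule '", nm, "' must cover at least 14 days")
    sched <- concat_schedules(standard_diet(daily_kcal, days = 7),
                              shift_schedule(s, 7 * 24))
    sim <- twin_simulate(twin, sched, t_span_h = c(0, 21 * 24),
                         grid_min = grid_min)
    w <- sim$time_h >= 14 * 24 & sim$time_h <= 21 * 24
    fx <- flux_breakdown(sim)
    data.frame(diet = nm,
               mean_glucose = mean(sim$state[w, "glc_plasma"]),
               mean_insulin = mean(sim$state[w, "ins_plasma"]),
               mean_glycogen = mean(sim$state[w, "glycogen_liver"]),
               mean_gng = mean(fx$gng[w]),
               mean_egp = mean(fx$EGP[w]),
               weekly_kcal = weekly_mean_kcal(s, days = 14))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("diet_comparison", "data.frame")
  out
}
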