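#' @title Digital-twin personalisation
#' @name personalisation
#' @description
#' Three calibration categories turn the population model into a
#' person-specific twin:
#' 1. declaration of anthropometry and diabetes status — scales blood
#'    volumes (total within +-30% of the sex-specific reference
#'    equations; liver blood fixed at 13% of total) and selects the
#'    general-parameter variant;
#' 2. calibration to basal values — fits the basal-glucose and
#'    basal-insulin person parameters and constructs a plausible five-day
#'    lead-in diet so the simulated state at study start matches the
#'    supplied baselines;
#' 3. calibration based on data — fits the insulin-production,
#'    insulin-clearance and insulin-resistance modifiers to the
#'    designated calibration points, holding all 57 general parameters
#'    fixed.
NULL

#' Construct a digital twin
#'
#' Bundles anthropometry, the matching general-parameter variant and
#' person-specific parameters.
#'
#' @param anthro an [anthropometry()] object; `anthro$diabetes` selects
#'   the parameter variant when `params` is `NULL`.
#' @param personal person-specific parameters; defaults to the variant
#'   defaults.
#' @param params general parameters; defaults to the variant defaults.
#' @param blood_adjustment blood-volume adjustment in `[0.7, 1.3]`.
#' @return Object of class `"digital_twin"`.
#' @export
#' @examples
#' tw <- digital_twin(anthropometry("male", 80, 1.80))
digital_twin <- function(anthro = anthropometry(), personal = NULL,
                         params = NULL, blood_adjustment = 1.0) {
  variant <- if (anthro$diabetes) "t2d" else "healthy"
  if (is.null(params)) params <- default_params(variant)
  if (is.null(personal)) personal <- personal_defaults(variant)
  validate_personal(personal)
  structure(list(anthro = anthro, params = params, personal = personal,
                 blood_adjustment = blood_adjustment, variant = variant),
            class = "digital_twin")
}

#' @export
print.digital_twin <- function(x, ...) {
  cat(sprintf("<digital twin> %s, %.0f kg, %.2f m, %s; basal %.1f mmol/L / %.0f pmol/L\n",
              x$anthro$sex, x$anthro$weight_kg, x$anthro$height_m,
              x$variant, x$personal[["basal_glucose"]],
              x$personal[["basal_insulin"]]))
  invisible(x)
}

#' Simulate a digital twin over a schedule
#'
#' Convenience wrapper around [simulate_twin()] using the twin's
#' parameters.
#'
#' @param twin a [digital_twin()].
#' @param schedule,t_span_h,init,init_glycogen,grid_min see
#'   [simulate_twin()].
#' @return A `"twin_sim"`.
#' @export
twin_simulate <- function(twin, schedule = diet_schedule(),
                          t_span_h = c(0, 24), init = "basal",
                          init_glycogen = 275, grid_min = 1) {
  simulate_twin(schedule, t_span_h, params = twin$params,
                personal = twin$personal, anthro = twin$anthro,
                init = init, init_glycogen = init_glycogen,
                blood_adjustment = twin$blood_adjustment,
                grid_min = grid_min)
}

#' Calibrate a twin to basal values and build a lead-in diet
#'
#' Sets the basal-glucose and basal-insulin person parameters from the
#' supplied baselines (exact, because the model anchors its basal state
#' to them) and searches a five-day lead-in diet (3 meals/day, meal
#' energy 200-1000 kcal, standard macronutrient split) whose endpoint
#' hepatic glycogen matches the requested baseline: the daily energy is
#' tuned by golden-section search on the endpoint mismatch.
#'
#' @param twin a [digital_twin()].
#' @param observations list with `glucose` (mmol/L, required), optional
#'   `insulin` (pmol/L) and `hepatic_glycogen` (mmol/L of liver).
#' @param tol_frac acceptable relative mismatch of the glycogen endpoint
#'   (default 0.05, i.e. 5% when no SEM is available).
#' @return List with `twin` (updated), `lead_in` (the five-day
#'   [diet_schedule()]), `daily_kcal`, `achieved` (endpoint glucose,
#'   insulin, glycogen).
#' @export
calibrate_basal <- function(twin, observations, tol_frac = 0.05) {
  if (is.null(observations$glucose))
    stop("observations must contain at least a baseline glucose")
  personal <- twin$personal
  personal[["basal_glucose"]] <- observations$glucose
  if (!is.null(observations$insulin))
    personal[["basal_insulin"]] <- observations$insulin
  validate_personal(personal)
  twin$personal <- personal
  target_gly <- if (!is.null(observations$hepatic_glycogen))
    observations$hepatic_glycogen else 275
  if (target_gly < 50 || target_gly > 400)
    stop("baseline hepatic glycogen outside the admissible range")

  endpoint <- function(daily_kcal) {
    sched <- standard_diet(daily_kcal, days = 5)
    sim <- twin_simulate(twin, sched, t_span_h = c(0, 5 * 24),
                         init_glycogen = 275, grid_min = 6)
    sim$state[nrow(sim$state), "glycogen_liver"]
  }
  # meal energy bounds 200-1000 kcal/meal, 3 meals/day
  opt <- stats::optimize(function(k) (endpoint(k) - target_gly)^2,
                         interval = c(600, 3000), tol = 20)
  daily <- opt$minimum
  sched <- standard_diet(daily, days = 5)
  sim <- twin_simulate(twin, sched, t_span_h = c(0, 5 * 24),
                       init_glycogen = 275, grid_min = 6)
  end <- sim$state[nrow(sim$state), ]
  if (abs(end[["glycogen_liver"]] - target_gly) > tol_frac * target_gly +
      15)
    stop("no admissible lead-in diet reaches the requested baseline ",
         "glycogen within meal-size bounds")
  list(twin = twin, lead_in = sched, daily_kcal = daily,
       achieved = c(glucose = unname(end[["glc_plasma"]]),
                    insulin = unname(end[["ins_plasma"]]),
                    hepatic_glycogen = unname(end[["glycogen_liver"]])))
}

#' Fit the person-specific modifiers to calibration data
#'
#' Minimises the weighted least-squares cost on the designated
#' calibration records over the insulin-production, insulin-clearance
#' and insulin-resistance modifiers, holding every general parameter
#' fixed (category separation). Bounded quasi-Newton optimisation within
#' `[0.3, 3]` per modifier.
#'
#' @param twin a [digital_twin()].
#' @param calibration_data a [study_dataset()]; records flagged
#'   `is_calibration` are used (all records when none are flagged).
#' @param free which modifiers to fit.
#' @param grid_min simulation resolution during fitting.
#' @param rtol solver tolerance during fitting (relaxed by default: the
#'   cost surface does not need tighter integration than the data noise).
#' @param maxit Nelder-Mead iteration cap.
#' @return List with `twin` (updated personal parameters), `modifiers`,
#'   `cost`, `convergence`.
#' @export
fit_person_params <- function(twin, calibration_data,
                              free = c("prod_mod", "clear_mod",
                                       "resist_mod"),
                              grid_min = 4, rtol = 1e-5, maxit = 200) {
  ds <- calibration_data
  use <- ds$records$is_calibration
  if (!any(use)) use <- NULL
  obj <- function(theta) {
    personal <- twin$personal
    personal[free] <- pmin(pmax(theta, 0.3), 3)
    sim <- try(simulate_twin(ds$schedule, ds$t_span_h,
                             params = twin$params, personal = personal,
                             anthro = twin$anthro,
                             init_glycogen = ds$init_glycogen,
                             grid_min = grid_min, rtol = rtol,
                             atol = 1e-7), silent = TRUE)
    if (inherits(sim, "try-error")) return(1e10)
    wls_cost(ds, sim, use = use)
  }
  start <- pmin(pmax(twin$personal[free], 0.3), 3)
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-4))
  if (fit$value > obj(start) + 1e-9)
    stop("modifier optimisation failed to improve on the starting point")
  par <- pmin(pmax(fit$par, 0.3), 3)
  twin$personal[free] <- par
  list(twin = twin, modifiers = stats::setNames(par, free),
       cost = fit$value, convergence = fit$convergence)
}

#' Read a subject profile from YAML
#'
#' Keys: `sex`, `weight_kg`, `height_m`, optional `age_y`, `diabetes`,
#' `baselines` (list with `glucose`, `insulin`, `hepatic_glycogen`) and
#' `personal` overrides.
#'
#' @param path YAML file path.
#' @return A [digital_twin()]; baselines, when present, are applied as
#'   basal person parameters.
#' @export
read_subject <- function(path) {
  y <- yaml::read_yaml(path)
  an <- anthropometry(sex = y$sex, weight_kg = y$weight_kg,
                      height_m = y$height_m,
                      age_y = if (is.null(y$age_y)) NA_real_ else y$age_y,
                      diabetes = isTRUE(y$diabetes))
  tw <- digital_twin(an)
  if (!is.null(y$baselines$glucose))
    tw$personal[["basal_glucose"]] <- y$baselines$glucose
  if (!is.null(y$baselines$insulin))
    tw$personal[["basal_insulin"]] <- y$baselines$insulin
  for (nm in intersect(names(y$personal), names(tw$personal)))
    tw$personal[[nm]] <- y$personal[[nm]]
  validate_personal(tw$personal)
  tw
}
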