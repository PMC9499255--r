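#' @title Parameter estimation and model acceptance
#' @name estimation
#' @description
#' The training stack: study datasets (observable time series weighted by
#' their standard errors of the mean), the weighted least-squares cost,
#' the chi-squared acceptance test at significance 0.05 with degrees of
#' freedom equal to the number of data points, eight qualitative
#' physiological penalty constraints (active during optimisation,
#' excluded from the chi-squared verdict), particle-swarm global
#' optimisation within per-parameter bounds, and ensemble min/max
#' uncertainty bands.
NULL

#' Standard error of the mean
#'
#' @param sigma sample standard deviation (>= 0).
#' @param n number of replicates (>= 1).
#' @return `sigma / sqrt(n)`.
#' @export
#' @examples
#' sem(2, 4)  # 1
sem <- function(sigma, n) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(sigma < 0)) stop("sigma must be >= 0")
  sigma / sqrt(n)
}

#' Construct a study dataset
#'
#' The unit the cost function consumes: per-observation records of time,
#' observable kind, value, sample SD and replicate count, plus the
#' protocol needed to simulate the study.
#'
#' @param records data.frame with columns `time_h`, `observable`, `value`,
#'   `sd`, `n`, and optionally `is_calibration` (logical, the designated
#'   calibration points).
#' @param schedule the study's [diet_schedule()].
#' @param t_span_h simulation window covering all record times.
#' @param population `"healthy"` or `"t2d"`.
#' @param study_id identifier string.
#' @param init_glycogen initial hepatic glycogen for the protocol.
#' @return Object of class `"study_dataset"`.
#' @export
study_dataset <- function(records, schedule = diet_schedule(),
                          t_span_h = NULL, population = "healthy",
                          study_id = "study", init_glycogen = 275) {
  need <- c("time_h", "observable", "value", "sd", "n")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(records$is_calibration))
    records$is_calibration <- FALSE
  records$sem <- sem(records$sd, records$n)
  if (is.null(t_span_h))
    t_span_h <- c(0, max(records$time_h) + 0.5)
  if (any(records$time_h < t_span_h[1]) || any(records$time_h > t_span_h[2]))
    stop("record times outside the protocol span")
  structure(list(records = records, schedule = schedule,
                 t_span_h = t_span_h, population = population,
                 study_id = study_id, init_glycogen = init_glycogen),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study dataset> %s (%s): %d records, %d observables, %.0f-%.0f h\n",
              x$study_id, x$population, nrow(x$records),
              length(unique(x$records$observable)),
              x$t_span_h[1], x$t_span_h[2]))
  invisible(x)
}

#' Read/write study datasets as CSV
#'
#' Columns: `study`, `population`, `time_h`, `observable`, `value`, `sd`,
#' `n`, `is_calibration`. The protocol is carried separately (YAML, see
#' [read_schedule()]).
#'
#' @param path CSV path.
#' @param schedule,t_span_h,init_glycogen protocol information to attach
#'   on read.
#' @return A [study_dataset()].
#' @export
read_study <- function(path, schedule = diet_schedule(), t_span_h = NULL,
                       init_glycogen = 275) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  study_dataset(df[, c("time_h", "observable", "value", "sd", "n",
                       "is_calibration")],
                schedule = schedule, t_span_h = t_span_h,
                population = df$population[1], study_id = df$study[1],
                init_glycogen = init_glycogen)
}

#' @rdname read_study
#' @param dataset a [study_dataset()].
#' @export
write_study <- function(dataset, path) {
  df <- dataset$records
  df$study <- dataset$study_id
  df$population <- dataset$population
  utils::write.csv(df[, c("study", "population", "time_h", "observable",
                          "value", "sd", "n", "is_calibration")],
                   path, row.names = FALSE)
  invisible(path)
}

# interpolate a simulated observable at the record times
.sim_at <- function(sim, kind, times_h) {
  ob <- observable_map(sim, kind)
  stats::approx(ob$time_h, ob$value, xout = times_h, rule = 2)$y
}

#' Weighted least-squares cost
#'
#' `sum(((y - yhat) / SEM)^2)` over all records, with the simulated
#' counterpart linearly interpolated from the dense output grid. Records
#' whose SEM falls below 5% of that observable's dynamic range (in the
#' dataset) are floored to that value to avoid single points dominating
#' the fit; an SEM of zero with a flat observable raises an error.
#'
#' @param dataset a [study_dataset()].
#' @param sim a `"twin_sim"` covering the record times.
#' @param use logical mask or `NULL`; e.g. `dataset$records$is_calibration`
#'   to restrict to calibration points.
#' @param sem_floor_frac floor as a fraction of the observable's range
#'   (default 0.05); set 0 to disable.
#' @return Non-negative scalar cost.
#' @export
wls_cost <- function(dataset, sim, use = NULL, sem_floor_frac = 0.05) {
  rec <- dataset$records
  if (!is.null(use)) rec <- rec[use, , drop = FALSE]
  if (nrow(rec) == 0) stop("no records selected")
  total <- 0
  for (kind in unique(rec$observable)) {
    rows <- rec[rec$observable == kind, , drop = FALSE]
    yhat <- .sim_at(sim, kind, rows$time_h)
    s <- rows$sem
    floor_val <- sem_floor_frac * diff(range(rows$value))
    s <- pmax(s, floor_val)
    if (any(s <= 0))
      stop("record with zero SEM and zero dynamic range in ", kind)
    total <- total + sum(((rows$value - yhat) / s)^2)
  }
  total
}

#' Chi-squared acceptance threshold
#'
#' The (1 - alpha) quantile of the chi-squared distribution with `dof`
#' degrees of freedom; the degrees of freedom equal the number of data
#' points.
#'
#' @param alpha significance level in (0, 1); default 0.05.
#' @param dof degrees of freedom (>= 1).
#' @return Threshold value.
#' @export
#' @examples
#' round(chi2_threshold(0.05, 126))  # 153
chi2_threshold <- function(alpha = 0.05, dof) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (any(dof < 1)) stop("dof must be >= 1")
  stats::qchisq(1 - alpha, df = dof)
}

#' Chi-squared model acceptance test
#'
#' The model is rejected when the (unpenalised) cost exceeds the
#' chi-squared threshold.
#'
#' @param cost_value weighted least-squares cost (penalties excluded).
#' @param dof number of data points.
#' @param alpha significance level.
#' @return List with `pass` (logical), `cost`, `dof`, `threshold`.
#' @export
#' @examples
#' chi2_test(175, 190)$pass  # TRUE
chi2_test <- function(cost_value, dof, alpha = 0.05) {
  thr <- chi2_threshold(alpha, dof)
  list(pass = cost_value <= thr, cost = cost_value, dof = dof,
       threshold = thr)
}

#' Evaluate the eight qualitative physiological constraints
#'
#' The constraints guard against non-physiological parameter vectors
#' during optimisation; violations add a constant penalty each (default
#' 1e5) to the optimisation objective but are excluded from the
#' chi-squared verdict:
#' 1. no negative fluxes, states or variables (tolerance 1e-9);
#' 2. plasma insulin never above 3000 pmol/L;
#' 3. renal glucose production never above 40% of total production;
#' 4. hepatic insulin degradation never below 40% of total degradation
#'    (time-averaged);
#' 5. organ glucose-uptake shares proportionate in the post-absorptive
#'    window (brain 0.35-0.55, muscle 0.10-0.28, liver 0.05-0.22, kidney
#'    0.02-0.14) and not brain-dominated postprandially (brain < 0.55);
#' 6. gluconeogenesis contribution to EGP never above 100%;
#' 7. fed-state hepatic glycogen between 200 and 350 mmol/L;
#' 8. unfed-state (>= 44 h fasted) hepatic glycogen below 100 mmol/L.
#'
#' @param sim a `"twin_sim"`. For constraints 5, 7 and 8 the simulation
#'   should cover the referenced windows; checks whose window is absent
#'   are skipped (reported `NA`).
#' @param fed_h time points (hours) representing the fed state; default
#'   taken 3 h after each meal that follows at least 6 h of prior intake,
#'   or `NULL` to skip.
#' @param unfed_h time points fasted >= 44 h, or `NULL` to skip.
#' @param postabs_window_h post-absorptive window for constraint 5.
#' @param postprandial_window_h postprandial window for constraint 5.
#' @param penalty_constant penalty per violated constraint.
#' @return List with `penalty` (>= 0) and `report`, a data.frame with one
#'   row per constraint (`constraint`, `ok`, `detail`).
#' @export
evaluate_penalties <- function(sim, fed_h = NULL, unfed_h = NULL,
                               postabs_window_h = NULL,
                               postprandial_window_h = NULL,
                               penalty_constant = 1e5) {
  fx <- flux_breakdown(sim)
  th <- sim$time_h
  ok <- rep(NA, 8L)
  detail <- character(8L)

  min_state <- min(sim$state)
  flux_cols <- c("HGP", "RGP", "EGP", "gng", "glycogenolysis",
                 "uptake_brain", "uptake_muscle", "uptake_liver",
                 "uptake_kidney", "uptake_other", "ins_secretion",
                 "ins_clear_liver", "ins_clear_periph")
  min_flux <- min(as.matrix(fx[flux_cols]))
  ok[1] <- min_state >= -1e-9 && min_flux >= -1e-9
  detail[1] <- sprintf("min state %.2e, min flux %.2e", min_state, min_flux)

  imax <- max(sim$state[, "ins_plasma"])
  ok[2] <- imax <= 3000
  detail[2] <- sprintf("max plasma insulin %.0f pmol/L", imax)

  rshare <- fx$RGP / pmax(fx$EGP, 1e-12)
  ok[3] <- max(rshare) <= 0.40
  detail[3] <- sprintf("max RGP/EGP %.3f", max(rshare))

  liv_share <- insulin_clearance_split(fx)
  ok[4] <- liv_share >= 0.40
  detail[4] <- sprintf("hepatic clearance share %.3f", liv_share)

  if (!is.null(postabs_window_h)) {
    u <- organ_uptake_fractions(fx, postabs_window_h)
    in_band <- u["brain"] >= 0.35 && u["brain"] <= 0.55 &&
      u["muscle"] >= 0.10 && u["muscle"] <= 0.28 &&
      u["liver"] >= 0.05 && u["liver"] <= 0.22 &&
      u["kidney"] >= 0.02 && u["kidney"] <= 0.14
    pp_ok <- TRUE
    if (!is.null(postprandial_window_h)) {
      up <- organ_uptake_fractions(fx, postprandial_window_h)
      pp_ok <- up["brain"] < 0.55
    }
    ok[5] <- in_band && pp_ok
    detail[5] <- sprintf("post-absorptive brain %.2f muscle %.2f liver %.2f kidney %.2f",
                         u["brain"], u["muscle"], u["liver"], u["kidney"])
  } else detail[5] <- "window not provided"

  gshare <- fx$gng / pmax(fx$EGP, 1e-12)
  ok[6] <- max(gshare) <= 1 + 1e-9
  detail[6] <- sprintf("max GNG/EGP %.3f", max(gshare))

  if (!is.null(fed_h)) {
    gl <- sapply(fed_h, function(h)
      sim$state[which.min(abs(th - h)), "glycogen_liver"])
    ok[7] <- all(gl >= 200 & gl <= 350)
    detail[7] <- sprintf("fed glycogen %s mmol/L",
                         paste(round(gl), collapse = "/"))
  } else detail[7] <- "fed time points not provided"

  if (!is.null(unfed_h)) {
    gl <- sapply(unfed_h, function(h)
      sim$state[which.min(abs(th - h)), "glycogen_liver"])
    ok[8] <- all(gl < 100)
    detail[8] <- sprintf("unfed glycogen %s mmol/L",
                         paste(round(gl), collapse = "/"))
  } else detail[8] <- "unfed time points not provided"

  viol <- sum(!ok, na.rm = TRUE)
  list(penalty = viol * penalty_constant,
       report = data.frame(constraint = 1:8, ok = ok, detail = detail))
}

# objective for fit_global: cost over datasets + penalties, plus the
# unpenalised cost needed for the chi-squared archive
.fit_objective <- function(theta, free, base_params, datasets, personal,
                           anthro, grid_min, penalty_sims, rtol = 1e-5) {
  p <- base_params
  p[free] <- theta
  total_cost <- 0
  for (ds in datasets) {
    sim <- try(simulate_twin(ds$schedule, ds$t_span_h, params = p,
                             personal = personal, anthro = anthro,
                             init_glycogen = ds$init_glycogen,
                             grid_min = grid_min, rtol = rtol,
                             atol = 1e-7), silent = TRUE)
    if (inherits(sim, "try-error"))
      return(list(cost = Inf, penalty = Inf))
    total_cost <- total_cost + wls_cost(ds, sim)
  }
  penalty <- 0
  if (penalty_sims) {
    pen <- try(suppressWarnings(
      evaluate_penalties(sim)), silent = TRUE)
    penalty <- if (inherits(pen, "try-error")) 1e5 else pen$penalty
  }
  list(cost = total_cost, penalty = penalty)
}

#' Global parameter estimation by particle swarm
#'
#' Minimises the penalised weighted least-squares cost over a set of free
#' general parameters within their bounds, using a standard global-best
#' particle swarm (inertia 0.729, cognitive/social weights 1.49). Every
#' evaluated vector whose unpenalised cost passes the chi-squared test at
#' the pooled degrees of freedom (total number of data points) is
#' archived into the acceptance ensemble. Deterministic under a fixed
#' seed.
#'
#' @param datasets list of [study_dataset()] objects sharing a population
#'   tag.
#' @param free character vector of general-parameter names to optimise;
#'   the rest stay at `base_params`.
#' @param base_params starting general parameters; defaults to the
#'   population variant defaults.
#' @param personal person-specific parameters held fixed.
#' @param anthro subject anthropometry.
#' @param bounds data.frame as [param_bounds()].
#' @param swarm_size particles; the full-scale default is 2000, the
#'   `"smoke"` preset uses 24.
#' @param max_iter iteration cap (smoke preset 40).
#' @param tol stop when the best cost improves by less than `tol` over
#'   `stall_iter` consecutive iterations.
#' @param stall_iter stall window (default 20).
#' @param preset `"smoke"` or `"full"`; presets set `swarm_size`/
#'   `max_iter` unless given explicitly.
#' @param alpha chi-squared significance level for the archive.
#' @param grid_min simulation grid used during fitting.
#' @param penalty_sims evaluate the qualitative constraints on the last
#'   dataset's simulation each evaluation (slower); default TRUE.
#' @param seed RNG seed (integer).
#' @return Object of class `"fit_result"`: `best` (named vector of free
#'   parameters), `best_params` (full vector), `best_cost`,
#'   `best_penalty`, `ensemble` (matrix of archived vectors),
#'   `ensemble_cost`, `dof`, `threshold`, `chi2` (verdict for the best
#'   vector), `param_range` (per-parameter min/max across the ensemble),
#'   `trace` (best cost per iteration).
#' @export
fit_global <- function(datasets, free, base_params = NULL,
                       personal = NULL, anthro = anthropometry(),
                       bounds = NULL, swarm_size = NULL, max_iter = NULL,
                       tol = 1e-6, stall_iter = 20,
                       preset = c("smoke", "full"), alpha = 0.05,
                       grid_min = 4, penalty_sims = TRUE, rtol = 1e-5,
                       seed = 1) {
  preset <- match.arg(preset)
  if (is.null(swarm_size)) swarm_size <- if (preset == "full") 2000 else 24
  if (is.null(max_iter)) max_iter <- if (preset == "full") 500 else 40
  if (!length(datasets)) stop("no datasets supplied")
  if (inherits(datasets, "study_dataset")) datasets <- list(datasets)
  pops <- unique(vapply(datasets, `[[`, "", "population"))
  if (length(pops) > 1) stop("datasets mix population tags")
  variant <- if (pops == "t2d") "t2d" else "healthy"
  if (is.null(base_params)) base_params <- default_params(variant)
  if (is.null(personal)) personal <- personal_defaults(variant)
  if (is.null(bounds)) bounds <- param_bounds(variant)
  if (any(bounds$lower > bounds$upper))
    stop("invalid bounds: lower > upper")
  miss <- setdiff(free, bounds$name)
  if (length(miss)) stop("unknown free parameters: ",
                         paste(miss, collapse = ", "))
  lb <- bounds$lower[match(free, bounds$name)]
  ub <- bounds$upper[match(free, bounds$name)]
  d <- length(free)
  dof <- sum(vapply(datasets, function(x) nrow(x$records), 0L))
  thr <- chi2_threshold(alpha, dof)

  set.seed(seed)
  obj <- function(theta) .fit_objective(theta, free, base_params, datasets,
                                        personal, anthro, grid_min,
                                        penalty_sims, rtol)

  # swarm init: include the base-parameter point so self-consistent
  # fixtures start near truth
  X <- matrix(stats::runif(swarm_size * d, lb, ub), nrow = swarm_size,
              byrow = TRUE)
  X[1, ] <- pmin(pmax(base_params[free], lb), ub)
  V <- matrix(stats::runif(swarm_size * d, -(ub - lb), ub - lb) * 0.1,
              nrow = swarm_size, byrow = TRUE)
  pbest <- X; pbest_val <- rep(Inf, swarm_size)
  gbest <- X[1, ]; gbest_val <- Inf
  archive <- list(); archive_cost <- numeric()
  trace <- numeric()
  stall <- 0L; last_best <- Inf

  w <- 0.729; c1 <- 1.49; c2 <- 1.49
  for (it in seq_len(max_iter)) {
    for (i in seq_len(swarm_size)) {
      r <- obj(X[i, ])
      val <- r$cost + r$penalty
      if (is.finite(r$cost) && r$penalty == 0 && r$cost <= thr) {
        archive[[length(archive) + 1L]] <- X[i, ]
        archive_cost <- c(archive_cost, r$cost)
      }
      if (val < pbest_val[i]) { pbest[i, ] <- X[i, ]; pbest_val[i] <- val }
      if (val < gbest_val) { gbest <- X[i, ]; gbest_val <- val }
    }
    trace <- c(trace, gbest_val)
    if (last_best - gbest_val < tol) stall <- stall + 1L else stall <- 0L
    last_best <- gbest_val
    if (stall >= stall_iter) break
    r1 <- matrix(stats::runif(swarm_size * d), swarm_size)
    r2 <- matrix(stats::runif(swarm_size * d), swarm_size)
    V <- w * V + c1 * r1 * (pbest - X) +
      c2 * r2 * (matrix(gbest, swarm_size, d, byrow = TRUE) - X)
    X <- X + V
    # reflect at bounds
    for (j in seq_len(d)) {
      lo <- X[, j] < lb[j]; X[lo, j] <- lb[j]; V[lo, j] <- -0.5 * V[lo, j]
      hi <- X[, j] > ub[j]; X[hi, j] <- ub[j]; V[hi, j] <- -0.5 * V[hi, j]
    }
  }

  best_r <- obj(gbest)
  best_params <- base_params
  best_params[free] <- gbest
  ens <- if (length(archive)) do.call(rbind, archive) else
    matrix(numeric(), 0, d)
  colnames(ens) <- free
  pr <- if (nrow(ens)) data.frame(name = free,
                                  min = apply(ens, 2, min),
                                  max = apply(ens, 2, max)) else
    data.frame(name = character(), min = numeric(), max = numeric())
  structure(list(best = stats::setNames(gbest, free),
                 best_params = best_params,
                 best_cost = best_r$cost, best_penalty = best_r$penalty,
                 ensemble = ens, ensemble_cost = archive_cost,
                 dof = dof, threshold = thr,
                 chi2 = chi2_test(best_r$cost, dof, alpha),
                 free = free, personal = personal, anthro = anthro,
                 datasets = datasets, trace = trace, seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit result> %d free parameters, best cost %.2f (dof %d, threshold %.1f): %s\n",
              length(x$free), x$best_cost, x$dof, x$threshold,
              if (x$chi2$pass) "PASS" else "FAIL"))
  cat(sprintf("  ensemble: %d accepted vectors\n", nrow(x$ensemble)))
  invisible(x)
}

#' Ensemble uncertainty bands
#'
#' Simulates every archived parameter vector of a fit over a protocol and
#' returns the pointwise min/max envelope per observable — the model's
#' estimated prediction uncertainty.
#'
#' @param fit a [fit_global()] result with a non-empty ensemble.
#' @param schedule protocol to simulate.
#' @param t_span_h simulation window.
#' @param observables observable kinds to envelope.
#' @param grid_min output resolution.
#' @param max_members cap on ensemble members simulated (uniformly
#'   thinned), to bound runtime.
#' @return data.frame with `time_h`, `observable`, `lower`, `upper`,
#'   `best`.
#' @export
ensemble_bands <- function(fit, schedule = diet_schedule(),
                           t_span_h = c(0, 24),
                           observables = c("plasma_glucose",
                                           "plasma_insulin"),
                           grid_min = 4, max_members = 50) {
  if (nrow(fit$ensemble) == 0) stop("empty ensemble: nothing to envelope")
  idx <- unique(round(seq(1, nrow(fit$ensemble),
                          length.out = min(max_members,
                                           nrow(fit$ensemble)))))
  sims <- lapply(idx, function(i) {
    p <- fit$best_params
    p[fit$free] <- fit$ensemble[i, ]
    simulate_twin(schedule, t_span_h, params = p, personal = fit$personal,
                  anthro = fit$anthro, grid_min = grid_min)
  })
  best_sim <- simulate_twin(schedule, t_span_h, params = fit$best_params,
                            personal = fit$personal, anthro = fit$anthro,
                            grid_min = grid_min)
  out <- list()
  for (kind in observables) {
    mats <- vapply(sims, function(s) observable_map(s, kind)$value,
                   numeric(length(sims[[1]]$time_h)))
    mats <- cbind(mats)
    out[[kind]] <- data.frame(
      time_h = sims[[1]]$time_h, observable = kind,
      lower = apply(mats, 1, min), upper = apply(mats, 1, max),
      best = observable_map(best_sim, kind)$value)
  }
  do.call(rbind, out)
}
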