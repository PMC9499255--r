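#' @title Synthetic study generator
#' @name study_fixtures
#' @description
#' Generates synthetic clinical-study datasets with the exact statistical
#' structure the estimation stack assumes: additive, independent,
#' normally distributed noise around a truth simulation, values stored as
#' replicate means with SEM = sigma/sqrt(n). With that construction the
#' weighted residuals of the truth parameters are standard normal, so the
#' truth cost is chi-squared distributed with one degree of freedom per
#' record — which is what the acceptance test assumes.
NULL

#' Specify a synthetic study
#'
#' @param params generating ("truth") general parameters.
#' @param personal truth person-specific parameters.
#' @param anthro subject [anthropometry()].
#' @param schedule study protocol.
#' @param t_span_h simulation window.
#' @param times_h sampling times (<= 30 per study keeps the fitting
#'   smoke tests fast).
#' @param observables observable kinds sampled at `times_h`.
#' @param sigma named per-observable sample SD (same units as the
#'   observable), or a single value recycled.
#' @param n replicate count per record.
#' @param init_glycogen initial glycogen of the protocol.
#' @param study_id identifier.
#' @param seed RNG seed recorded in the output.
#' @return Object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(params = default_params(),
                         personal = personal_defaults(),
                         anthro = anthropometry(),
                         schedule = diet_schedule(),
                         t_span_h = c(0, 12),
                         times_h = seq(0.5, 11.5, by = 1),
                         observables = c("plasma_glucose",
                                         "plasma_insulin"),
                         sigma = c(plasma_glucose = 0.4,
                                   plasma_insulin = 20),
                         n = 6, init_glycogen = 275,
                         study_id = "synthetic", seed = 1) {
  if (length(sigma) == 1) sigma <- stats::setNames(
    rep(sigma, length(observables)), observables)
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (n < 1) stop("n must be >= 1")
  structure(list(params = params, personal = personal, anthro = anthro,
                 schedule = schedule, t_span_h = t_span_h,
                 times_h = times_h, observables = observables,
                 sigma = sigma, n = n, init_glycogen = init_glycogen,
                 study_id = study_id, seed = seed),
            class = "fixture_spec")
}

#' Generate a synthetic study dataset
#'
#' Simulates the truth model over the protocol, samples each observable
#' at the specified times, adds independent normal noise per replicate,
#' and stores the replicate mean with SEM = sigma/sqrt(n). The truth
#' parameters and the seed are attached for recovery testing.
#'
#' @param spec a [fixture_spec()].
#' @param population population tag stored in the dataset.
#' @return A [study_dataset()] with attributes `truth` (list with
#'   `params`, `personal`, `seed`) and the generating spec.
#' @export
#' @examples
#' ds <- generate_study(fixture_spec(times_h = c(1, 2, 4), seed = 42))
#' ds$records$sem  # sigma / sqrt(n) by construction
generate_study <- function(spec, population = "healthy") {
  stopifnot(inherits(spec, "fixture_spec"))
  sim <- simulate_twin(spec$schedule, spec$t_span_h, params = spec$params,
                       personal = spec$personal, anthro = spec$anthro,
                       init_glycogen = spec$init_glycogen)
  set.seed(spec$seed)
  recs <- list()
  for (kind in spec$observables) {
    truth <- .sim_at(sim, kind, spec$times_h)
    s <- spec$sigma[[kind]]
    reps <- matrix(stats::rnorm(length(truth) * spec$n, mean = truth,
                                sd = s),
                   nrow = length(truth))
    recs[[kind]] <- data.frame(
      time_h = spec$times_h, observable = kind,
      value = rowMeans(reps), sd = s, n = spec$n,
      is_calibration = FALSE)
  }
  ds <- study_dataset(do.call(rbind, recs), schedule = spec$schedule,
                      t_span_h = spec$t_span_h, population = population,
                      study_id = spec$study_id,
                      init_glycogen = spec$init_glycogen)
  attr(ds, "truth") <- list(params = spec$params,
                            personal = spec$personal, seed = spec$seed)
  attr(ds, "spec") <- spec
  ds
}

#' Write a fixture with its truth sidecar
#'
#' Writes the dataset CSV, the protocol YAML and a JSON sidecar holding
#' the truth parameters and seed.
#'
#' @param dataset a [generate_study()] result.
#' @param dir output directory.
#' @return Invisibly the three paths written.
#' @export
write_fixture <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, dataset$study_id)
  write_study(dataset, paste0(base, ".csv"))
  write_schedule(dataset$schedule, paste0(base, "_protocol.yaml"))
  truth <- attr(dataset, "truth")
  jsonlite::write_json(list(params = as.list(truth$params),
                            personal = as.list(truth$personal),
                            seed = truth$seed),
                       paste0(base, "_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(paste0(base, ".csv"), paste0(base, "_protocol.yaml"),
              paste0(base, "_truth.json")))
}
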