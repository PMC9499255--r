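# Shared, lazily computed simulations so expensive protocols run once per
# test session.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

fast48_sim <- function() cached("fast48", simulate_twin(t_span_h = c(0, 48)))

meal_schedule <- function() diet_schedule(meal_event(1, carb_g = 87,
                                                     protein_g = 23))

meal_sim <- function() cached("meal",
  simulate_twin(meal_schedule(), t_span_h = c(0, 10)))

standard_day_sim <- function() cached("stdday",
  simulate_twin(standard_diet(2000, days = 2), t_span_h = c(0, 48),
                grid_min = 2))

t2d_fast_sim <- function() cached("t2dfast",
  simulate_twin(t_span_h = c(0, 48),
                anthro = anthropometry("male", 80, 1.80, diabetes = TRUE)))

optt_result <- function() cached("optt",
  run_optt_fast_optt(digital_twin(anthropometry("male", 80, 1.80))))

small_fixture_spec <- function(seed = 7) {
  fixture_spec(
    schedule = diet_schedule(meal_event(1, carb_g = 60, protein_g = 20)),
    t_span_h = c(0, 10), times_h = seq(0.5, 9.5, by = 1), seed = seed)
}

small_fixture <- function(seed = 7) generate_study(small_fixture_spec(seed))
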