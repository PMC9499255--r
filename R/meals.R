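#' Meal events and diet schedules
#'
#' A meal event is a timed macronutrient input: start time (hours from
#' protocol start), ingestion duration (minutes), grams of carbohydrate,
#' protein and fat, and the Atwater energy (4 kcal/g carbohydrate and
#' protein, 9 kcal/g fat). A diet schedule is an ordered,
#' non-overlapping collection of meal events with a scheme tag.
#'
#' @name meals
NULL

.ATWATER <- c(carb = 4, protein = 4, fat = 9)

#' Construct a meal event
#'
#' @param start_h meal start, hours from protocol start.
#' @param carb_g,protein_g,fat_g macronutrient masses in grams (>= 0).
#' @param duration_min ingestion duration in minutes (> 0); the meal is a
#'   square pulse of constant ingestion rate over this window.
#' @param kcal optional energy; when given it must close with the Atwater
#'   factors to within 1 kcal.
#' @return A one-row data.frame of class `"meal_event"` with columns
#'   `start_h`, `duration_min`, `carb_g`, `protein_g`, `fat_g`, `kcal`.
#' @export
#' @examples
#' meal_event(1, carb_g = 87, protein_g = 23)
meal_event <- function(start_h, carb_g = 0, protein_g = 0, fat_g = 0,
                       duration_min = 15, kcal = NULL) {
  if (any(c(carb_g, protein_g, fat_g) < 0)) stop("grams must be >= 0")
  if (duration_min <= 0) stop("duration_min must be > 0")
  e <- sum(.ATWATER * c(carb_g, protein_g, fat_g))
  if (!is.null(kcal) && abs(kcal - e) > 1)
    stop(sprintf("kcal (%.1f) does not close with Atwater energy (%.1f)",
                 kcal, e))
  out <- data.frame(start_h = start_h, duration_min = duration_min,
                    carb_g = carb_g, protein_g = protein_g, fat_g = fat_g,
                    kcal = e)
  class(out) <- c("meal_event", "data.frame")
  out
}

#' Complete a meal from its energy and carbohydrate/protein content
#'
#' Fat is inferred from the Atwater closure:
#' `fat_g = (kcal - 4 carb_g - 4 protein_g) / 9`.
#'
#' @inheritParams meal_event
#' @param kcal total meal energy (must be at least the carbohydrate plus
#'   protein energy).
#' @return A [meal_event()].
#' @export
#' @examples
#' meal_from_energy(940, carb_g = 81, protein_g = 41, start_h = 1)
meal_from_energy <- function(kcal, carb_g, protein_g, start_h = 0,
                             duration_min = 15) {
  fat_g <- (kcal - 4 * carb_g - 4 * protein_g) / 9
  if (fat_g < -1e-9)
    stop("kcal below the carbohydrate + protein energy: implied fat < 0")
  meal_event(start_h, carb_g = carb_g, protein_g = protein_g,
             fat_g = max(fat_g, 0), duration_min = duration_min)
}

#' Construct a diet schedule from meal events
#'
#' @param ... [meal_event()] objects (or data.frames with the same
#'   columns).
#' @param scheme tag: one of `"IF"`, `"5:2"`, `"SFM"`, `"HCLF"`, `"LCHF"`,
#'   `"custom"`.
#' @return data.frame of class `"diet_schedule"`, ordered by start time.
#' @export
diet_schedule <- function(..., scheme = "custom") {
  meals <- list(...)
  if (length(meals) == 1 && is.data.frame(meals[[1]]) &&
      !inherits(meals[[1]], "meal_event")) meals <- list(meals[[1]])
  df <- do.call(rbind, lapply(meals, as.data.frame))
  if (is.null(df) || nrow(df) == 0) {
    df <- data.frame(start_h = numeric(), duration_min = numeric(),
                     carb_g = numeric(), protein_g = numeric(),
                     fat_g = numeric(), kcal = numeric())
  }
  df <- df[order(df$start_h), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 1) {
    ends <- df$start_h + df$duration_min / 60
    if (any(df$start_h[-1] < ends[-nrow(df)] - 1e-9))
      stop("meals overlap in time")
  }
  structure(df, class = c("diet_schedule", "data.frame"), scheme = scheme)
}

#' @export
print.diet_schedule <- function(x, ...) {
  cat(sprintf("<diet schedule> scheme %s, %d meals, %.0f kcal total\n",
              attr(x, "scheme"), nrow(x), sum(x$kcal)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Build one of the named diet schemes
#'
#' Builds a multi-day schedule for the five named schemes at a daily
#' energy target. IF takes two meals (12:00, 20:00); SFM three smaller
#' meals (08:00, 13:00, 19:00); 5:2 runs five normal days at 2560
#' kcal/day (three meals) and two restricted days at 600 kcal/day (two
#' meals), whose weekly mean is the 2000 kcal/day target; HCLF uses a
#' 60/25/15 carbohydrate/protein/fat energy split; LCHF halves the HCLF
#' carbohydrate energy, keeps the protein share, and moves the freed
#' energy to fat (30/25/45). All other schemes use the standard 45/27/27
#' split (normalised to sum to 1).
#'
#' @param scheme `"IF"`, `"5:2"`, `"SFM"`, `"HCLF"` or `"LCHF"`.
#' @param daily_kcal daily energy target; for 5:2 this is the weekly mean
#'   (normal/restricted days are scaled as 1.28x / 0.3x the target).
#' @param days protocol length in days.
#' @param macro_split optional energy split `c(carb=, protein=, fat=)` in
#'   percent; overrides the scheme default. Normalised to sum to 1.
#' @param duration_min ingestion duration per meal.
#' @return A [diet_schedule()] spanning `days` days.
#' @export
#' @examples
#' wk <- build_diet("5:2", daily_kcal = 2000, days = 7)
#' weekly_mean_kcal(wk)  # 2000
build_diet <- function(scheme = c("IF", "5:2", "SFM", "HCLF", "LCHF"),
                       daily_kcal = 2000, days = 7, macro_split = NULL,
                       duration_min = 15) {
  scheme <- match.arg(scheme)
  split <- if (!is.null(macro_split)) macro_split else switch(scheme,
    HCLF = c(carb = 60, protein = 25, fat = 15),
    LCHF = c(carb = 30, protein = 25, fat = 45),
    c(carb = 45, protein = 27, fat = 27))
  split <- split / sum(split)

  day_plan <- function(day_kcal, times) {
    kcal <- rep(day_kcal / length(times), length(times))
    mapply(function(t0, k) {
      meal_event(t0, carb_g = k * split[["carb"]] / 4,
                 protein_g = k * split[["protein"]] / 4,
                 fat_g = k * split[["fat"]] / 9,
                 duration_min = duration_min)
    }, times, kcal, SIMPLIFY = FALSE)
  }

  meals <- list()
  for (d in seq_len(days) - 1) {
    plan <- switch(scheme,
      "IF"  = day_plan(daily_kcal, d * 24 + c(12, 20)),
      "SFM" = day_plan(daily_kcal, d * 24 + c(8, 13, 19)),
      "5:2" = if (d %% 7 < 5) {
        day_plan(daily_kcal * 1.28, d * 24 + c(8, 13, 19))
      } else {
        day_plan(daily_kcal * 0.30, d * 24 + c(12, 19))
      },
      "HCLF" = day_plan(daily_kcal, d * 24 + c(8, 13, 19)),
      "LCHF" = day_plan(daily_kcal, d * 24 + c(8, 13, 19)))
    meals <- c(meals, plan)
  }
  sched <- do.call(diet_schedule, c(meals, list(scheme = scheme)))
  sched
}

#' Standard mixed-diet day(s)
#'
#' Three meals per day (08:00, 13:00, 19:00) at the standard 45/27/27
#' split; used as the lead-in week of the diet-comparison protocol and as
#' the default "standard diet".
#'
#' @param daily_kcal daily energy.
#' @param days number of days.
#' @param offset_h shift of the whole schedule in hours.
#' @return A [diet_schedule()].
#' @export
standard_diet <- function(daily_kcal = 2000, days = 1, offset_h = 0) {
  split <- c(carb = 45, protein = 27, fat = 27) / 99
  meals <- list()
  for (d in seq_len(days) - 1) {
    for (t0 in d * 24 + c(8, 13, 19)) {
      k <- daily_kcal / 3
      meals <- c(meals, list(meal_event(offset_h + t0,
        carb_g = k * split[["carb"]] / 4,
        protein_g = k * split[["protein"]] / 4,
        fat_g = k * split[["fat"]] / 9)))
    }
  }
  do.call(diet_schedule, c(meals, list(scheme = "custom")))
}

#' Concatenate diet schedules
#' @param ... `diet_schedule` objects, already expressed on a common time
#'   axis.
#' @param scheme tag for the result.
#' @return A [diet_schedule()].
#' @export
concat_schedules <- function(..., scheme = "custom") {
  parts <- list(...)
  df <- do.call(rbind, lapply(parts, as.data.frame))
  do.call(diet_schedule, c(split(df, seq_len(nrow(df))),
                           list(scheme = scheme)))
}

#' Shift a schedule in time
#' @param schedule a [diet_schedule()].
#' @param by_h hours to add to every meal start.
#' @return A [diet_schedule()].
#' @export
shift_schedule <- function(schedule, by_h) {
  df <- as.data.frame(schedule)
  df$start_h <- df$start_h + by_h
  do.call(diet_schedule, c(split(df, seq_len(nrow(df))),
                           list(scheme = attr(schedule, "scheme"))))
}

#' Mean daily energy of a schedule
#' @param schedule a [diet_schedule()].
#' @param days horizon in days; defaults to the span implied by the last
#'   meal (rounded up to whole days).
#' @return kcal/day averaged over the horizon.
#' @export
weekly_mean_kcal <- function(schedule, days = NULL) {
  if (nrow(schedule) == 0) return(0)
  if (is.null(days)) days <- ceiling(max(schedule$start_h + 1e-9) / 24)
  sum(schedule$kcal) / days
}

#' Convert a diet schedule to the model input signal
#'
#' The input signal u(t) gives the ingestion rate of each macronutrient in
#' g/min as square pulses: rate = grams / duration over each meal window,
#' zero elsewhere. The integral of each rate over a meal equals that
#' meal's grams exactly.
#'
#' @param schedule a [diet_schedule()].
#' @return List of class `"model_input"` with `rate(t_min)` returning
#'   `c(carb, protein, fat)` g/min at internal time t (minutes), and
#'   `breaks_min`, the sorted meal start/end times used as integration
#'   boundaries.
#' @export
to_input_signal <- function(schedule) {
  df <- as.data.frame(schedule)
  s <- df$start_h * 60
  e <- s + df$duration_min
  rc <- ifelse(df$duration_min > 0, df$carb_g / df$duration_min, 0)
  rp <- ifelse(df$duration_min > 0, df$protein_g / df$duration_min, 0)
  rf <- ifelse(df$duration_min > 0, df$fat_g / df$duration_min, 0)
  rate <- function(t_min) {
    on <- t_min >= s & t_min < e
    c(carb = sum(rc[on]), protein = sum(rp[on]), fat = sum(rf[on]))
  }
  structure(list(rate = rate,
                 breaks_min = sort(unique(c(s, e))),
                 schedule = df),
            class = "model_input")
}

#' Read / write diet schedules as YAML
#'
#' The YAML layout is a list of meals with keys `start_h`, `duration_min`,
#' `carb_g`, `protein_g`, `fat_g`, and an optional top-level `scheme`.
#'
#' @param path file path.
#' @return [read_schedule()] returns a [diet_schedule()];
#'   [write_schedule()] returns `path` invisibly.
#' @export
read_schedule <- function(path) {
  y <- yaml::read_yaml(path)
  scheme <- if (!is.null(y$scheme)) y$scheme else "custom"
  meals <- lapply(y$meals, function(m) {
    meal_event(m$start_h,
               carb_g = if (is.null(m$carb_g)) 0 else m$carb_g,
               protein_g = if (is.null(m$protein_g)) 0 else m$protein_g,
               fat_g = if (is.null(m$fat_g)) 0 else m$fat_g,
               duration_min = if (is.null(m$duration_min)) 15 else m$duration_min)
  })
  do.call(diet_schedule, c(meals, list(scheme = scheme)))
}

#' @rdname read_schedule
#' @param schedule a [diet_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  df <- as.data.frame(schedule)
  y <- list(scheme = attr(schedule, "scheme"),
            meals = lapply(seq_len(nrow(df)), function(i) as.list(df[i, ])))
  yaml::write_yaml(y, path)
  invisible(path)
}
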