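#' Subject anthropometry
#'
#' Bundles the subject descriptors that drive the first calibration
#' category: sex, weight, height, age (informational only) and diabetes
#' status. Diabetes selects the general-parameter variant; sex, weight and
#' height scale the blood volumes.
#'
#' @param sex `"male"` or `"female"`.
#' @param weight_kg body weight in kg (30-250).
#' @param height_m height in metres (1.2-2.2).
#' @param age_y age in years; informational.
#' @param diabetes logical; `TRUE` selects the T2D parameter variant.
#' @return An object of class `"anthropometry"`.
#' @export
#' @examples
#' anthropometry("male", 80, 1.80)
anthropometry <- function(sex = c("male", "female"), weight_kg = 80,
                          height_m = 1.80, age_y = NA_real_,
                          diabetes = FALSE) {
  sex <- match.arg(sex)
  if (!is.finite(weight_kg) || weight_kg < 30 || weight_kg > 250)
    stop("weight_kg must lie in [30, 250]")
  if (!is.finite(height_m) || height_m < 1.2 || height_m > 2.2)
    stop("height_m must lie in [1.2, 2.2]")
  structure(list(sex = sex, weight_kg = weight_kg, height_m = height_m,
                 age_y = age_y, diabetes = isTRUE(diabetes)),
            class = "anthropometry")
}

#' @export
print.anthropometry <- function(x, ...) {
  cat(sprintf("<anthropometry> %s, %.1f kg, %.2f m, %s\n", x$sex,
              x$weight_kg, x$height_m,
              if (x$diabetes) "T2D" else "healthy"))
  invisible(x)
}

#' Total and liver blood volume from anthropometry
#'
#' Total blood volume follows the classic sex-specific height-cubed/weight
#' regression equations (Nadler): male `0.3669 h^3 + 0.03219 w + 0.6041`,
#' female `0.3561 h^3 + 0.03308 w + 0.1833` (h in m, w in kg, volume in
#' L). A free adjustment factor bounded to +-30% of the equation value
#' absorbs individual deviation; liver blood is fixed at 13% of the total.
#'
#' @param anthro an [anthropometry()] object.
#' @param adjustment multiplicative factor in `[0.7, 1.3]`.
#' @return List of class `"blood_volumes"` with `total_L`, `liver_L`,
#'   `adjustment`.
#' @export
#' @examples
#' blood_volumes(anthropometry("male", 80, 1.78))
blood_volumes <- function(anthro, adjustment = 1.0) {
  stopifnot(inherits(anthro, "anthropometry"))
  if (!is.finite(adjustment) || adjustment < 0.7 || adjustment > 1.3)
    stop("blood-volume adjustment must lie within +-30% (0.7-1.3)")
  h <- anthro$height_m; w <- anthro$weight_kg
  total <- if (anthro$sex == "male") {
    0.3669 * h^3 + 0.03219 * w + 0.6041
  } else {
    0.3561 * h^3 + 0.03308 * w + 0.1833
  }
  total <- total * adjustment
  structure(list(total_L = total, liver_L = 0.13 * total,
                 adjustment = adjustment),
            class = "blood_volumes")
}

#' @export
print.blood_volumes <- function(x, ...) {
  cat(sprintf("<blood volumes> total %.2f L, liver %.2f L (13%%), adj %.2f\n",
              x$total_L, x$liver_L, x$adjustment))
  invisible(x)
}
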