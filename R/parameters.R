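#' @title Model parameter sets
#' @name parameters
#' @description
#' The model carries 57 general parameters (rate constants, Michaelis
#' constants, inhibition midpoints, distribution volumes) that are shared
#' within a population, in two variants (`"healthy"` and `"t2d"`), plus 5
#' person-specific parameters. General parameters carry per-parameter
#' lower/upper optimisation bounds; person-specific modifiers are strictly
#' positive with 1 meaning "population default".
#'
#' Unit conventions: glucose mmol/L, insulin pmol/L, hepatic glycogen
#' mmol/L of liver volume, Vmax-type fluxes umol/kg/min, first-order rates
#' 1/min, time in hours at the interface and minutes internally.
NULL

# One row per general parameter: default (healthy), default (t2d), lower,
# upper bound, unit. Bounds are the optimisation restriction window.
.param_table <- function() {
  # name, healthy, t2d, lo_f, hi_f (bounds as multiples of healthy default
  # unless given absolutely below)
  tab <- rbind(
    # --- gut absorption -------------------------------------------------
    c("k_gastric_carb",  0.022, 0.022),  # gastric emptying, carbohydrate [1/min]
    c("k_abs_carb",      0.022, 0.022),  # intestinal glucose absorption [1/min]
    c("k_gastric_prot",  0.024, 0.024),  # gastric emptying, protein [1/min]
    c("k_abs_prot",      0.032, 0.032),  # intestinal amino-acid absorption [1/min]
    c("aa_glc_equiv",    0.60,  0.60),   # glucose-equivalent yield of protein [g/g]
    # --- distribution ---------------------------------------------------
    c("v_glc_plasma",    0.12,  0.12),   # plasma glucose space [L/kg]
    c("v_glc_tissue",    0.10,  0.10),   # interstitial glucose space [L/kg]
    c("k_transfer",      0.15,  0.15),   # plasma<->tissue glucose exchange [1/min]
    c("liver_volume",    0.022, 0.022),  # liver volume [L/kg]
    c("kidney_volume",   0.004, 0.004),  # kidney volume [L/kg]
    # --- glucose uptake -------------------------------------------------
    c("vm_brain",        5.40,  5.40),   # brain uptake Vmax [umol/kg/min]
    c("vm_muscle",      42.8,  42.8),    # muscle uptake Vmax [umol/kg/min]
    c("km_muscle",       5.00,  5.00),   # muscle uptake Km [mmol/L]
    c("i50_muscle",    250,   320),      # insulin midpoint, muscle transport [pmol/L]
    c("f0_muscle",       0.06,  0.06),   # insulin-independent muscle fraction [-]
    c("vm_other",        3.57,  3.57),   # other-tissue uptake Vmax [umol/kg/min]
    c("vm_kidney_upt",   1.65,  1.65),   # renal uptake Vmax [umol/kg/min]
    c("km_kidney_upt",   6.00,  6.00),   # renal uptake Km [mmol/L]
    c("vm_hgu",         43.0,  43.0),    # hepatic glucose uptake Vmax [umol/kg/min]
    c("km_hgu",         10.0,  14.0),    # hepatic uptake glucose midpoint [mmol/L]
    c("i50_hgu",       250,   300),      # insulin midpoint, hepatic uptake [pmol/L]
    # --- insulin --------------------------------------------------------
    c("sec_rate",       20.0,  14.0),    # nominal secretion capacity [pmol/kg/min]
    c("g50_secretion",   7.5,  10.0),    # glucose midpoint of secretion [mmol/L]
    c("h_secretion",     5.0,   4.0),    # secretion Hill exponent [-]
    c("f0_secretion",    0.05,  0.05),   # glucose-independent secretion floor [-]
    c("inc_max",         2.00,  2.00),   # incretin amplification of secretion [-]
    c("inc_50",        150,   150),      # gut glucose midpoint of amplification [mmol]
    c("cl_hep_insulin",  1.08,  1.08),   # hepatic insulin degradation [1/min]
    c("cl_per_insulin",  0.242, 0.242),  # peripheral insulin degradation [1/min]
    c("hep_plasma_flow", 0.90,  0.90),   # liver-compartment plasma flow [L/min]
    # --- liver glycogen and gluconeogenesis -----------------------------
    c("vm_glycolysis_l", 6.98,  2.00),   # glycogenolysis Vmax [umol/kg/min]
    c("km_glycogen",   150.0, 110.0),    # glycogenolysis store midpoint [mmol/L]
    c("i50_glycolysis", 300,   450),     # insulin inhibition midpoint, glycogenolysis [pmol/L]
    c("h_glycolysis",    2.0,   2.0),    # Hill exponent of that inhibition [-]
    c("vm_gng_liver",   22.0,  24.0),    # hepatic gluconeogenesis Vmax [umol/kg/min]
    c("km_gng",         10.0,  10.0),    # gluconeogenic substrate Km [mmol]
    c("i50_gng",       200,   400),      # insulin inhibition midpoint, GNG [pmol/L]
    c("h_gng",           1.5,   1.5),    # Hill exponent of GNG inhibition [-]
    c("k_glycsyn",       0.20,  0.06),   # glycogen synthesis from hepatic G6P [1/min]
    c("gly_max",       360,   330),      # glycogen storage capacity [mmol/L]
    c("k_spill",         0.08,  0.08),   # hepatic G6P oxidation spill [1/min]
    c("gly50_routing",  80.0,  80.0),    # glycogen midpoint of amino-acid routing [mmol/L]
    c("h_routing",       2.0,   2.0),    # routing Hill exponent [-]
    # --- protein / muscle / substrate -----------------------------------
    c("k_cat_aa",        0.080, 0.080),  # hepatic amino-acid catabolism [1/min]
    c("k_ana_aa",        0.020, 0.018),  # hepatic amino-acid anabolic export [1/min]
    c("vm_proteolysis",  7.0,  11.0),    # muscle proteolysis Vmax [umol/kg/min]
    c("gly50_proteolysis", 250, 250),    # glycogen suppression midpoint, proteolysis [mmol/L]
    c("h_proteolysis",   1.0,   1.0),    # proteolysis suppression exponent [-]
    c("f_cori",          0.75,  0.95),   # peripheral uptake recycled as pyruvate [-]
    c("k_pyr_ox",        0.006, 0.006),  # pyruvate oxidation into TCA pool [1/min]
    c("k_tca",           0.050, 0.050),  # TCA pool turnover [1/min]
    c("protein_reserve",10000, 10000),   # labile muscle protein [mmol glc-eq]
    # --- kidney glucose production --------------------------------------
    c("vm_gng_kidney",   2.40,  2.60),   # renal gluconeogenesis Vmax [umol/kg/min]
    c("i50_gng_kidney",200,   400),      # insulin inhibition midpoint, renal GNG [pmol/L]
    c("vm_glycolysis_k", 0.30,  0.30),   # renal glycogenolysis Vmax [umol/kg/min]
    c("km_glycogen_k",   5.0,   5.0),    # renal glycogen midpoint [mmol/L]
    c("k_glyksyn",       2.0,   1.6)     # renal glycogen synthesis rate [umol/kg/min per (mmol/L)]
  )
  data.frame(
    name = tab[, 1],
    healthy = as.numeric(tab[, 2]),
    t2d = as.numeric(tab[, 3]),
    stringsAsFactors = FALSE
  )
}

#' Default general parameter set
#'
#' Returns the named vector of the 57 general parameters for a population
#' variant. The two variants were tuned separately: the diabetic variant
#' has reduced secretory capacity, right-shifted insulin-inhibition and
#' insulin-activation midpoints (insulin resistance), a larger
#' gluconeogenic capacity and a smaller glycogenolytic/storage capacity.
#'
#' @param variant `"healthy"` or `"t2d"`.
#' @return Named numeric vector of length 57 with attribute `variant`.
#' @export
#' @examples
#' p <- default_params()
#' length(p)  # 57
default_params <- function(variant = c("healthy", "t2d")) {
  variant <- match.arg(variant)
  tab <- .param_table()
  p <- tab[[variant]]
  names(p) <- tab$name
  attr(p, "variant") <- variant
  p
}

#' Optimisation bounds for the general parameters
#'
#' Per-parameter lower/upper restriction windows used by [fit_global()].
#' Rate constants and capacities are allowed a factor-of-three window
#' around the variant default; Hill exponents, yields and fractions get a
#' narrower physiological window so the optimiser cannot leave the regime
#' in which the qualitative constraints are meaningful.
#'
#' @inheritParams default_params
#' @return data.frame with columns `name`, `lower`, `upper`, `default`.
#' @export
param_bounds <- function(variant = c("healthy", "t2d")) {
  variant <- match.arg(variant)
  p <- default_params(variant)
  narrow <- c("aa_glc_equiv", "f0_muscle", "f0_secretion",
              "f_cori", "h_secretion", "h_glycolysis", "h_gng", "h_routing",
              "h_proteolysis", "v_glc_plasma", "v_glc_tissue",
              "liver_volume", "kidney_volume")
  lo <- ifelse(names(p) %in% narrow, p / 1.5, p / 3)
  hi <- ifelse(names(p) %in% narrow, p * 1.5, p * 3)
  data.frame(name = names(p), lower = unname(lo), upper = unname(hi),
             default = unname(p), stringsAsFactors = FALSE)
}

#' Default person-specific parameters
#'
#' The five person-specific parameters: basal plasma glucose (mmol/L),
#' basal plasma insulin (pmol/L), and three multiplicative modifiers for
#' insulin production, insulin clearance and insulin resistance (1 =
#' population default).
#'
#' @inheritParams default_params
#' @return Named numeric vector of length 5.
#' @export
personal_defaults <- function(variant = c("healthy", "t2d")) {
  variant <- match.arg(variant)
  if (variant == "healthy") {
    c(basal_glucose = 5.0, basal_insulin = 40,
      prod_mod = 1, clear_mod = 1, resist_mod = 1)
  } else {
    c(basal_glucose = 9.0, basal_insulin = 60,
      prod_mod = 1, clear_mod = 1, resist_mod = 1)
  }
}

#' Validate a general parameter vector against its bounds
#'
#' @param params named numeric vector as from [default_params()].
#' @param bounds data.frame as from [param_bounds()]; defaults to the
#'   bounds of the vector's own variant.
#' @return Invisibly `TRUE`; errors if a parameter is missing, non-finite,
#'   non-positive or outside its bounds.
#' @export
validate_params <- function(params, bounds = NULL) {
  variant <- attr(params, "variant")
  if (is.null(bounds))
    bounds <- param_bounds(if (is.null(variant)) "healthy" else variant)
  miss <- setdiff(bounds$name, names(params))
  if (length(miss))
    stop("missing general parameters: ", paste(miss, collapse = ", "))
  v <- params[bounds$name]
  if (any(!is.finite(v)) || any(v <= 0))
    stop("general parameters must be finite and positive")
  bad <- bounds$name[v < bounds$lower - 1e-12 | v > bounds$upper + 1e-12]
  if (length(bad))
    stop("parameters outside bounds: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Validate person-specific parameters
#' @param personal named numeric vector of the five person-specific
#'   parameters.
#' @return Invisibly `TRUE`; errors on violations.
#' @export
validate_personal <- function(personal) {
  need <- names(personal_defaults())
  miss <- setdiff(need, names(personal))
  if (length(miss))
    stop("missing person-specific parameters: ", paste(miss, collapse = ", "))
  if (any(!is.finite(personal[need])) || any(personal[need] <= 0))
    stop("person-specific parameters must be finite and strictly positive")
  g <- personal[["basal_glucose"]]; i <- personal[["basal_insulin"]]
  if (g < 3 || g > 15)
    stop("basal glucose must lie in [3, 15] mmol/L")
  if (i < 5 || i > 500)
    stop("basal insulin must lie in [5, 500] pmol/L")
  invisible(TRUE)
}
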