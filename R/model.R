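#' @title Whole-body metabolic model core
#' @name model_core
#' @description
#' A multi-timescale ODE system for whole-body glucose, insulin, glycogen
#' and protein metabolism. States cover the gut (stomach and intestinal
#' carbohydrate and protein pools), the circulation (plasma and
#' interstitial glucose, plasma and liver-compartment insulin), the liver
#' (glycogen, a glucose-6-phosphate pool, amino-acid, pyruvate and
#' TCA-intermediate pools), the kidney (glycogen) and muscle (labile
#' protein reserve), plus two bookkeeping integrals of absorbed
#' carbohydrate and protein.
#'
#' Mechanisms implemented: insulin-dependent glucose uptake (muscle,
#' liver), insulin-independent uptake (brain, kidney, other tissues),
#' glucose-dependent insulin secretion with first-pass hepatic plus
#' peripheral clearance, hepatic and renal glucose production from finite
#' glycogen stores and from gluconeogenesis, Hill-type insulin inhibition
#' of both gluconeogenesis and glycogenolysis, energy-status-controlled
#' routing of amino acids between catabolic (pyruvate/TCA) and anabolic
#' fates, muscle proteolysis feeding pyruvate during fasting, and
#' Cori-cycle recycling of peripheral glucose uptake into gluconeogenic
#' substrate. Ingested fat is tracked for energy bookkeeping only and is
#' metabolically inert.
#'
#' Internal time is minutes; the user interface is in hours.
NULL

.GLC_MMOL_PER_G <- 1000 / 180.16

.state_names <- c(
  "stomach_carb",     # g carbohydrate in stomach
  "gut_glucose",      # mmol glucose in intestine
  "stomach_protein",  # g protein in stomach
  "gut_aa",           # mmol (glucose-equivalent) amino acids in intestine
  "glc_plasma",       # mmol/L plasma glucose
  "glc_tissue",       # mmol/L interstitial glucose
  "ins_plasma",       # pmol/L plasma insulin
  "ins_liver",        # pmol/L liver-compartment insulin
  "glycogen_liver",   # mmol/L liver volume
  "g6p_liver",        # mmol hepatic glucose-6-phosphate pool
  "aa_liver",         # mmol (glc-eq) hepatic amino-acid pool
  "pyruvate_liver",   # mmol (glc-eq) gluconeogenic substrate pool
  "tca_liver",        # mmol TCA-intermediate pool
  "glycogen_kidney",  # mmol/L kidney volume
  "protein_muscle",   # mmol (glc-eq) labile muscle protein
  "carb_absorbed",    # g, cumulative carbohydrate appearance in plasma
  "protein_absorbed"  # g, cumulative protein appearance in liver
)

.hill_inh <- function(x, x50, h) 1 / (1 + (x / x50)^h)

# All glucose fluxes in mmol/min, insulin fluxes in pmol/min.
.model_fluxes <- function(t_min, y, pc) {
  p <- pc$p
  y <- pmax(unname(y), 0)
  Gp <- y[5L]; Gt <- y[6L]; Ip <- y[7L]; Il <- y[8L]
  gly <- y[9L]; g6p <- y[10L]; aal <- y[11L]; pyr <- y[12L]
  glyk <- y[14L]; protm <- y[15L]
  kf <- pc$kf; r <- pc$resist

  u <- pc$input$rate(t_min)

  # gut transport
  ra_glc <- p[["k_abs_carb"]] * y[2L]
  ra_aa  <- p[["k_abs_prot"]] * y[4L]

  # uptakes
  u_brain <- p[["vm_brain"]] * kf * Gp / (1 + Gp)
  a_mus <- Ip^2 / ((p[["i50_muscle"]] * r)^2 + Ip^2)
  u_mus <- p[["vm_muscle"]] * kf * Gt / (p[["km_muscle"]] + Gt) *
    (p[["f0_muscle"]] + (1 - p[["f0_muscle"]]) * a_mus)
  u_oth <- p[["vm_other"]] * kf * Gt / (5 + Gt)
  u_kid <- p[["vm_kidney_upt"]] * kf * Gp / (p[["km_kidney_upt"]] + Gp)
  a_hgu <- Il^2 / ((p[["i50_hgu"]] * r)^2 + Il^2)
  u_liv <- p[["vm_hgu"]] * kf * Gp^2 / (p[["km_hgu"]]^2 + Gp^2) *
    (0.03 + 0.97 * a_hgu)

  transfer <- p[["k_transfer"]] * (Gp - Gt) * pc$Vp

  # hepatic glycogen
  cap <- max(0, 1 - (gly / p[["gly_max"]])^4)
  gs <- p[["k_glycsyn"]] * g6p * cap
  spill <- p[["k_spill"]] * g6p
  gl_l <- pc$egp_anchor * p[["vm_glycolysis_l"]] * kf *
    gly^2 / (p[["km_glycogen"]]^2 + gly^2) *
    .hill_inh(Il, p[["i50_glycolysis"]] * r, p[["h_glycolysis"]])

  # gluconeogenesis (liver + kidney) from the common substrate pool
  satp <- pyr / (p[["km_gng"]] + pyr)
  gng_l <- pc$egp_anchor * p[["vm_gng_liver"]] * kf * satp *
    .hill_inh(Il, p[["i50_gng"]] * r, p[["h_gng"]])
  gng_k <- pc$egp_anchor * p[["vm_gng_kidney"]] * kf * satp *
    .hill_inh(Ip, p[["i50_gng_kidney"]] * r, p[["h_gng"]])

  # renal glycogen
  capk <- max(0, 1 - (glyk / 60)^2)
  gsk <- p[["k_glyksyn"]] * kf * Gp * a_mus * capk
  gl_k <- pc$egp_anchor * p[["vm_glycolysis_k"]] * kf *
    glyk / (p[["km_glycogen_k"]] + glyk) *
    .hill_inh(Ip, p[["i50_glycolysis"]] * r, p[["h_glycolysis"]])

  # amino-acid routing: energy status (glycogen) selects catabolic vs
  # anabolic fate of the hepatic amino-acid pool
  fcat <- .hill_inh(gly, p[["gly50_routing"]], p[["h_routing"]])
  aa_cat <- p[["k_cat_aa"]] * aal * fcat
  aa_ana <- p[["k_ana_aa"]] * aal * (1 - fcat)

  # muscle protein breakdown follows whole-body energy status (the
  # glycogen store), rising smoothly as the store empties
  proteolysis <- p[["vm_proteolysis"]] * kf * (protm / pc$prot_m0) *
    .hill_inh(gly, p[["gly50_proteolysis"]], p[["h_proteolysis"]])
  cori <- p[["f_cori"]] * (u_mus + u_oth)
  pyr_ox <- p[["k_pyr_ox"]] * pyr
  tca_out <- p[["k_tca"]] * y[13L]

  # insulin: glucose-driven secretion with a glucose-independent floor and
  # an incretin-type amplification by intestinal glucose content. The
  # production modifier scales the dynamic increment above the anchored
  # basal rate, so basal closure is preserved while responsiveness varies.
  sigma <- p[["f0_secretion"]] + (1 - p[["f0_secretion"]]) *
    Gp^p[["h_secretion"]] /
    (p[["g50_secretion"]]^p[["h_secretion"]] + Gp^p[["h_secretion"]])
  amp <- 1 + p[["inc_max"]] * y[2L] / (p[["inc_50"]] + y[2L])
  secretion <- p[["sec_rate"]] * pc$BW * pc$sec_anchor *
    max(pc$sigma_b + pc$prod * (sigma * amp - pc$sigma_b), 0)
  cl_liver <- p[["cl_hep_insulin"]] * pc$clear * Il * pc$Vlb
  cl_periph <- p[["cl_per_insulin"]] * pc$clear * Ip * pc$Vpb
  i_flow <- pc$flow * (Ip - Il)

  c(ra_glucose = ra_glc, ra_aa = ra_aa,
    u_brain = u_brain, u_muscle = u_mus, u_liver = u_liv,
    u_kidney = u_kid + gsk, u_other = u_oth, transfer = transfer,
    glycogenolysis_liver = gl_l, gng_liver = gng_l,
    glycogenolysis_kidney = gl_k, gng_kidney = gng_k,
    glycogen_synthesis = gs, glycogen_synthesis_kidney = gsk,
    g6p_spill = spill, aa_catabolism = aa_cat, aa_anabolism = aa_ana,
    proteolysis = proteolysis, cori = cori, pyr_oxidation = pyr_ox,
    tca_out = tca_out, ins_secretion = secretion,
    ins_clear_liver = cl_liver, ins_clear_periph = cl_periph,
    u_carb = u[["carb"]], u_prot = u[["protein"]], u_fat = u[["fat"]])
}

#' Model right-hand side
#'
#' The derivative function `dX/dt = f(X, t, q, u)` in the deSolve calling
#' convention (internal time in minutes). Exposed for use with external
#' integrators and for direct inspection of the rate laws.
#'
#' @param t_min internal time, minutes.
#' @param state named numeric state vector (see `model_context()$init`).
#' @param pc a model context from [model_context()].
#' @return `list(dstate)` as deSolve expects.
#' @export
metab_rhs <- function(t_min, state, pc) {
  if (any(!is.finite(state)))
    stop("non-finite state at t = ", t_min, " min: integration blow-up")
  f <- .model_fluxes(t_min, state, pc)
  p <- pc$p
  egp <- f[["glycogenolysis_liver"]] + f[["gng_liver"]] +
    f[["glycogenolysis_kidney"]] + f[["gng_kidney"]]
  d <- numeric(17L)
  d[1L] <- f[["u_carb"]] - p[["k_gastric_carb"]] * max(state[1L], 0)
  d[2L] <- p[["k_gastric_carb"]] * max(state[1L], 0) * .GLC_MMOL_PER_G -
    p[["k_abs_carb"]] * max(state[2L], 0)
  d[3L] <- f[["u_prot"]] - p[["k_gastric_prot"]] * max(state[3L], 0)
  d[4L] <- p[["k_gastric_prot"]] * max(state[3L], 0) *
    p[["aa_glc_equiv"]] * .GLC_MMOL_PER_G -
    p[["k_abs_prot"]] * max(state[4L], 0)
  d[5L] <- (f[["ra_glucose"]] + egp - f[["u_brain"]] - f[["u_kidney"]] -
              f[["u_liver"]] - f[["transfer"]]) / pc$Vp
  d[6L] <- (f[["transfer"]] - f[["u_muscle"]] - f[["u_other"]]) / pc$Vt
  d[7L] <- (pc$flow * (state[8L] - state[7L]) - f[["ins_clear_periph"]]) /
    pc$Vpb
  d[8L] <- (f[["ins_secretion"]] + pc$flow * (state[7L] - state[8L]) -
              f[["ins_clear_liver"]]) / pc$Vlb
  d[9L] <- (f[["glycogen_synthesis"]] - f[["glycogenolysis_liver"]]) / pc$Vl
  d[10L] <- f[["u_liver"]] - f[["glycogen_synthesis"]] - f[["g6p_spill"]]
  d[11L] <- f[["ra_aa"]] - f[["aa_catabolism"]] - f[["aa_anabolism"]]
  d[12L] <- f[["aa_catabolism"]] + f[["proteolysis"]] + f[["cori"]] -
    f[["gng_liver"]] - f[["gng_kidney"]] - f[["pyr_oxidation"]]
  d[13L] <- f[["pyr_oxidation"]] + f[["g6p_spill"]] - f[["tca_out"]]
  d[14L] <- (f[["glycogen_synthesis_kidney"]] -
               f[["glycogenolysis_kidney"]]) / pc$Vk
  d[15L] <- f[["aa_anabolism"]] - f[["proteolysis"]]
  d[16L] <- f[["ra_glucose"]] / .GLC_MMOL_PER_G
  d[17L] <- f[["ra_aa"]] / (p[["aa_glc_equiv"]] * .GLC_MMOL_PER_G)
  list(d)
}

#' Build a model context
#'
#' Assembles general and person-specific parameters, anthropometry and a
#' diet schedule into the internal context consumed by [metab_rhs()],
#' [steady_state()] and [simulate_twin()]. Two derived anchoring constants
#' close the basal state exactly: a secretion anchor makes the insulin
#' subsystem stationary at the person's basal glucose/insulin pair, and a
#' production anchor scales the four endogenous-glucose-production
#' capacities so that production balances total uptake at the basal state
#' with the reference glycogen level.
#'
#' @param params general parameters ([default_params()]); the variant is
#'   taken from `anthro$diabetes` when `params` is `NULL`.
#' @param personal person-specific parameters ([personal_defaults()]).
#' @param anthro an [anthropometry()] object.
#' @param schedule a [diet_schedule()].
#' @param init_glycogen reference hepatic glycogen (mmol/L of liver) at
#'   which the basal state is anchored; the fed default is 275.
#' @param blood_adjustment blood-volume adjustment factor, see
#'   [blood_volumes()].
#' @return List of class `"model_context"` with the derived constants and
#'   the basal initial state in `$init`.
#' @export
model_context <- function(params = NULL, personal = NULL,
                          anthro = anthropometry(),
                          schedule = diet_schedule(),
                          init_glycogen = 275, blood_adjustment = 1.0) {
  variant <- if (anthro$diabetes) "t2d" else "healthy"
  if (is.null(params)) params <- default_params(variant)
  if (is.null(personal)) personal <- personal_defaults(variant)
  validate_personal(personal)
  p <- params
  BW <- anthro$weight_kg
  bv <- blood_volumes(anthro, blood_adjustment)
  pc <- list(
    p = p, personal = personal, anthro = anthro,
    BW = BW, kf = BW / 1000,
    Vp = p[["v_glc_plasma"]] * BW,
    Vt = p[["v_glc_tissue"]] * BW,
    Vl = p[["liver_volume"]] * BW,
    Vk = p[["kidney_volume"]] * BW,
    Vlb = bv$liver_L, Vpb = bv$total_L - bv$liver_L,
    flow = p[["hep_plasma_flow"]] * bv$total_L / 5.3,
    prod = personal[["prod_mod"]],
    clear = personal[["clear_mod"]],
    resist = personal[["resist_mod"]],
    prot_m0 = p[["protein_reserve"]],
    blood = bv,
    input = to_input_signal(schedule),
    schedule = schedule,
    init_glycogen = init_glycogen,
    sec_anchor = 1, egp_anchor = 1
  )

  Gb <- personal[["basal_glucose"]]; Ib <- personal[["basal_insulin"]]
  glyk_ref <- 30

  # --- insulin anchoring: make (Gb, Ib) a fixed point of the insulin
  # subsystem ----------------------------------------------------------
  clh <- p[["cl_hep_insulin"]] * pc$clear
  clp <- p[["cl_per_insulin"]] * pc$clear
  Il_b <- Ib * (1 + clp * pc$Vpb / pc$flow)
  s_req <- clh * pc$Vlb * Il_b + clp * pc$Vpb * Ib
  sigma_b <- p[["f0_secretion"]] + (1 - p[["f0_secretion"]]) *
    Gb^p[["h_secretion"]] /
    (p[["g50_secretion"]]^p[["h_secretion"]] + Gb^p[["h_secretion"]])
  pc$sigma_b <- sigma_b
  pc$sec_anchor <- s_req / (p[["sec_rate"]] * BW * sigma_b)

  # --- glucose anchoring: balance production against uptake -----------
  base <- rep(0, 17L); names(base) <- .state_names
  base[5L] <- Gb; base[7L] <- Ib; base[8L] <- Il_b
  base[9L] <- init_glycogen; base[14L] <- glyk_ref
  base[15L] <- pc$prot_m0
  periph <- function(Gt) {
    st <- base; st[6L] <- Gt
    f <- .model_fluxes(0, st, pc)
    p[["k_transfer"]] * (Gb - Gt) * pc$Vp - f[["u_muscle"]] - f[["u_other"]]
  }
  Gt_b <- stats::uniroot(periph, c(1e-6, Gb - 1e-9), tol = 1e-10)$root
  base[6L] <- Gt_b
  f0 <- .model_fluxes(0, base, pc)
  egp_req <- f0[["u_brain"]] + f0[["u_kidney"]] + f0[["u_liver"]] +
    f0[["u_muscle"]] + f0[["u_other"]]
  if (egp_req <= 0)
    stop("no admissible basal state: total uptake non-positive")
  in_pyr <- f0[["proteolysis"]] + f0[["cori"]]
  gl_hat <- f0[["glycogenolysis_liver"]] + f0[["glycogenolysis_kidney"]]
  vg_hat <- function(pyr) {
    st <- base; st[12L] <- pyr
    f <- .model_fluxes(0, st, pc)
    f[["gng_liver"]] + f[["gng_kidney"]]
  }
  resid <- function(pyr) {
    a <- egp_req / (gl_hat + vg_hat(pyr))
    a * vg_hat(pyr) - (in_pyr - p[["k_pyr_ox"]] * pyr)
  }
  lo <- 1e-6
  hi <- in_pyr / p[["k_pyr_ox"]] - 1e-9  # beyond this, RHS < 0
  if (resid(hi) < 0)
    stop("no admissible basal state: gluconeogenic supply cannot match demand")
  pyr_b <- stats::uniroot(resid, c(lo, hi), tol = 1e-10)$root
  base[12L] <- pyr_b
  pc$egp_anchor <- egp_req / (gl_hat + vg_hat(pyr_b))

  # quasi-steady fast pools
  fb <- .model_fluxes(0, base, pc)
  cap <- max(0, 1 - (init_glycogen / p[["gly_max"]])^4)
  base[10L] <- fb[["u_liver"]] / (p[["k_glycsyn"]] * cap + p[["k_spill"]])
  fb <- .model_fluxes(0, base, pc)
  base[13L] <- (fb[["pyr_oxidation"]] + fb[["g6p_spill"]]) / p[["k_tca"]]

  pc$init <- base
  class(pc) <- "model_context"
  pc
}

#' Basal steady-state initial condition
#'
#' Returns a state whose fast subsystems (plasma/tissue glucose, both
#' insulin compartments, the hepatic substrate pools) are exact fixed
#' points at the person's basal glucose and insulin, with glycogen set to
#' the requested level (the fed window is 200-350 mmol/L; the fed default
#' is 275). Glycogen itself and the muscle protein reserve are slow
#' stores and drift on the hour-to-day scale, as they do physiologically.
#'
#' @param params,personal,anthro as in [model_context()].
#' @param glycogen hepatic glycogen (mmol/L of liver) of the returned
#'   state.
#' @return Named state vector.
#' @export
#' @examples
#' st <- steady_state()
#' st[["glc_plasma"]]  # the basal glucose, 5 mmol/L by default
steady_state <- function(params = NULL, personal = NULL,
                         anthro = anthropometry(), glycogen = 275) {
  pc <- model_context(params, personal, anthro, init_glycogen = glycogen)
  pc$init
}

#' Simulate the model over a protocol
#'
#' Integrates the ODE system over `t_span_h` with the meals of `schedule`
#' as square-pulse inputs. Integration is stiff-capable (lsoda) and
#' proceeds piecewise between meal start/end boundaries so input
#' discontinuities never straddle a solver step. Dense output is returned
#' on a regular grid.
#'
#' @param schedule a [diet_schedule()].
#' @param t_span_h length-2 numeric, simulation window in hours; must
#'   cover all scheduled meals.
#' @param params,personal,anthro,init_glycogen,blood_adjustment passed to
#'   [model_context()]; alternatively supply a ready `context`.
#' @param context optional pre-built [model_context()] (its schedule is
#'   used).
#' @param init `"basal"` for steady-state initialisation, or a named
#'   state vector.
#' @param grid_min output grid resolution, minutes.
#' @param rtol,atol solver tolerances.
#' @return Object of class `"twin_sim"`: list with `time_h`, `state`
#'   (matrix, one column per state), `flux` (data.frame of flux time
#'   series; glucose fluxes in umol/kg/min, insulin fluxes in pmol/min),
#'   `context`, and `negative_states` (TRUE if any state fell below
#'   -1e-6).
#' @export
#' @examples
#' sim <- simulate_twin(diet_schedule(meal_event(1, carb_g = 87,
#'   protein_g = 23)), t_span_h = c(0, 10))
#' max(observable_map(sim, "plasma_glucose")$value)
simulate_twin <- function(schedule = diet_schedule(),
                          t_span_h = c(0, 24), params = NULL,
                          personal = NULL, anthro = anthropometry(),
                          init = "basal", init_glycogen = 275,
                          blood_adjustment = 1.0, context = NULL,
                          grid_min = 1, rtol = 1e-6, atol = 1e-8) {
  if (is.null(context)) {
    context <- model_context(params, personal, anthro, schedule,
                             init_glycogen, blood_adjustment)
  }
  pc <- context
  t0 <- t_span_h[1] * 60; tf <- t_span_h[2] * 60
  if (tf <= t0) stop("t_span_h must be increasing")
  brk <- pc$input$breaks_min
  if (length(brk) && (min(brk) < t0 - 1e-9 || max(brk) > tf + 1e-9))
    stop("t_span_h does not cover all scheduled meals")
  y <- if (identical(init, "basal")) pc$init else {
    if (length(init) != 17L) stop("init state must have 17 elements")
    st <- as.numeric(init); names(st) <- .state_names; st
  }
  bounds <- sort(unique(c(t0, brk[brk > t0 & brk < tf], tf)))
  total_kcal <- sum(pc$schedule$kcal)
  if (nrow(pc$schedule) && any(pc$schedule$kcal > 1000))
    warning("meal above 1000 kcal: outside the supported meal-size range, ",
            "simulations may show non-physiological behaviour")

  rows <- vector("list", length(bounds) - 1L)
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    times <- unique(c(seq(a, b, by = grid_min), b))
    out <- deSolve::ode(y = y, times = times, func = metab_rhs, parms = pc,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(out, "istate")[1L] < 0)
      stop(sprintf("solver failure in segment [%.1f, %.1f] min; last good time %.2f min",
                   a, b, max(out[, 1L])))
    y <- out[nrow(out), -1L]
    rows[[i]] <- if (i == 1L) out else out[-1L, , drop = FALSE]
  }
  traj <- do.call(rbind, rows)
  state <- traj[, -1L, drop = FALSE]
  colnames(state) <- .state_names
  time_min <- traj[, 1L]

  flux <- t(vapply(seq_along(time_min), function(i)
    .model_fluxes(time_min[i], state[i, ], pc), numeric(27L)))
  flux <- as.data.frame(flux)
  # report glucose fluxes in umol/kg/min
  gcols <- c("ra_glucose", "u_brain", "u_muscle", "u_liver", "u_kidney",
             "u_other", "transfer", "glycogenolysis_liver", "gng_liver",
             "glycogenolysis_kidney", "gng_kidney", "glycogen_synthesis",
             "glycogen_synthesis_kidney", "g6p_spill", "cori")
  flux[gcols] <- flux[gcols] / pc$kf

  res <- list(time_h = time_min / 60, state = state, flux = flux,
              context = pc,
              negative_states = any(state < -1e-6))
  class(res) <- "twin_sim"
  res
}

#' @export
print.twin_sim <- function(x, ...) {
  cat(sprintf("<twin simulation> %.1f-%.1f h, %d grid points, %d meals\n",
              min(x$time_h), max(x$time_h), length(x$time_h),
              nrow(x$context$schedule)))
  g <- x$state[, "glc_plasma"]
  cat(sprintf("  plasma glucose %.2f-%.2f mmol/L; hepatic glycogen %.0f-%.0f mmol/L\n",
              min(g), max(g), min(x$state[, "glycogen_liver"]),
              max(x$state[, "glycogen_liver"])))
  invisible(x)
}

#' Fixed-step reference integration
#'
#' Classic fourth-order Runge-Kutta at a fixed step, respecting the same
#' meal boundaries as [simulate_twin()]. Serves as an integrator-
#' independent reference for verifying the adaptive solution.
#'
#' @inheritParams simulate_twin
#' @param step_min fixed step, minutes.
#' @return A `"twin_sim"` object on the step grid.
#' @export
simulate_fixed_step <- function(schedule = diet_schedule(),
                                t_span_h = c(0, 24), params = NULL,
                                personal = NULL, anthro = anthropometry(),
                                init = "basal", init_glycogen = 275,
                                context = NULL, step_min = 0.25) {
  if (is.null(context))
    context <- model_context(params, personal, anthro, schedule,
                             init_glycogen)
  pc <- context
  t0 <- t_span_h[1] * 60; tf <- t_span_h[2] * 60
  brk <- pc$input$breaks_min
  bounds <- sort(unique(c(t0, brk[brk > t0 & brk < tf], tf)))
  y <- if (identical(init, "basal")) pc$init else {
    st <- as.numeric(init); names(st) <- .state_names; st
  }
  ts <- list(t0); ys <- list(y)
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    n <- max(1L, ceiling((b - a) / step_min))
    h <- (b - a) / n
    t <- a
    for (k in seq_len(n)) {
      k1 <- metab_rhs(t, y, pc)[[1L]]
      k2 <- metab_rhs(t + h / 2, y + h / 2 * k1, pc)[[1L]]
      k3 <- metab_rhs(t + h / 2, y + h / 2 * k2, pc)[[1L]]
      k4 <- metab_rhs(t + h, y + h * k3, pc)[[1L]]
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
      ts[[length(ts) + 1L]] <- t; ys[[length(ys) + 1L]] <- y
    }
  }
  time_min <- unlist(ts)
  state <- do.call(rbind, ys)
  colnames(state) <- .state_names
  flux <- t(vapply(seq_along(time_min), function(i)
    .model_fluxes(time_min[i], state[i, ], pc), numeric(27L)))
  flux <- as.data.frame(flux)
  gcols <- c("ra_glucose", "u_brain", "u_muscle", "u_liver", "u_kidney",
             "u_other", "transfer", "glycogenolysis_liver", "gng_liver",
             "glycogenolysis_kidney", "gng_kidney", "glycogen_synthesis",
             "glycogen_synthesis_kidney", "g6p_spill", "cori")
  flux[gcols] <- flux[gcols] / pc$kf
  res <- list(time_h = time_min / 60, state = state, flux = flux,
              context = pc, negative_states = any(state < -1e-6))
  class(res) <- "twin_sim"
  res
}

#' Tidy export of a simulation
#'
#' @param x a `"twin_sim"`.
#' @param ... unused.
#' @return data.frame in long format with columns `time_h`, `variable`,
#'   `value` covering all states and fluxes.
#' @export
as.data.frame.twin_sim <- function(x, ...) {
  st <- as.data.frame(x$state)
  wide <- cbind(time_h = x$time_h, st, x$flux)
  long <- stats::reshape(wide, direction = "long",
                         varying = names(wide)[-1L],
                         v.names = "value", timevar = "variable",
                         times = names(wide)[-1L], idvar = "time_h")
  rownames(long) <- NULL
  long[order(long$time_h), c("time_h", "variable", "value")]
}
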