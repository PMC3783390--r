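#' Society state
#'
#' Per-occupation productivity and activity flags at a phase boundary.
#' Inactive occupations hold exactly zero productivity; at phase boundaries
#' every active occupation holds at least limina.
#'
#' @param x numeric vector of nonnegative productivities.
#' @param active logical vector; defaults to `x > 0`.
#' @param phase_index develop/mutate cycles completed so far.
#' @return An object of class `society_state`.
#' @export
society_state <- function(x, active = NULL, phase_index = 0L) {
  if (!is.numeric(x) || any(x < 0)) stop("x must be nonnegative")
  if (is.null(active)) active <- x > 0
  if (length(active) != length(x)) stop("active must match x in length")
  if (any(x[!active] != 0)) stop("inactive occupations must have x = 0")
  structure(list(x = as.numeric(x), active = as.logical(active),
                 phase_index = as.integer(phase_index)),
            class = "society_state")
}

#' @export
print.society_state <- function(x, ...) {
  cat("<society_state> phase ", x$phase_index, ": ", sum(x$active), "/",
      length(x$x), " active, total X = ", format(sum(x$x)), "\n", sep = "")
  invisible(x)
}

#' Has the whole society gone extinct?
#' @param state a [society_state()].
#' @return `TRUE` when no occupation is active.
#' @export
is_extinct <- function(state) !any(state$active)

#' Environment parameters
#'
#' @param a supporting coefficient (> 0); every support link contributes
#'   `a * x_j` to the supported occupation's competing strength.
#' @param b environmental restriction coefficient (> 0); the restriction
#'   strength shared by all occupations is `b * X`.
#' @param disturbance_schedule data frame with columns `phase` and `r_d`
#'   listing pulse amplifications of `b` (each `r_d >= 1`) applied to the
#'   develop phase of the given step.
#' @return An object of class `environment_params`.
#' @export
environment_params <- function(a, b = 1,
                               disturbance_schedule = NULL) {
  if (!is.numeric(a) || a <= 0 || !is.numeric(b) || b <= 0)
    stop("a and b must be positive")
  if (is.null(disturbance_schedule))
    disturbance_schedule <- data.frame(phase = integer(0), r_d = numeric(0))
  if (!all(c("phase", "r_d") %in% names(disturbance_schedule)))
    stop("disturbance_schedule needs columns phase and r_d")
  if (any(disturbance_schedule$r_d < 1)) stop("every r_d must be >= 1")
  structure(list(a = a, b = b,
                 disturbance_schedule = disturbance_schedule),
            class = "environment_params")
}

#' Competing strength of every occupation
#'
#' `Cs_i = a * sum_j c_ij x_j`: the supporting inflow an occupation wields
#' against the environment. Inactive occupations hold zero productivity and
#' therefore contribute nothing.
#'
#' @param x productivity vector (zeros for inactive occupations).
#' @param C [support_matrix()] or binary matrix.
#' @param a supporting coefficient.
#' @return Numeric vector of competing strengths.
#' @export
competing_strength <- function(x, C, a) {
  M <- as_support_mat(C)
  if (length(x) != nrow(M)) stop("x and C dimensions disagree")
  a * as.vector(M %*% x)
}

#' Environmental restriction strength
#'
#' The linear incremental restriction `Ce = b * X` shared by every
#' occupation: pressure grows with the total population of the environment.
#'
#' @param X total productivity (>= 0).
#' @param b restriction coefficient (> 0).
#' @return Scalar restriction strength.
#' @export
environmental_restriction <- function(X, b) {
  if (X < 0) stop("X must be nonnegative")
  if (b <= 0) stop("b must be positive")
  b * X
}

#' Productivity change rate
#'
#' The canonical (`"ratio"`) form divides the supporting inflow by the
#' occupation's own productivity, `dx_i/dt = a (Cx)_i / x_i - bX`: growth
#' slows as an occupation gets large, and the restriction term is a shared
#' pressure rather than a dilution flux, so the system can expand. The
#' `"mass"` form `dx_i/dt = a (Cx)_i - bX x_i` shares the same fixed points.
#' Inactive occupations have rate zero.
#'
#' @param state a [society_state()]; every active occupation must hold
#'   positive productivity (the ratio form is singular at zero).
#' @param C [support_matrix()] or binary matrix.
#' @param env [environment_params()].
#' @param rate_form `"ratio"` (canonical) or `"mass"`.
#' @return Numeric vector of rates.
#' @export
derivative <- function(state, C, env, rate_form = c("ratio", "mass")) {
  rate_form <- match.arg(rate_form)
  if (any(state$active & state$x == 0))
    stop("active occupation with zero productivity: eliminate it first")
  cs <- competing_strength(state$x, C, env$a)
  ce <- environmental_restriction(sum(state$x[state$active]), env$b)
  g <- numeric(length(state$x))
  act <- state$active
  if (rate_form == "ratio") {
    g[act] <- cs[act] / state$x[act] - ce
  } else {
    g[act] <- cs[act] - ce * state$x[act]
  }
  g
}

rate_form_code <- function(rate_form) {
  switch(match.arg(rate_form, c("ratio", "mass")), ratio = 1L, mass = 2L)
}

#' Developing phase: relax to the attractor with eliminations
#'
#' Integrates the productivity dynamics with explicit stepping until the
#' stationarity residual `max_i |a (Cx)_i / x_i - bX|` falls below the
#' configured tolerance. Whenever an active occupation drops below limina it
#' is eliminated (productivity zeroed, flagged inactive) and integration
#' continues on the reduced set, so elimination cascades resolve within one
#' develop phase. When the final active submatrix is irreducible the result
#' matches [equilibrium_productivity()] of that submatrix.
#'
#' @param state a [society_state()] with at least one active occupation
#'   (an extinct state is returned unchanged).
#' @param C [support_matrix()] or binary matrix.
#' @param env [environment_params()].
#' @param cfg a [scenario_config()] supplying limina and the integrator
#'   options (`dt`, `tol`, `max_steps`, `rate_form`).
#' @param b_override optional replacement for `env$b` (used for disturbance
#'   pulses).
#' @return The relaxed [society_state()] (same phase index). A warning is
#'   raised if the step cap is reached before convergence.
#' @export
develop <- function(state, C, env, cfg, b_override = NULL) {
  if (is_extinct(state)) return(state)
  M <- as_support_mat(C)
  b <- b_override %||% env$b
  res <- cpp_develop(M, state$x, state$active, env$a, b, cfg$limina,
                     cfg$dt / b, cfg$tol, cfg$max_steps,
                     rate_form_code(cfg$rate_form))
  if (res$status == 2L)
    warning("develop: step cap reached before convergence")
  society_state(res$x, res$active, state$phase_index)
}

#' Eligible mutation targets for a source occupation
#'
#' An inhabitant flow can only target an occupation that is actually
#' supported by at least one active occupation: flows between existing
#' occupations, and creation or regeneration of currently inactive ones (a
#' society keeps the memory of its destroyed occupations).
#'
#' @param state a [society_state()].
#' @param C [support_matrix()] or binary matrix.
#' @param source index of the (active) source occupation.
#' @return Integer vector of target indices (possibly empty).
#' @export
eligible_targets <- function(state, C, source) {
  M <- as_support_mat(C)
  if (!state$active[source]) stop("source occupation is not active")
  supported <- rowSums(M[, state$active, drop = FALSE]) > 0
  setdiff(which(supported), source)
}

#' Mutating phase: stochastic transfer of productivity quanta
#'
#' Visits the active occupations in a uniformly random order. Each occupation
#' holding more than `2 * limina` fires with probability `p_m`; on firing it
#' transfers exactly one limina quantum to a target drawn from
#' [eligible_targets()], with own-society targets at weight 1 and
#' other-society targets at weight `cross_weight`. A previously inactive
#' target becomes active at exactly limina. Total productivity is conserved
#' exactly.
#'
#' @param state a [society_state()] at a phase boundary.
#' @param C [support_matrix()] (labels drive the cross-society weighting).
#' @param cfg a [scenario_config()] supplying `limina`, `p_m` and
#'   `cross_weight`.
#' @return A list with the new `state` and `events`, a data frame of
#'   (source, target, amount) rows.
#' @export
mutate <- function(state, C, cfg) {
  M <- as_support_mat(C)
  labels <- support_labels(C, nrow(M))
  res <- cpp_mutate(M, society_codes(labels), state$x, state$active,
                    cfg$limina, cfg$p_m, cfg$cross_weight)
  events <- data.frame(source = res$events[, 1], target = res$events[, 2],
                       amount = rep(cfg$limina, nrow(res$events)))
  list(state = society_state(res$x, res$active, state$phase_index),
       events = events)
}

#' One develop + mutate cycle
#'
#' Applies the developing phase (under a disturbance-amplified `b` if a pulse
#' is scheduled for this step), then the mutating phase, and increments the
#' phase counter. An extinct state is returned unchanged.
#'
#' @inheritParams develop
#' @return The advanced [society_state()].
#' @export
step <- function(state, C, env, cfg) {
  if (is_extinct(state)) return(state)
  phase <- state$phase_index + 1L
  sched <- env$disturbance_schedule
  r_d <- sched$r_d[match(phase, sched$phase)]
  b_eff <- if (!is.na(r_d)) env$b * r_d else env$b
  state <- develop(state, C, env, cfg, b_override = b_eff)
  if (!is_extinct(state)) state <- mutate(state, C, cfg)$state
  state$phase_index <- phase
  state
}

#' Apply a pulse disturbance
#'
#' Runs one develop phase under the amplified restriction coefficient
#' `b' = r_d * b` (with eliminations), after which `b` returns to normal.
#' Starting from equilibrium, the disturbed attractor scales every surviving
#' occupation's productivity by `1/r_d`; occupations pushed below limina on
#' the way are eliminated, and the cascade may leave only a small
#' self-sustaining core, or nothing.
#'
#' @inheritParams develop
#' @param r_d disturbance severity (>= 1).
#' @return The disturbed [society_state()].
#' @export
apply_disturbance <- function(state, C, env, r_d, cfg) {
  if (!is.numeric(r_d) || r_d < 1) stop("r_d must be >= 1")
  develop(state, C, env, cfg, b_override = env$b * r_d)
}
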