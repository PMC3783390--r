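CONFIG_FIELDS <- c("n_o", "n_d", "n_i", "p_c_oo", "p_c_od", "p_c_do",
                   "p_c_dd", "p_c_ii", "a_over_b", "p_m", "r_d", "limina",
                   "cross_weight", "n_phases", "n_reps", "seed",
                   "event_phase", "rate_form", "origin_state",
                   "invader_entry", "dt", "tol", "max_steps",
                   "n", "p_c")

#' Scenario configuration
#'
#' Collects every knob of a simulation run: society structure (block sizes
#' and support probabilities), environment ratio `a/b`, mutation parameters,
#' disturbance severity, phase counts and integrator options. `n` and `p_c`
#' are accepted as aliases for `n_o` and `p_c_oo` in single-society runs.
#'
#' Defaults: `limina = 1` (the arbitrary functioning threshold all other
#' productivities are measured against), `cross_weight = 0.1` (transforming
#' into another society's occupation is less likely than staying inside the
#' own society), `event_phase = 51` (scenario events strike after a 50-phase
#' steady stretch of the developed society), integrator step `dt = 1e-3` in
#' units of `1/b`, stationarity tolerance `tol = 1e-8 * a_over_b`.
#'
#' @param n_o,p_c_oo size and support probability of the original society.
#' @param a_over_b ratio of supporting to restriction coefficient; only the
#'   ratio matters for equilibria, so internally `b = 1`, `a = a_over_b`.
#' @param p_m per-occupation mutation probability per phase.
#' @param n_d,n_i,p_c_od,p_c_do,p_c_dd,p_c_ii derived/invader blocks, see
#'   [inter_society_spec()].
#' @param limina minimum functioning productivity; also the quantum moved by
#'   one mutation event.
#' @param cross_weight relative weight of other-society mutation targets.
#' @param r_d disturbance severity (disturbing scenario only).
#' @param n_phases develop/mutate cycles to run.
#' @param n_reps default replication count for [replicate_scenario()].
#' @param seed default base seed.
#' @param event_phase phase at which the scenario event (pulse, invasion)
#'   strikes.
#' @param rate_form `"ratio"` (canonical) or `"mass"` derivative form.
#' @param origin_state `"boot"`: the original society self-boots from a
#'   single occupation while derived formation is live (supporting/mutual
#'   scenarios race society formation against parasitic load);
#'   `"equilibrium"`: it starts fully formed at its equilibrium.
#' @param invader_entry productivity carried by an arriving invader squad:
#'   `"equilibrium"` (its home-environment equilibrium) or `"limina"`.
#' @param dt integrator step in units of `1/b`.
#' @param tol stationarity tolerance on `|a (Cx)_i/x_i - bX|`.
#' @param max_steps integrator step cap per develop phase.
#' @param n,p_c aliases for `n_o`, `p_c_oo`.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_o = NULL, p_c_oo = NULL, a_over_b, p_m,
                            n_d = 0, n_i = 0, p_c_od = 0, p_c_do = 0,
                            p_c_dd = 0, p_c_ii = 0, limina = 1,
                            cross_weight = 0.1, r_d = 1,
                            n_phases = 500L, n_reps = 50L, seed = 1L,
                            event_phase = 51L,
                            rate_form = c("ratio", "mass"),
                            origin_state = c("boot", "equilibrium"),
                            invader_entry = c("equilibrium", "limina"),
                            dt = 1e-3, tol = NULL, max_steps = 1e7,
                            n = NULL, p_c = NULL) {
  n_o <- n_o %||% n
  p_c_oo <- p_c_oo %||% p_c
  if (is.null(n_o)) stop("n_o (or n) is required")
  if (is.null(p_c_oo)) stop("p_c_oo (or p_c) is required")
  rate_form <- match.arg(rate_form)
  origin_state <- match.arg(origin_state)
  invader_entry <- match.arg(invader_entry)
  if (!is.numeric(a_over_b) || a_over_b <= 0) stop("a_over_b must be > 0")
  if (!is.numeric(p_m) || p_m < 0 || p_m > 1)
    stop("p_m must be a probability in [0, 1]")
  if (!is.numeric(limina) || limina <= 0) stop("limina must be > 0")
  if (!is.numeric(cross_weight) || cross_weight < 0 || cross_weight > 1)
    stop("cross_weight must be in [0, 1]")
  if (!is.numeric(r_d) || r_d < 1) stop("r_d must be >= 1")
  if (!is.numeric(n_phases) || n_phases < 1) stop("n_phases must be >= 1")
  if (!is.numeric(event_phase) || event_phase < 1)
    stop("event_phase must be >= 1")
  if (!is.numeric(n_reps) || n_reps < 1) stop("n_reps must be >= 1")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  if (!is.numeric(max_steps) || max_steps < 1) stop("max_steps must be >= 1")
  spec <- inter_society_spec(n_o = n_o, n_d = n_d, n_i = n_i,
                             p_c_oo = p_c_oo, p_c_od = p_c_od,
                             p_c_do = p_c_do, p_c_dd = p_c_dd,
                             p_c_ii = p_c_ii)
  tol <- tol %||% (1e-8 * a_over_b)
  if (tol <= 0) stop("tol must be > 0")
  structure(c(unclass(spec),
              list(a_over_b = a_over_b, p_m = p_m, limina = limina,
                   cross_weight = cross_weight, r_d = r_d,
                   n_phases = as.integer(n_phases),
                   n_reps = as.integer(n_reps), seed = as.integer(seed),
                   event_phase = as.integer(event_phase),
                   rate_form = rate_form, origin_state = origin_state,
                   invader_entry = invader_entry, dt = dt, tol = tol,
                   max_steps = max_steps)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> n_o=", x$n_o,
      if (x$n_d > 0) paste0(" n_d=", x$n_d),
      if (x$n_i > 0) paste0(" n_i=", x$n_i),
      " a/b=", x$a_over_b, " p_m=", x$p_m, " limina=", x$limina,
      " phases=", x$n_phases, "\n", sep = "")
  invisible(x)
}

#' Environment parameters implied by a scenario configuration
#' @param cfg a [scenario_config()].
#' @return An [environment_params()] with `a = a_over_b`, `b = 1`.
#' @export
config_environment <- function(cfg) environment_params(a = cfg$a_over_b, b = 1)

#' Load and validate a scenario configuration file
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON (`.json`) file whose keys mirror the
#' parameter table of the model (`a_over_b`, `n_o`, `n_d`, `n_i`, `p_c_oo`,
#' `p_c_od`, `p_c_do`, `p_c_dd`, `p_c_ii`, `p_m`, `r_d`, `limina`,
#' `cross_weight`, `n_phases`, `n_reps`, `seed`, ...). Unknown keys are
#' rejected; validation errors name the offending key; probabilities above 1
#' are capped at 1 with a warning.
#'
#' @param path configuration file.
#' @return A [scenario_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    # identity handlers keep short keys such as "n" or "y" from being
    # YAML-1.1-coerced to booleans
    yaml::read_yaml(path, handlers = list("bool#yes" = function(x) x,
                                          "bool#no" = function(x) x))
  }
  if (!is.list(raw)) stop("config must be a mapping of parameter names")
  unknown <- setdiff(names(raw), CONFIG_FIELDS)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(scenario_config, raw)
}
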