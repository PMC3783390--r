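REC_COLS <- c("X_original", "X_derived", "X_invader",
              "n_original", "n_derived", "n_invader")

state_record <- function(state, labels) {
  out <- data.frame(phase = state$phase_index,
                    X_original = 0, X_derived = 0, X_invader = 0,
                    n_original = 0, n_derived = 0, n_invader = 0)
  for (soc in SOCIETY_LEVELS) {
    sel <- state$active & labels == soc
    out[[paste0("X_", soc)]] <- sum(state$x[sel])
    out[[paste0("n_", soc)]] <- sum(sel)
  }
  out
}

# Runs n_phases develop+mutate cycles through the compiled loop, carrying the
# state's phase counter so disturbance schedules use absolute phase indices.
phase_chunk <- function(sm, state, cfg, n_phases,
                        disturb_phase = integer(0), disturb_rd = numeric(0)) {
  env <- config_environment(cfg)
  res <- cpp_run_phases(as.matrix(sm), society_codes(sm$labels),
                        state$x, state$active, env$a, env$b, cfg$limina,
                        cfg$p_m, cfg$cross_weight, as.integer(n_phases),
                        as.integer(disturb_phase), as.numeric(disturb_rd),
                        cfg$dt / env$b, cfg$tol, cfg$max_steps,
                        rate_form_code(cfg$rate_form),
                        as.integer(state$phase_index))
  if (res$nonconverged > 0)
    warning(res$nonconverged, " develop phase(s) hit the step cap before ",
            "reaching stationarity")
  recs <- as.data.frame(res$records)
  names(recs) <- REC_COLS
  recs <- cbind(phase = state$phase_index + seq_len(n_phases), recs)
  list(state = society_state(res$x, res$active,
                             state$phase_index + n_phases),
       records = recs)
}

new_trajectory <- function(scenario, sm, cfg, seed, records, final_state) {
  societies <- intersect(SOCIETY_LEVELS, unique(sm$labels))
  extinct <- vapply(societies, function(soc) {
    !any(final_state$active & sm$labels == soc)
  }, logical(1))
  structure(list(scenario = scenario, records = records,
                 final_state = final_state, extinct = extinct,
                 support = sm, config = cfg, seed = seed),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  fin <- x$records[nrow(x$records), ]
  cat("<trajectory> ", x$scenario, " scenario, ", nrow(x$records) - 1,
      " phases, seed ", x$seed, "\n", sep = "")
  for (soc in names(x$extinct)) {
    cat("  ", soc, ": X = ", format(fin[[paste0("X_", soc)]]),
        ", active = ", fin[[paste0("n_", soc)]],
        if (x$extinct[[soc]]) "  [extinct]", "\n", sep = "")
  }
  invisible(x)
}

equilibrium_state <- function(sm, cfg, indices = NULL) {
  n <- n_occupations(sm)
  env <- config_environment(cfg)
  if (is.null(indices)) indices <- seq_len(n)
  sub <- as.matrix(sm)[indices, indices, drop = FALSE]
  x <- numeric(n)
  x[indices] <- equilibrium_productivity(sub, env$a, env$b)
  society_state(x)
}

#' Self-boot of a society from a single occupation
#'
#' Starts from one self-supporting occupation at productivity limina and
#' alternates developing and mutating phases. Mutation gradually creates the
#' remaining occupations; on long runs the active count approaches `n` and
#' the total productivity fluctuates around `(a/b) * lambda_pf` of the full
#' support matrix.
#'
#' @param cfg a [scenario_config()] (single-society: `n_o`, `p_c_oo`).
#' @param seed integer seed; defaults to `cfg$seed`.
#' @return A `trajectory` object.
#' @export
run_boot <- function(cfg, seed = NULL) {
  seed <- seed %||% cfg$seed
  set.seed(seed)
  sm <- generate_support_matrix(cfg$n_o, cfg$p_c_oo,
                                require_irreducible = TRUE,
                                ensure_self_supporter = TRUE)
  selfers <- which(diag(as.matrix(sm)) == 1L)
  s0 <- if (length(selfers) == 1L) selfers else sample(selfers, 1L)
  x0 <- numeric(cfg$n_o)
  x0[s0] <- cfg$limina
  chunk <- phase_chunk(sm, society_state(x0), cfg, cfg$n_phases)
  records <- rbind(state_record(society_state(x0), sm$labels), chunk$records)
  new_trajectory("boot", sm, cfg, seed, records, chunk$state)
}

#' Parasitic supporting scenario
#'
#' The original society So self-boots from a single self-supporting
#' occupation while mutation may also populate the derived society Sd
#' (other-society targets carry the lower `cross_weight`, so Sd forms with a
#' lag behind So). Sd receives support from So (`p_c_od`) but gives none
#' back (`p_c_do = 0` is required): a parasitic society that contributes
#' nothing to the total productivity, grabbing a growing share as it forms.
#' The outcome is a race: if every So occupation still clears limina once Sd
#' has fully formed the societies coexist; otherwise So loses occupations or
#' collapses entirely, and a collapsed So drags a non-self-supporting Sd
#' down with it. With `origin_state = "equilibrium"` the race is skipped and
#' So starts fully formed at its equilibrium instead.
#'
#' @inheritParams run_boot
#' @export
run_supporting <- function(cfg, seed = NULL) {
  if (cfg$n_d < 1) stop("supporting scenario needs a derived block (n_d >= 1)")
  if (cfg$p_c_do != 0)
    stop("parasitic supporting scenario requires p_c_do = 0 (no back-support)")
  run_origin_derived("supporting", cfg, seed)
}

# Shared engine of the supporting and mutual scenarios: original + derived
# blocks, starting either from a single-occupation self-boot or from the
# original society's equilibrium.
run_origin_derived <- function(scenario, cfg, seed) {
  seed <- seed %||% cfg$seed
  set.seed(seed)
  sm <- generate_two_society_matrix(config_spec(cfg, invader = FALSE))
  if (cfg$origin_state == "boot") {
    Coo <- as.matrix(sm)[sm$labels == "original", sm$labels == "original"]
    if (all(diag(Coo) == 0L)) {
      k <- sample.int(cfg$n_o, 1L)
      sm$C[k, k] <- 1L  # guarantee a legal single-occupation seed
    }
    selfers <- which(diag(as.matrix(sm)) == 1L & sm$labels == "original")
    s0 <- if (length(selfers) == 1L) selfers else sample(selfers, 1L)
    x0 <- numeric(n_occupations(sm))
    x0[s0] <- cfg$limina
    state <- society_state(x0)
  } else {
    state <- equilibrium_state(sm, cfg,
                               indices = which(sm$labels == "original"))
  }
  chunk <- phase_chunk(sm, state, cfg, cfg$n_phases)
  records <- rbind(state_record(state, sm$labels), chunk$records)
  new_trajectory(scenario, sm, cfg, seed, records, chunk$state)
}

#' Pulse-disturbance scenario
#'
#' The society runs at its steady state until `event_phase`, whose develop
#' phase is executed under the amplified restriction coefficient
#' `b' = r_d * b` (the pulse affects that single step only). Occupations
#' pushed below limina are eliminated; afterwards the survivors act as seed
#' and rebuild the society through mutation. Larger `r_d` eliminates more
#' occupations, lengthens recovery and may wipe out the society entirely.
#'
#' @inheritParams run_boot
#' @export
run_disturbing <- function(cfg, seed = NULL) {
  if (cfg$event_phase > cfg$n_phases)
    stop("event_phase must lie within n_phases")
  seed <- seed %||% cfg$seed
  set.seed(seed)
  sm <- generate_support_matrix(cfg$n_o, cfg$p_c_oo,
                                require_irreducible = TRUE)
  state <- equilibrium_state(sm, cfg)
  chunk <- phase_chunk(sm, state, cfg, cfg$n_phases,
                       disturb_phase = cfg$event_phase,
                       disturb_rd = cfg$r_d)
  records <- rbind(state_record(state, sm$labels), chunk$records)
  new_trajectory("disturbing", sm, cfg, seed, records, chunk$state)
}

#' Peaceful-invasion scenario
#'
#' The original society So dwells at equilibrium; at `event_phase` an intact
#' squad of the invader society Si enters the environment, by default
#' carrying the productivity it held at its home-environment equilibrium
#' (`invader_entry = "limina"` lands every invader occupation at the bare
#' functioning minimum instead). The two societies share the environment but
#' exchange no support, so they compete only through the restriction term:
#' the block with the larger spectral radius eventually drives the other
#' extinct, with ties resolved in favour of the larger established mass.
#'
#' @inheritParams run_boot
#' @export
run_invading <- function(cfg, seed = NULL) {
  if (cfg$n_i < 1) stop("invading scenario needs an invader block (n_i >= 1)")
  if (cfg$n_d > 0 || cfg$p_c_od != 0 || cfg$p_c_do != 0 || cfg$p_c_dd != 0)
    stop("invading scenario is pure competition: no derived block allowed")
  if (cfg$event_phase > cfg$n_phases)
    stop("event_phase must lie within n_phases")
  seed <- seed %||% cfg$seed
  set.seed(seed)
  sm <- generate_two_society_matrix(config_spec(cfg, invader = TRUE))
  state <- equilibrium_state(sm, cfg, indices = which(sm$labels == "original"))
  rec0 <- state_record(state, sm$labels)
  pre <- phase_chunk(sm, state, cfg, cfg$event_phase - 1L)
  state <- pre$state
  inv <- which(sm$labels == "invader")
  env <- config_environment(cfg)
  state$x[inv] <- if (cfg$invader_entry == "equilibrium") {
    # the squad arrives as a functioning whole, carrying the productivity it
    # held at its home-environment equilibrium
    equilibrium_productivity(as.matrix(sm)[inv, inv, drop = FALSE],
                             env$a, env$b)
  } else {
    cfg$limina
  }
  state$active[inv] <- TRUE
  post <- phase_chunk(sm, state, cfg, cfg$n_phases - cfg$event_phase + 1L)
  records <- rbind(rec0, pre$records, post$records)
  new_trajectory("invading", sm, cfg, seed, records, post$state)
}

#' Mutually supporting scenario
#'
#' As in the supporting scenario the derived society is populated by
#' mutation, but it also supports the original society back
#' (`p_c_do > 0`). When the merged support matrix is irreducible the two
#' societies fuse into a new, larger one whose spectral radius — and hence
#' equilibrium total productivity — exceeds the original's: societal growth.
#'
#' @inheritParams run_boot
#' @export
run_mutual <- function(cfg, seed = NULL) {
  if (cfg$n_d < 1) stop("mutual scenario needs a derived block (n_d >= 1)")
  run_origin_derived("mutual", cfg, seed)
}

config_spec <- function(cfg, invader) {
  inter_society_spec(n_o = cfg$n_o,
                     n_d = if (invader) 0L else cfg$n_d,
                     n_i = if (invader) cfg$n_i else 0L,
                     p_c_oo = cfg$p_c_oo,
                     p_c_od = if (invader) 0 else cfg$p_c_od,
                     p_c_do = if (invader) 0 else cfg$p_c_do,
                     p_c_dd = if (invader) 0 else cfg$p_c_dd,
                     p_c_ii = if (invader) cfg$p_c_ii else 0)
}

#' Write a trajectory log to CSV
#'
#' One row per phase (including the initial state) with the per-society
#' totals and active counts; round-trips with [read.csv()].
#'
#' @param trajectory a `trajectory` object.
#' @param path output CSV file.
#' @export
write_trajectory <- function(trajectory, path) {
  write.csv(trajectory$records, path, row.names = FALSE)
  invisible(path)
}

SCENARIOS <- c("boot", "supporting", "disturbing", "invading", "mutual")

#' Run a scenario by name
#' @param scenario one of `"boot"`, `"supporting"`, `"disturbing"`,
#'   `"invading"`, `"mutual"`.
#' @inheritParams run_boot
#' @return A `trajectory` object.
#' @export
run_scenario <- function(scenario, cfg, seed = NULL) {
  scenario <- match.arg(scenario, SCENARIOS)
  runner <- switch(scenario, boot = run_boot, supporting = run_supporting,
                   disturbing = run_disturbing, invading = run_invading,
                   mutual = run_mutual)
  runner(cfg, seed = seed)
}
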