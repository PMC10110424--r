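#' Simulate an asynchronous cycling progenitor population
#'
#' Realises the steady-state premise of cumulative and pulse labelling
#' experiments: neural progenitors are not synchronised, so at any instant
#' cells are spread across the cycle. Under `growth_mode =
#' "uniform_position"` the cycle position of each cycling cell is uniform
#' over its cycle, which makes the expected fraction of cells in a phase
#' exactly `t_phase / t_c`; under `"exponential_age"` the age density is
#' proportional to `2^(-a / t_c)` (an exponentially expanding population),
#' which over-represents young (G1) cells.
#'
#' A `quiescent_fraction` of cells is placed outside the cycle: they are
#' Ki67-negative and take no part in labelling, but remain SOX2-positive
#' (progenitor identity persists after cycle exit).
#'
#' @param config A [sim_config()] object.
#' @return A tibble of class `cell_population` with one row per cell and
#'   columns `cell_id`, `cell_cycle_length`, `cycle_position` (hours),
#'   `t_g1_cell`, `t_s_cell` (per-cell phase boundaries), `phase` (`"G1"`,
#'   `"S"`, `"G2M"` or `"quiescent"`), `sox2`, `tuj1`, `ki67`. The
#'   configuration is attached as attribute `config`.
#' @examples
#' cfg <- sim_config(phase_durations(10, 6, 4), n_cells = 1000, seed = 42)
#' pop <- simulate_population(cfg)
#' table(pop$phase) / nrow(pop) # approx 0.5 / 0.3 / 0.2
#' @export
simulate_population <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be created with sim_config()", call. = FALSE)
  }
  ph <- config$phases
  n <- config$n_cells
  withr::with_seed(config$seed, {
    # log-normal cycle-length jitter with mean preserved
    if (config$duration_cv > 0) {
      sdlog <- sqrt(log1p(config$duration_cv^2))
      len <- ph$t_c * exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
    } else {
      len <- rep(ph$t_c, n)
    }
    u <- stats::runif(n)
    pos <- switch(config$growth_mode,
      uniform_position = u * len,
      # inverse CDF of f(a) = c * 2^(-a/L) on [0, L)
      exponential_age = -len * log2(1 - u / 2)
    )
    quiescent <- stats::runif(n) < config$quiescent_fraction
    tuj1 <- stats::runif(n) < config$tuj1_fraction
  })
  scale <- len / ph$t_c
  g1_end <- ph$t_g1 * scale
  s_end <- (ph$t_g1 + ph$t_s) * scale
  phase <- ifelse(pos < g1_end, "G1", ifelse(pos < s_end, "S", "G2M"))
  phase[quiescent] <- "quiescent"
  out <- tibble::tibble(
    cell_id = seq_len(n),
    cell_cycle_length = len,
    cycle_position = pos,
    t_g1_cell = g1_end,
    t_s_cell = s_end - g1_end,
    phase = phase,
    sox2 = TRUE,
    tuj1 = tuj1,
    ki67 = !quiescent
  )
  class(out) <- c("cell_population", class(out))
  attr(out, "config") <- config
  out
}

# does the (forward, possibly cycle-wrapping) interval [a, b] overlap the
# S-phase interval [s0, s1) of a cell with cycle length L?
interval_hits_s <- function(a, b, s0, s1, len) {
  (b >= s0 & a < s1) | (b >= s0 + len & a < s1 + len)
}

#' Apply a virtual sequential IdU/BrdU double pulse
#'
#' Advances every cycling cell deterministically through its cycle over the
#' labelling window and records which thymidine analogues it incorporated.
#' A cell that is in S phase at any moment of the IdU-only window
#' `[0, t_idu]` becomes IdU-positive; any S-phase overlap with the BrdU
#' window `[t_idu, t_idu + t_brdu]` makes it BrdU-positive (incorporation
#' is treated as instantaneous). Quiescent cells are never labelled. Cells
#' that complete mitosis during the window wrap to position 0 as a single
#' cell: over a window of ~2 h the growth of a population with a 20-34 h
#' cycle is negligible, and keeping counts conserved keeps the labelling
#' ratios exact.
#'
#' The asynchronous steady state makes the initial IdU-labelled cohort exit
#' S phase at a constant rate during the IdU-only window; the cells that
#' left (IdU+BrdU-) are the "leaving cells" and those still in S at the end
#' (IdU+BrdU+) the "S cells", whose ratio estimates `t_idu / t_s`.
#'
#' @param pop A `cell_population` from [simulate_population()].
#' @param schedule A [pulse_schedule()].
#' @return The population tibble with logical columns `idu` and `brdu`
#'   appended and `cycle_position` / `phase` advanced to the end of the
#'   labelling window (class `labeled_population`).
#' @export
apply_dual_pulse <- function(pop, schedule = pulse_schedule()) {
  if (!inherits(pop, "cell_population")) {
    stop("`pop` must be a cell_population from simulate_population()",
         call. = FALSE)
  }
  if (!inherits(schedule, "pulse_schedule")) {
    stop("`schedule` must be created with pulse_schedule()", call. = FALSE)
  }
  total <- schedule$t_idu + schedule$t_brdu
  cycling <- pop$phase != "quiescent"
  if (any(cycling) && total > min(pop$cell_cycle_length[cycling])) {
    stop("labelling window (", total, " h) exceeds the shortest cell ",
         "cycle; the single-wrap assumption of the virtual pulse is ",
         "violated", call. = FALSE)
  }
  s0 <- pop$t_g1_cell
  s1 <- pop$t_g1_cell + pop$t_s_cell
  p <- pop$cycle_position
  len <- pop$cell_cycle_length
  idu <- interval_hits_s(p, p + schedule$t_idu, s0, s1, len) & cycling
  brdu <- interval_hits_s(p + schedule$t_idu, p + total, s0, s1, len) &
    cycling
  out <- pop
  newpos <- (p + total) %% len
  out$cycle_position[cycling] <- newpos[cycling]
  newphase <- ifelse(newpos < s0, "G1", ifelse(newpos < s1, "S", "G2M"))
  out$phase[cycling] <- newphase[cycling]
  out$idu <- idu
  out$brdu <- brdu
  class(out) <- unique(c("labeled_population", class(out)))
  attr(out, "schedule") <- schedule
  out
}

#' Count leaving cells and S cells after a dual pulse
#'
#' Tallies the two labelled classes used by the S-phase duration estimator:
#' leaving cells (`l_cells`, IdU+BrdU-: cells that exited S during the
#' IdU-only window) and S cells (`s_cells`, IdU+BrdU+: cells in S at the
#' end of the window). Cells that entered S only after the IdU pulse
#' (IdU-BrdU+) belong to neither class and are excluded.
#'
#' @param labels A `labeled_population` from [apply_dual_pulse()], or any
#'   data frame with logical `idu` and `brdu` columns.
#' @param schedule The [pulse_schedule()] used; its `t_idu` is carried as
#'   the labelling window `t_i` of the counts.
#' @return A [labeling_counts()] object.
#' @export
count_labeling <- function(labels, schedule = attr(labels, "schedule")) {
  if (is.null(schedule)) schedule <- pulse_schedule()
  stopifnot(is.logical(labels$idu), is.logical(labels$brdu))
  labeling_counts(
    l_cells = sum(labels$idu & !labels$brdu),
    s_cells = sum(labels$idu & labels$brdu),
    t_i = schedule$t_idu
  )
}
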