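#' Cell-cycle phase durations
#'
#' Container for the durations of the G1, S and combined G2+M phases of the
#' cell cycle. The total cycle length `t_c` is derived as their sum and is
#' kept consistent by construction.
#'
#' @param t_g1,t_s,t_g2m Phase durations in hours; all strictly positive.
#'
#' @return An object of class `phase_durations`: a list with fields `t_g1`,
#'   `t_s`, `t_g2m` and the derived total `t_c = t_g1 + t_s + t_g2m`.
#' @examples
#' ph <- phase_durations(t_g1 = 10, t_s = 6, t_g2m = 4)
#' ph$t_c # 20
#' @export
phase_durations <- function(t_g1, t_s, t_g2m) {
  for (nm in c("t_g1", "t_s", "t_g2m")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop("`", nm, "` must be a single finite positive number (hours)",
           call. = FALSE)
    }
  }
  structure(
    list(t_g1 = t_g1, t_s = t_s, t_g2m = t_g2m, t_c = t_g1 + t_s + t_g2m),
    class = "phase_durations"
  )
}

#' @export
print.phase_durations <- function(x, ...) {
  cat(sprintf(
    "<phase_durations> G1 %.3g h | S %.3g h | G2M %.3g h | cycle %.3g h\n",
    x$t_g1, x$t_s, x$t_g2m, x$t_c
  ))
  invisible(x)
}

#' Simulation configuration for a cycling progenitor population
#'
#' Parameters for [simulate_population()]. The simulator realises a
#' steady-state asynchronous population: cells are spread across the cycle
#' rather than synchronised, so the expected fraction of cells in a phase
#' equals the ratio of that phase's duration to the total cycle length
#' (under `growth_mode = "uniform_position"`).
#'
#' @param phases A [phase_durations()] object.
#' @param n_cells Number of cells to simulate (>= 1).
#' @param quiescent_fraction Proportion of cells outside the cycle (Ki67-);
#'   in `[0, 1]`.
#' @param duration_cv Coefficient of variation of per-cell total cycle
#'   length (log-normal multiplicative jitter; phase boundaries scale
#'   proportionally). `0` gives identical cycle lengths.
#' @param growth_mode `"uniform_position"` (non-expanding steady state,
#'   positions uniform over the cycle) or `"exponential_age"` (expanding
#'   population, age density proportional to `2^(-a / t_c)`), useful for
#'   quantifying estimator bias under expansion.
#' @param tuj1_fraction Proportion of cells expressing the late-NPC /
#'   immature-neuron marker TUJ1.
#' @param seed Integer seed; the same configuration and seed always produce
#'   an identical population.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(phases,
                       n_cells,
                       quiescent_fraction = 0,
                       duration_cv = 0,
                       growth_mode = c("uniform_position", "exponential_age"),
                       tuj1_fraction = 0,
                       seed = 1L) {
  if (!inherits(phases, "phase_durations")) {
    stop("`phases` must be created with phase_durations()", call. = FALSE)
  }
  growth_mode <- match.arg(growth_mode)
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 1L) {
    stop("`n_cells` must be a positive integer", call. = FALSE)
  }
  stopifnot(
    is.numeric(quiescent_fraction), length(quiescent_fraction) == 1L,
    quiescent_fraction >= 0, quiescent_fraction <= 1,
    is.numeric(duration_cv), length(duration_cv) == 1L, duration_cv >= 0,
    is.numeric(tuj1_fraction), tuj1_fraction >= 0, tuj1_fraction <= 1
  )
  structure(
    list(
      phases = phases, n_cells = n_cells,
      quiescent_fraction = quiescent_fraction,
      duration_cv = duration_cv, growth_mode = growth_mode,
      tuj1_fraction = tuj1_fraction, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Dual-pulse labelling schedule
#'
#' Timing of the sequential IdU / BrdU exposure. During the first `t_idu`
#' hours only IdU is available (this is the window Ti of the S-phase
#' estimator); BrdU is then added for a further `t_brdu` hours. Cells that
#' leave S phase during the IdU-only window end up IdU+BrdU- ("leaving
#' cells"); cells still in S at the end are IdU+BrdU+ ("S cells").
#'
#' @param t_idu IdU-only window in hours (default 1.5).
#' @param t_brdu BrdU window in hours (default 0.5).
#' @return An object of class `pulse_schedule`.
#' @export
pulse_schedule <- function(t_idu = 1.5, t_brdu = 0.5) {
  stopifnot(
    is.numeric(t_idu), length(t_idu) == 1L, is.finite(t_idu), t_idu > 0,
    is.numeric(t_brdu), length(t_brdu) == 1L, is.finite(t_brdu), t_brdu > 0
  )
  structure(list(t_idu = t_idu, t_brdu = t_brdu), class = "pulse_schedule")
}

#' Gating configuration for flow-cytometry-like event tables
#'
#' Controls doublet exclusion, marker thresholds and DNA-content windows
#' used by [gate_events()].
#'
#' @param doublet_ratio_tolerance Relative tolerance around the median
#'   singlet area/height ratio; events outside `[1 - tol, 1 + tol]` times
#'   the median ratio (Hoechst first, then forward scatter) are excluded as
#'   doublets.
#' @param sox2_threshold,ki67_threshold,tuj1_threshold Positive numeric
#'   cutoffs, or `"auto"` for a two-class Otsu split of the log-intensity
#'   histogram. The defaults (100 a.u.) sit at the geometric midpoint of
#'   the synthetic negative (10 a.u.) and positive (1000 a.u.) intensity
#'   modes of [synthesize_flow_events()] and remain correct when a channel
#'   is single-moded (e.g. a fully quiescent, Ki67-negative population),
#'   where an automatic two-class split has nothing to separate.
#' @param dna_ref_2n Either `"auto"` (mode of the Hoechst-area density over
#'   cycling cells, taken as the 2n / G1 peak) or a positive number giving
#'   the Hoechst-area value corresponding to 2n DNA content.
#' @param dna_halfwidth Relative half-width of the 2n and 4n DNA-content
#'   windows (default 0.2, i.e. 2n +/- 20% and 4n +/- 20%); cells between
#'   the windows are scored as S phase.
#' @param s_phase_extension Logical; if `TRUE` (default) the S-phase count
#'   is extended into the 2n/4n windows by estimating the (uniform) S-phase
#'   event density from the inter-window band and reallocating the expected
#'   S tails out of the G1 and G2M windows. Hard rectangular windows on a
#'   continuous DNA-replication ramp otherwise systematically assign early-
#'   and late-S cells to G1/G2M, biasing downstream duration estimates.
#'
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(doublet_ratio_tolerance = 0.15,
                        sox2_threshold = 100,
                        ki67_threshold = 100,
                        tuj1_threshold = 100,
                        dna_ref_2n = "auto",
                        dna_halfwidth = 0.2,
                        s_phase_extension = TRUE) {
  chk_thr <- function(x, nm) {
    ok <- (is.character(x) && identical(x, "auto")) ||
      (is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0)
    if (!ok) stop("`", nm, "` must be \"auto\" or a positive number",
                  call. = FALSE)
  }
  stopifnot(
    is.numeric(doublet_ratio_tolerance), doublet_ratio_tolerance > 0,
    doublet_ratio_tolerance < 1,
    is.numeric(dna_halfwidth), dna_halfwidth > 0, dna_halfwidth < 1 / 3,
    is.logical(s_phase_extension), length(s_phase_extension) == 1L
  )
  chk_thr(sox2_threshold, "sox2_threshold")
  chk_thr(ki67_threshold, "ki67_threshold")
  chk_thr(tuj1_threshold, "tuj1_threshold")
  chk_thr(dna_ref_2n, "dna_ref_2n")
  structure(
    list(
      doublet_ratio_tolerance = doublet_ratio_tolerance,
      sox2_threshold = sox2_threshold,
      ki67_threshold = ki67_threshold,
      tuj1_threshold = tuj1_threshold,
      dna_ref_2n = dna_ref_2n,
      dna_halfwidth = dna_halfwidth,
      s_phase_extension = s_phase_extension
    ),
    class = "gate_config"
  )
}
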