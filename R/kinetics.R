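#' Construct IdU/BrdU labelling counts
#'
#' Container for the two labelled classes of a sequential dual-pulse
#' experiment: leaving cells (`l_cells`, IdU+BrdU-) and S cells (`s_cells`,
#' IdU+BrdU+), together with the IdU-only window `t_i` in hours.
#'
#' @param l_cells,s_cells Non-negative integer counts.
#' @param t_i IdU-only window in hours (> 0), 1.5 h in the standard
#'   protocol.
#' @return An object of class `labeling_counts`.
#' @export
labeling_counts <- function(l_cells, s_cells, t_i = 1.5) {
  stopifnot(
    is.numeric(l_cells), length(l_cells) == 1L, is.finite(l_cells),
    l_cells >= 0, l_cells == round(l_cells),
    is.numeric(s_cells), length(s_cells) == 1L, is.finite(s_cells),
    s_cells >= 0, s_cells == round(s_cells),
    is.numeric(t_i), length(t_i) == 1L, is.finite(t_i), t_i > 0
  )
  structure(
    list(l_cells = as.integer(l_cells), s_cells = as.integer(s_cells),
         t_i = t_i),
    class = "labeling_counts"
  )
}

#' Estimate the S-phase duration from dual-pulse labelling
#'
#' In an asynchronous steady-state population the ratio of the durations of
#' two cell-cycle compartments equals the ratio of the cell numbers found
#' in them. The IdU-only window `t_i` and the S phase are two such
#' compartments: cells that exited S during the window (leaving cells,
#' IdU+BrdU-) stand to cells still in S (IdU+BrdU+) as `t_i` stands to
#' `t_s`, so
#' \deqn{T_s = T_i \cdot S_{cells} / L_{cells}.}
#'
#' @param lab A [labeling_counts()] object.
#' @return The S-phase duration in hours.
#' @examples
#' estimate_ts(labeling_counts(l_cells = 50, s_cells = 200, t_i = 1.5)) # 6
#' @export
estimate_ts <- function(lab) {
  stopifnot(inherits(lab, "labeling_counts"))
  if (lab$l_cells == 0L) {
    stop("l_cells is 0: no cells left S phase during the IdU-only window, ",
         "so t_s is unidentifiable (infinite estimate)", call. = FALSE)
  }
  if (lab$s_cells == 0L) {
    stop("s_cells is 0: no IdU+BrdU+ cells, so t_s cannot be estimated",
         call. = FALSE)
  }
  lab$t_i * lab$s_cells / lab$l_cells
}

#' Estimate the total cell-cycle length from flow phase counts
#'
#' The S-phase duration stands to the total cycle length as the number of
#' S-phase cells stands to the whole proliferative pool:
#' \deqn{T_c = T_s \cdot P_{cells} / S_{cells}^{flow}.}
#' `S_cells` here is the flow-cytometric DNA-content S count, a different
#' measurement from the imaging-derived `s_cells` of [estimate_ts()]; the
#' two are deliberately never conflated.
#'
#' @param t_s S-phase duration in hours (> 0), typically from
#'   [estimate_ts()].
#' @param flow A [flow_counts()] object.
#' @return The total cell-cycle length in hours.
#' @export
estimate_tc <- function(t_s, flow) {
  stopifnot(is.numeric(t_s), length(t_s) == 1L, is.finite(t_s), t_s > 0,
            inherits(flow, "flow_counts"))
  if (flow$n_s_flow == 0L) {
    stop("n_s_flow is 0: cannot scale t_s to the full cycle", call. = FALSE)
  }
  if (flow$n_pcells < flow$n_s_flow) {
    stop("inconsistent counts: n_pcells < n_s_flow", call. = FALSE)
  }
  t_s * flow$n_pcells / flow$n_s_flow
}

#' Estimate the G1 duration from flow phase counts
#'
#' The fraction of the proliferative pool found in G1 times the total
#' cycle length:
#' \deqn{T_{G1} = T_c \cdot G1_{cells} / P_{cells}.}
#'
#' @param t_c Total cycle length in hours (> 0).
#' @param flow A [flow_counts()] object.
#' @return A number with (possibly empty) character attribute `flags`.
#' @export
estimate_tg1 <- function(t_c, flow) {
  stopifnot(is.numeric(t_c), length(t_c) == 1L, is.finite(t_c), t_c > 0,
            inherits(flow, "flow_counts"))
  if (flow$n_pcells == 0L) {
    stop("n_pcells is 0: empty proliferative pool", call. = FALSE)
  }
  flags <- character()
  if (flow$n_g1 == 0L) flags <- c(flags, "zero_g1_count")
  if (flow$n_g1 == flow$n_pcells) {
    flags <- c(flags, "all_cells_in_g1_implies_ts_tg2m_zero")
  }
  structure(t_c * flow$n_g1 / flow$n_pcells, flags = flags)
}

#' Estimate the combined G2+M duration by subtraction
#'
#' \deqn{T_{G2M} = T_c - T_s - T_{G1}.}
#' With noisy counts the subtraction can go negative; by default the
#' negative value is kept and flagged rather than silently clipped, so that
#' inconsistent inputs remain visible. Set `clip_negative = TRUE` to clamp
#' at zero (still flagged).
#'
#' @param t_c,t_s,t_g1 Durations in hours.
#' @param clip_negative Clamp negative results to 0 (default `FALSE`).
#' @return A number with character attribute `flags`.
#' @export
estimate_tg2m <- function(t_c, t_s, t_g1, clip_negative = FALSE) {
  vals <- c(t_c, t_s, t_g1)
  if (any(!is.finite(vals))) {
    stop("t_c, t_s and t_g1 must all be finite", call. = FALSE)
  }
  out <- t_c - t_s - t_g1
  flags <- character()
  if (out < 0) {
    flags <- "negative_tg2m"
    if (clip_negative) {
      out <- 0
      flags <- c(flags, "clipped_to_zero")
    }
  }
  structure(out, flags = flags)
}

#' Estimate all cell-cycle phase durations for one organoid
#'
#' Chains the four estimators: `t_s` from the dual-pulse counts, `t_c` from
#' the flow S/P ratio, `t_g1` from the flow G1/P ratio, and `t_g2m` by
#' subtraction. The additive identity `t_g1 + t_s + t_g2m == t_c` holds
#' exactly by construction. Warnings raised by individual steps are
#' collected in the `flags` field.
#'
#' @param lab A [labeling_counts()] object.
#' @param flow A [flow_counts()] object.
#' @param clip_negative_tg2m Passed to [estimate_tg2m()].
#' @return An object of class `cell_cycle_estimate`: a list with fields
#'   `t_s`, `t_c`, `t_g1`, `t_g2m` (hours) and `flags` (character vector).
#' @examples
#' est <- estimate_all(
#'   labeling_counts(l_cells = 50, s_cells = 200, t_i = 1.5),
#'   flow_counts(20000, 15000, 12000, 6000, 3000, 3000)
#' )
#' unlist(est[c("t_s", "t_c", "t_g1", "t_g2m")]) # 6 24 12 6
#' @export
estimate_all <- function(lab, flow, clip_negative_tg2m = FALSE) {
  if (isTRUE(attr(flow, "flagged"))) {
    stop("flow counts are flagged (degenerate gating, e.g. empty ",
         "proliferative pool); refusing to estimate", call. = FALSE)
  }
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  t_s <- step("estimate_ts", estimate_ts(lab))
  t_c <- step("estimate_tc", estimate_tc(t_s, flow))
  t_g1 <- step("estimate_tg1", estimate_tg1(t_c, flow))
  t_g2m <- step("estimate_tg2m",
                estimate_tg2m(t_c, t_s, as.numeric(t_g1),
                              clip_negative = clip_negative_tg2m))
  flags <- c(attr(t_g1, "flags"), attr(t_g2m, "flags"))
  structure(
    list(t_s = t_s, t_c = t_c, t_g1 = as.numeric(t_g1),
         t_g2m = as.numeric(t_g2m), flags = flags %||% character()),
    class = "cell_cycle_estimate"
  )
}

#' @export
print.cell_cycle_estimate <- function(x, ...) {
  cat(sprintf(
    "<cell_cycle_estimate> Tc %.2f h = G1 %.2f + S %.2f + G2M %.2f%s\n",
    x$t_c, x$t_g1, x$t_s, x$t_g2m,
    if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ", "), "]")
    else ""
  ))
  invisible(x)
}

#' Proliferation fractions from gated flow counts
#'
#' Summaries of progenitor state used alongside the kinetics: the
#' proliferative pool as a fraction of all SOX2+ cells
#' (`prolif_pool_frac`), proliferating late neurogenic NPCs as a fraction
#' of SOX2+ cells (`late_npc_frac`), and the ratio of proliferating late
#' (TUJ1+Ki67+) to early (SOX2+Ki67+) progenitors (`late_to_early`).
#'
#' @param flow A [flow_counts()] object with `n_sox2 > 0`.
#' @return A list with fields `prolif_pool_frac`, `late_npc_frac` and
#'   `late_to_early` (the last is `NA` with a flag when the proliferative
#'   pool is empty).
#' @export
proliferation_fractions <- function(flow) {
  stopifnot(inherits(flow, "flow_counts"))
  if (flow$n_sox2 == 0L) {
    stop("n_sox2 is 0: proliferation fractions undefined", call. = FALSE)
  }
  late_to_early <- if (flow$n_pcells > 0L) {
    flow$n_tuj1_ki67 / flow$n_pcells
  } else {
    NA_real_
  }
  structure(
    list(
      prolif_pool_frac = flow$n_pcells / flow$n_sox2,
      late_npc_frac = flow$n_tuj1_ki67 / flow$n_sox2,
      late_to_early = late_to_early
    ),
    flags = if (flow$n_pcells == 0L) "empty_proliferative_pool"
            else character()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
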