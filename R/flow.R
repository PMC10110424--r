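# Arbitrary-unit intensity scales of the event synthesiser. One Hoechst
# unit per n of DNA content (2n -> 2 units); marker-negative and -positive
# modes at 10 and 1000 a.u., separated far enough that default gates and
# Otsu splits agree at realistic noise.
.DNA_2N <- 2
.MARKER_NEG <- 10
.MARKER_POS <- 1000
.FSC_SINGLET <- 100

#' Construct gated flow-cytometry phase counts
#'
#' Validated container for the event counts produced by [gate_events()] (or
#' entered from a real pre-gated dataset): total singlets, SOX2+ cells, the
#' proliferative pool (SOX2+Ki67+, `n_pcells`), its split into G1 / S / G2M
#' by DNA content, and TUJ1+Ki67+ late neurogenic progenitors.
#'
#' @param n_total_singlets,n_sox2,n_pcells,n_g1,n_s_flow,n_g2m,n_tuj1_ki67
#'   Non-negative counts. `n_pcells <= n_sox2 <= n_total_singlets` and
#'   `n_g1 + n_s_flow + n_g2m == n_pcells` are enforced.
#' @param flagged Logical; marks a degenerate gating result (e.g. an empty
#'   proliferative pool) so downstream estimators can refuse cleanly.
#' @return An object of class `flow_counts`.
#' @export
flow_counts <- function(n_total_singlets, n_sox2, n_pcells,
                        n_g1, n_s_flow, n_g2m, n_tuj1_ki67 = 0,
                        flagged = FALSE) {
  cnt <- c(
    n_total_singlets = n_total_singlets, n_sox2 = n_sox2,
    n_pcells = n_pcells, n_g1 = n_g1, n_s_flow = n_s_flow,
    n_g2m = n_g2m, n_tuj1_ki67 = n_tuj1_ki67
  )
  if (any(!is.finite(cnt)) || any(cnt < 0)) {
    stop("all flow counts must be finite and non-negative", call. = FALSE)
  }
  if (n_pcells > n_sox2 || n_sox2 > n_total_singlets) {
    stop("flow counts must satisfy n_pcells <= n_sox2 <= n_total_singlets",
         call. = FALSE)
  }
  if (n_g1 + n_s_flow + n_g2m != n_pcells) {
    stop("phase counts must satisfy n_g1 + n_s_flow + n_g2m == n_pcells",
         call. = FALSE)
  }
  structure(as.list(cnt), flagged = isTRUE(flagged), class = "flow_counts")
}

#' @export
print.flow_counts <- function(x, ...) {
  cat(sprintf(
    paste0("<flow_counts> singlets %d | SOX2+ %d | P (SOX2+Ki67+) %d ",
           "[G1 %d / S %d / G2M %d] | TUJ1+Ki67+ %d%s\n"),
    x$n_total_singlets, x$n_sox2, x$n_pcells, x$n_g1, x$n_s_flow,
    x$n_g2m, x$n_tuj1_ki67,
    if (isTRUE(attr(x, "flagged"))) " (FLAGGED)" else ""
  ))
  invisible(x)
}

# multiplicative log-normal noise factors with mean 1 and the given CV
lnorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Synthesize a flow-cytometry-like event table from a cell population
#'
#' Produces per-event fluorescence channels mimicking a DNA-content /
#' marker panel: Hoechst area centred on DNA content (2 units at 2n for
#' G1/quiescent cells, 4 at 4n for G2M, a linear ramp across S by
#' replication progress), Hoechst height on the same scale, forward scatter,
#' and SOX2 / Ki67 / TUJ1 intensities drawn from well-separated negative
#' (10 a.u.) and positive (1000 a.u.) modes. All channels carry
#' multiplicative log-normal noise of coefficient of variation `noise_cv`.
#'
#' Each cell yields one event; with probability `doublet_fraction` an event
#' is instead recorded as a coincident doublet, summing its Hoechst area
#' with that of a second random cell while its Hoechst height (and forward-
#' scatter height) stays at single-cell scale — the pulse-geometry signature
#' used for doublet discrimination. Truth columns (`phase`, `is_doublet`)
#' are retained for testing and are ignored by [gate_events()].
#'
#' @param pop A `cell_population` (optionally pulsed).
#' @param noise_cv Coefficient of variation of the measurement noise.
#' @param doublet_fraction Probability that an event is a doublet, in
#'   `[0, 1)`.
#' @param seed Integer seed; fixed seed gives an identical table.
#' @return A tibble of class `event_table` with columns `hoechst_area`,
#'   `hoechst_height`, `fsc_area`, `fsc_height`, `sox2_intensity`,
#'   `ki67_intensity`, `tuj1_intensity`, `phase`, `is_doublet`.
#' @export
synthesize_flow_events <- function(pop, noise_cv = 0.05,
                                   doublet_fraction = 0.02, seed = 1L) {
  if (!inherits(pop, "cell_population") || nrow(pop) == 0L) {
    stop("`pop` must be a non-empty cell_population", call. = FALSE)
  }
  stopifnot(
    is.numeric(noise_cv), noise_cv >= 0,
    is.numeric(doublet_fraction), doublet_fraction >= 0,
    doublet_fraction < 1
  )
  n <- nrow(pop)
  s_frac <- pmin(pmax(
    (pop$cycle_position - pop$t_g1_cell) / pop$t_s_cell, 0), 1)
  dna <- ifelse(pop$phase %in% c("G1", "quiescent"), .DNA_2N,
    ifelse(pop$phase == "G2M", 2 * .DNA_2N, .DNA_2N * (1 + s_frac)))
  marker_mode <- function(pos) ifelse(pos, .MARKER_POS, .MARKER_NEG)
  withr::with_seed(seed, {
    is_doublet <- stats::runif(n) < doublet_fraction
    partner <- sample.int(n, n, replace = TRUE)
    area_base <- ifelse(is_doublet, dna + dna[partner], dna)
    height_base <- ifelse(is_doublet, pmax(dna, dna[partner]), dna)
    fsc_area_base <- .FSC_SINGLET * ifelse(is_doublet, 2, 1)
    out <- tibble::tibble(
      hoechst_area = area_base * lnorm_noise(n, noise_cv),
      hoechst_height = height_base * lnorm_noise(n, noise_cv),
      fsc_area = fsc_area_base * lnorm_noise(n, noise_cv),
      fsc_height = .FSC_SINGLET * lnorm_noise(n, noise_cv),
      sox2_intensity = marker_mode(pop$sox2) * lnorm_noise(n, noise_cv),
      ki67_intensity = marker_mode(pop$ki67) * lnorm_noise(n, noise_cv),
      tuj1_intensity = marker_mode(pop$tuj1) * lnorm_noise(n, noise_cv),
      phase = ifelse(is_doublet, NA_character_, pop$phase),
      is_doublet = is_doublet
    )
  })
  class(out) <- c("event_table", class(out))
  out
}

#' Otsu two-class threshold on log intensities
#'
#' Splits a positive-valued intensity channel into two classes by
#' maximising the between-class variance of the log-intensity histogram.
#' Requires a genuinely bimodal channel; on a unimodal channel the split is
#' arbitrary, which is why numeric thresholds are the [gate_config()]
#' default for channels whose scale is known.
#'
#' @param x Positive intensities.
#' @param n_bins Number of histogram bins.
#' @return The threshold on the original intensity scale.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x) & x > 0]
  if (length(x) < 2L || diff(range(x)) == 0) {
    stop("otsu_threshold() needs a channel with spread", call. = FALSE)
  }
  lx <- log(x)
  h <- graphics::hist(lx, breaks = n_bins, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  exp(mids[which.max(sigma_b)])
}

resolve_threshold <- function(value, x) {
  if (identical(value, "auto")) otsu_threshold(x) else value
}

# allocate a non-negative real vector to integers preserving the total
round_preserve_sum <- function(x, total) {
  x <- pmax(x, 0)
  if (sum(x) == 0) return(c(total, rep(0L, length(x) - 1L)))
  x <- x / sum(x) * total
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    idx <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  as.integer(fl)
}

#' Gate a flow event table into phase counts
#'
#' Reproduces a standard DNA-content gating scheme: doublets are excluded
#' first on Hoechst area-versus-height pulse geometry, then on forward
#' scatter; SOX2+, Ki67+ and TUJ1+ events are called by per-channel
#' thresholds; and the proliferative pool (SOX2+Ki67+) is split by DNA
#' content into G1 (within the 2n window), G2M (within the 4n window) and
#' S (between). With the default `s_phase_extension` the S count is
#' extended under the 2n/4n windows by estimating the uniform S-phase event
#' density from the inter-window band, removing the systematic loss of
#' early- and late-S cells into the G1/G2M windows.
#'
#' @param events An `event_table` (truth columns, if present, are ignored).
#' @param gates A [gate_config()].
#' @return A [flow_counts()]; if gating leaves an empty proliferative pool
#'   the result is flagged (see [flow_counts()]) rather than failing, so
#'   callers can decide how to treat the organoid.
#' @export
gate_events <- function(events, gates = gate_config()) {
  if (!is.data.frame(events) || nrow(events) == 0L) {
    stop("`events` must be a non-empty event table", call. = FALSE)
  }
  req <- c("hoechst_area", "hoechst_height", "fsc_area", "fsc_height",
           "sox2_intensity", "ki67_intensity", "tuj1_intensity")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols)) {
    stop("event table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!inherits(gates, "gate_config")) {
    stop("`gates` must be created with gate_config()", call. = FALSE)
  }
  tol <- gates$doublet_ratio_tolerance
  within_tol <- function(ratio) {
    med <- stats::median(ratio)
    ratio >= med * (1 - tol) & ratio <= med * (1 + tol)
  }
  singlet <- within_tol(events$hoechst_area / events$hoechst_height)
  ev <- events[singlet, , drop = FALSE]
  if (nrow(ev) == 0L) {
    stop("doublet exclusion removed every event; no singlets to gate",
         call. = FALSE)
  }
  keep_fsc <- within_tol(ev$fsc_area / ev$fsc_height)
  ev <- ev[keep_fsc, , drop = FALSE]
  if (nrow(ev) == 0L) {
    stop("forward-scatter doublet exclusion removed every event",
         call. = FALSE)
  }

  sox2 <- ev$sox2_intensity > resolve_threshold(gates$sox2_threshold,
                                                ev$sox2_intensity)
  ki67 <- ev$ki67_intensity > resolve_threshold(gates$ki67_threshold,
                                                ev$ki67_intensity)
  tuj1 <- ev$tuj1_intensity > resolve_threshold(gates$tuj1_threshold,
                                                ev$tuj1_intensity)
  pcell <- sox2 & ki67
  n_p <- sum(pcell)

  if (n_p == 0L) {
    return(flow_counts(
      n_total_singlets = nrow(ev), n_sox2 = sum(sox2), n_pcells = 0L,
      n_g1 = 0L, n_s_flow = 0L, n_g2m = 0L,
      n_tuj1_ki67 = sum(tuj1 & ki67), flagged = TRUE
    ))
  }

  dna <- ev$hoechst_area[pcell]
  ref <- gates$dna_ref_2n
  if (identical(ref, "auto")) {
    # the 2n (G1) peak is the leftmost prominent density peak, not
    # necessarily the global mode: a G2M-heavy organoid has its tallest
    # peak at 4n
    d <- stats::density(dna, n = 512)
    pk <- which(diff(sign(diff(d$y))) == -2) + 1L
    pk <- pk[d$y[pk] >= 0.25 * max(d$y)]
    ref <- if (length(pk)) d$x[min(pk)] else d$x[which.max(d$y)]
  }
  w <- gates$dna_halfwidth
  g1_raw <- sum(dna <= ref * (1 + w))
  g2m_raw <- sum(dna >= 2 * ref * (1 - w))
  s_raw <- n_p - g1_raw - g2m_raw

  if (gates$s_phase_extension && s_raw > 0) {
    # S events are uniform in DNA over [ref, 2*ref]; the band between the
    # windows has width ref*(1 - 3w), so density lambda = s_raw / that.
    # Expected S tails inside the windows: lambda*ref*w (G1 side, ramp
    # starts at the 2n centre) and lambda*2*ref*w (G2M side).
    lambda_w <- s_raw * w / (1 - 3 * w)   # = lambda * ref * w
    counts <- round_preserve_sum(
      c(g1_raw - lambda_w, s_raw + 3 * lambda_w, g2m_raw - 2 * lambda_w),
      n_p
    )
  } else {
    counts <- as.integer(c(g1_raw, s_raw, g2m_raw))
  }

  flow_counts(
    n_total_singlets = nrow(ev),
    n_sox2 = sum(sox2),
    n_pcells = n_p,
    n_g1 = counts[1], n_s_flow = counts[2], n_g2m = counts[3],
    n_tuj1_ki67 = sum(tuj1 & ki67),
    flagged = FALSE
  )
}
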