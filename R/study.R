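#' Multi-batch, multi-line organoid study design
#'
#' Describes which cell lines are grown in which differentiation batches
#' and how many organoids each contributes. The default mirrors a
#' four-control / three-deletion isogenic panel grown across four batches,
#' every batch containing at least one control and one deletion line, with
#' line replication varying between two and four batches and 12 organoids
#' per line per batch; an additional late batch of one control and one
#' deletion line supplies qPCR samples.
#'
#' @param lines A data frame with columns `line_id` and `genotype`
#'   (`"control"` / `"deletion"`).
#' @param batches Named list: for each batch id, the character vector of
#'   line ids grown in it. Every batch must contain at least one control
#'   and one deletion line.
#' @param organoids_per_line Organoids per line per batch (4 to 15).
#' @param days Imaging days for the growth series.
#' @param kinetics_day Day at which labelling, flow cytometry and day-35
#'   morphometry are performed.
#' @param seed Integer seed driving every random draw of
#'   [generate_study()].
#' @return An object of class `study_design`.
#' @export
study_design <- function(
    lines = tibble::tibble(
      line_id = c("FACS51", "FACS52", "FACS53", "GM8",
                  "DELD5", "DELA3", "DELB8"),
      genotype = c(rep("control", 4), rep("deletion", 3))
    ),
    batches = list(
      RF1 = c("FACS51", "FACS53", "DELD5", "DELA3"),
      RF2 = c("FACS52", "FACS53", "DELD5", "DELB8"),
      RF3 = c("FACS51", "GM8", "FACS53", "DELD5"),
      RF4 = c("FACS52", "GM8", "DELD5", "DELA3", "DELB8")
    ),
    organoids_per_line = 12L,
    days = c(5L, 10L, 15L, 20L, 25L),
    kinetics_day = 35L,
    seed = 1L) {
  stopifnot(
    is.data.frame(lines), all(c("line_id", "genotype") %in% names(lines)),
    all(lines$genotype %in% c("control", "deletion")),
    is.list(batches), length(batches) >= 1L, !is.null(names(batches))
  )
  organoids_per_line <- as.integer(organoids_per_line)
  if (organoids_per_line < 4L || organoids_per_line > 15L) {
    stop("`organoids_per_line` must be between 4 and 15", call. = FALSE)
  }
  geno <- stats::setNames(lines$genotype, lines$line_id)
  for (b in names(batches)) {
    unknown <- setdiff(batches[[b]], lines$line_id)
    if (length(unknown)) {
      stop("batch ", b, " references unknown line(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    g <- geno[batches[[b]]]
    if (!all(c("control", "deletion") %in% g)) {
      stop("batch ", b, " must contain at least one control and one ",
           "deletion line", call. = FALSE)
    }
  }
  structure(
    list(lines = lines, batches = batches,
         organoids_per_line = organoids_per_line,
         days = as.integer(days), kinetics_day = as.integer(kinetics_day),
         seed = as.integer(seed)),
    class = "study_design"
  )
}

#' Flow-cytometry-scale study design
#'
#' A smaller companion to the default [study_design()], mirroring the
#' scale of a per-organoid flow-cytometric kinetics dataset: three control
#' and two deletion lines spread over four batches (every batch with at
#' least one of each genotype, the deletion line DELD5 replicated in all
#' four), four organoids per line per batch, roughly fifty organoids in
#' total. Useful when the question is whether an effect of realistic size
#' is detectable at realistic per-genotype organoid numbers.
#'
#' @param seed Integer seed for [generate_study()].
#' @param organoids_per_line Organoids per line per batch (default 4).
#' @return A [study_design()].
#' @export
flow_study_design <- function(seed = 1L, organoids_per_line = 4L) {
  study_design(
    lines = tibble::tibble(
      line_id = c("FACS51", "FACS52", "FACS53", "DELD5", "DELA3"),
      genotype = c("control", "control", "control",
                   "deletion", "deletion")
    ),
    batches = list(
      RF1 = c("FACS51", "FACS53", "DELD5"),
      RF2 = c("FACS52", "FACS53", "DELD5", "DELA3"),
      RF3 = c("FACS51", "FACS53", "DELD5"),
      RF4 = c("FACS52", "DELD5", "DELA3")
    ),
    organoids_per_line = organoids_per_line,
    seed = seed
  )
}

#' Effect model for synthetic organoid studies
#'
#' Parameterises how genotype and batch act on every generated variable:
#' baseline means, deletion mean shifts, batch random effects, organoid-
#' level noise, and -- the signature phenotype -- deletion variance
#' inflation. An inflation factor `f >= 1` makes the total deletion
#' variance of a variable converge to `f` times the control variance, and
#' is applied jointly at the batch level (a batch-by-genotype random
#' deviation with variance `(f - 1) * batch_sd^2`) and at the organoid
#' level (organoid noise scaled by `sqrt(f)`), so that deletion
#' variability localises between batches of deletion organoids rather than
#' between deletion lines.
#'
#' Phase-duration defaults are anchored to a control total cycle length of
#' 20.1 h (G1 10.0, S 6.0, G2M 4.1) and a deletion total of 33.8 h, the
#' shift acting on G1 (+9.8 h) and G2M (+3.4 h) with only a small S shift
#' (+0.5 h) that sits near the detection limit at realistic per-genotype
#' organoid numbers. Growth follows a log-normal multiplicative curve per
#' 5-day interval.
#'
#' @param area_day5 Mean organoid area at day 5 (mm^2).
#' @param area_growth_per_interval Multiplicative growth per 5-day
#'   interval.
#' @param area_cv Organoid-level CV of area.
#' @param area_batch_sd Batch intercept SD of log area.
#' @param area_inflation Deletion variance inflation for area from
#'   `area_inflation_from_day` on.
#' @param area_inflation_from_day First day at which deletion area
#'   variance is inflated.
#' @param rosette_mean,rosette_shift,rosette_sd,rosette_batch_sd,rosette_inflation
#'   Relative rosette area: control mean, deletion mean shift, organoid
#'   SD, batch intercept SD, deletion variance inflation.
#' @param couptfii_mean,couptfii_shift,couptfii_sd,couptfii_batch_sd,couptfii_inflation
#'   COUPTFII+ areal density (cells per mm^2), same roles.
#' @param intensity_mean,intensity_shift,intensity_sd,intensity_batch_sd,intensity_inflation
#'   Relative mean fluorescence intensity (TUJ1, GAD67), same roles.
#' @param phases_control Control [phase_durations()].
#' @param phase_shifts Deletion mean shift per phase, hours (named:
#'   `t_g1`, `t_s`, `t_g2m`).
#' @param phase_sd Organoid-level SD per phase, hours (same names).
#' @param phase_batch_sd Batch intercept SD applied to each phase, hours.
#' @param phase_inflation Deletion variance inflation per phase (same
#'   names; S defaults to no inflation).
#' @param quiescent_fraction,tuj1_fraction Population composition passed
#'   to the cell-level simulator.
#' @param n_cells_flow Cells simulated per organoid for the virtual
#'   labelling / flow experiment.
#' @param noise_cv,doublet_fraction Event-synthesis noise and doublet
#'   rate.
#' @param qpcr_genes Named list: per target gene, the deletion delta-Ct
#'   shift (negative = higher expression).
#' @param qpcr_ct_sd Sample-level Ct SD.
#' @return An object of class `effect_model`.
#' @export
effect_model <- function(
    area_day5 = 0.35,
    area_growth_per_interval = 1.35,
    area_cv = 0.15,
    area_batch_sd = 0.08,
    area_inflation = 4,
    area_inflation_from_day = 15L,
    rosette_mean = 0.10, rosette_shift = 0.08,
    rosette_sd = 0.035, rosette_batch_sd = 0.02, rosette_inflation = 4,
    couptfii_mean = 250, couptfii_shift = 130,
    couptfii_sd = 60, couptfii_batch_sd = 35, couptfii_inflation = 4,
    intensity_mean = 40, intensity_shift = 18,
    intensity_sd = 8, intensity_batch_sd = 5, intensity_inflation = 3,
    phases_control = phase_durations(t_g1 = 10.0, t_s = 6.0, t_g2m = 4.1),
    phase_shifts = c(t_g1 = 9.8, t_s = 0.5, t_g2m = 3.4),
    phase_sd = c(t_g1 = 1.6, t_s = 1.2, t_g2m = 0.8),
    phase_batch_sd = 0.8,
    phase_inflation = c(t_g1 = 3, t_s = 1, t_g2m = 3),
    quiescent_fraction = 0.6,
    tuj1_fraction = 0.12,
    n_cells_flow = 5000L,
    noise_cv = 0.05,
    doublet_fraction = 0.02,
    qpcr_genes = list(NEUN = -1.0, LHX6 = 0, CALB1 = -0.8, RELN = 0.6),
    qpcr_ct_sd = 0.35) {
  stopifnot(
    inherits(phases_control, "phase_durations"),
    all(c("t_g1", "t_s", "t_g2m") %in% names(phase_shifts)),
    all(c("t_g1", "t_s", "t_g2m") %in% names(phase_sd)),
    all(c("t_g1", "t_s", "t_g2m") %in% names(phase_inflation)),
    all(phase_inflation >= 1), area_inflation >= 1,
    rosette_inflation >= 1, couptfii_inflation >= 1,
    intensity_inflation >= 1,
    area_batch_sd >= 0, rosette_batch_sd >= 0, couptfii_batch_sd >= 0,
    intensity_batch_sd >= 0, phase_batch_sd >= 0, qpcr_ct_sd >= 0
  )
  structure(as.list(environment()), class = "effect_model")
}

# batch-level and organoid-level draws for one variable under the
# variance-inflation model; returns organoid-level values
draw_variable <- function(n, deletion, batch_idx, mean0, shift,
                          sd_org, sd_batch, inflation,
                          batch_intercepts, batch_geno_dev) {
  mu <- mean0 + shift * deletion +
    batch_intercepts[batch_idx] * sd_batch +
    batch_geno_dev[batch_idx] * sqrt(pmax(inflation - 1, 0)) * sd_batch *
      deletion
  mu + stats::rnorm(n, 0, sd_org * ifelse(deletion, sqrt(inflation), 1))
}

#' Generate a full synthetic organoid study
#'
#' Draws a complete dataset bundle under a [study_design()] and an
#' [effect_model()]: a growth series of organoid areas, day-35
#' morphometry (relative rosette area, COUPTFII density, TUJ1/GAD67
#' relative intensity), per-organoid dual-pulse labelling counts and gated
#' flow counts produced by running the cell-level simulator
#' ([simulate_population()], [apply_dual_pulse()],
#' [synthesize_flow_events()], [gate_events()]) with per-organoid phase
#' durations drawn from the effect model, and a long-format qPCR table.
#' Batch effects are shared by all organoids of a batch; everything is
#' reproducible from `design$seed`.
#'
#' @param design A [study_design()].
#' @param effects An [effect_model()].
#' @return A list of class `study_bundle` with tibbles `growth`,
#'   `morphometry`, `kinetics` (labelling + flow counts + true phase
#'   durations per organoid) and `qpcr`, plus `design` and `effects`.
#' @export
generate_study <- function(design = study_design(),
                           effects = effect_model()) {
  stopifnot(inherits(design, "study_design"),
            inherits(effects, "effect_model"))
  geno <- stats::setNames(design$lines$genotype, design$lines$line_id)
  batch_ids <- names(design$batches)
  nb <- length(batch_ids)

  # organoid roster: one row per organoid per batch-line membership
  roster <- dplyr::bind_rows(lapply(batch_ids, function(b) {
    tibble::tibble(
      batch_id = b,
      line_id = rep(design$batches[[b]], each = design$organoids_per_line)
    )
  }))
  roster$genotype <- unname(geno[roster$line_id])
  roster$organoid_id <- sprintf("%s_%s_%02d", roster$batch_id,
                                roster$line_id,
                                stats::ave(seq_len(nrow(roster)),
                                           roster$batch_id, roster$line_id,
                                           FUN = seq_along))
  n_org <- nrow(roster)
  del <- roster$genotype == "deletion"
  bidx <- match(roster$batch_id, batch_ids)
  eff <- effects

  withr::with_seed(design$seed, {
    # shared batch random effects (standard-normal; scaled per variable)
    z_int <- matrix(stats::rnorm(nb * 8), nrow = nb)
    z_dev <- matrix(stats::rnorm(nb * 8), nrow = nb)

    # --- growth series -------------------------------------------------
    org_scale <- exp(stats::rnorm(
      n_org, 0,
      sqrt(log1p(eff$area_cv^2)) * ifelse(del, sqrt(eff$area_inflation), 1)
    ))
    growth <- dplyr::bind_rows(lapply(seq_along(design$days), function(k) {
      d <- design$days[k]
      base <- eff$area_day5 * eff$area_growth_per_interval^(k - 1)
      inflate_now <- del & d >= eff$area_inflation_from_day
      batch_eff <- exp(z_int[bidx, 1] * eff$area_batch_sd +
                         z_dev[bidx, 1] *
                           sqrt(max(eff$area_inflation - 1, 0)) *
                           eff$area_batch_sd * inflate_now)
      day_noise <- exp(stats::rnorm(n_org, 0,
                                    0.5 * sqrt(log1p(eff$area_cv^2))))
      scale_now <- ifelse(inflate_now, org_scale,
                          org_scale^(1 / ifelse(del,
                                                sqrt(eff$area_inflation),
                                                1)))
      tibble::tibble(
        organoid_id = roster$organoid_id, line_id = roster$line_id,
        genotype = roster$genotype, batch_id = roster$batch_id,
        day = d, area = base * batch_eff * scale_now * day_noise
      )
    }))

    # --- day-35 morphometry --------------------------------------------
    area35 <- eff$area_day5 * eff$area_growth_per_interval^
      ((design$kinetics_day - design$days[1]) / 5) *
      exp(z_int[bidx, 1] * eff$area_batch_sd) * org_scale
    rel_rosette <- pmin(pmax(draw_variable(
      n_org, del, bidx, eff$rosette_mean, eff$rosette_shift,
      eff$rosette_sd, eff$rosette_batch_sd, eff$rosette_inflation,
      z_int[, 2], z_dev[, 2]), 0), 1)
    couptfii_density <- pmax(draw_variable(
      n_org, del, bidx, eff$couptfii_mean, eff$couptfii_shift,
      eff$couptfii_sd, eff$couptfii_batch_sd, eff$couptfii_inflation,
      z_int[, 3], z_dev[, 3]), 0)
    tuj1_rel <- pmax(draw_variable(
      n_org, del, bidx, eff$intensity_mean, eff$intensity_shift,
      eff$intensity_sd, eff$intensity_batch_sd, eff$intensity_inflation,
      z_int[, 4], z_dev[, 4]), 0)
    gad67_rel <- pmax(draw_variable(
      n_org, del, bidx, eff$intensity_mean * 0.6,
      eff$intensity_shift * 0.6, eff$intensity_sd * 0.6,
      eff$intensity_batch_sd * 0.6, eff$intensity_inflation,
      z_int[, 5], z_dev[, 5]), 0)
    morphometry <- tibble::tibble(
      organoid_id = roster$organoid_id, line_id = roster$line_id,
      genotype = roster$genotype, batch_id = roster$batch_id,
      day = design$kinetics_day,
      area = area35,
      rosette_area = rel_rosette * area35,
      couptfii_count = round(couptfii_density * area35),
      tuj1_mean_intensity = tuj1_rel * area35,
      gad67_mean_intensity = gad67_rel * area35
    )

    # --- per-organoid true phase durations -----------------------------
    ph_true <- vapply(c("t_g1", "t_s", "t_g2m"), function(p) {
      col <- match(p, c("t_g1", "t_s", "t_g2m")) + 5L
      pmax(draw_variable(
        n_org, del, bidx, eff$phases_control[[p]],
        eff$phase_shifts[[p]], eff$phase_sd[[p]], eff$phase_batch_sd,
        eff$phase_inflation[[p]], z_int[, col], z_dev[, col]
      ), 0.5)
    }, numeric(n_org))

    org_seeds <- sample.int(.Machine$integer.max - 1L, n_org)
  })

  # --- virtual labelling + flow per organoid ---------------------------
  kin <- lapply(seq_len(n_org), function(i) {
    cfg <- sim_config(
      phase_durations(ph_true[i, "t_g1"], ph_true[i, "t_s"],
                      ph_true[i, "t_g2m"]),
      n_cells = eff$n_cells_flow,
      quiescent_fraction = eff$quiescent_fraction,
      tuj1_fraction = eff$tuj1_fraction,
      seed = org_seeds[i]
    )
    pop <- simulate_population(cfg)
    lab <- count_labeling(apply_dual_pulse(pop, pulse_schedule()))
    ev <- synthesize_flow_events(pop, noise_cv = eff$noise_cv,
                                 doublet_fraction = eff$doublet_fraction,
                                 seed = org_seeds[i])
    fc <- gate_events(ev, gate_config())
    tibble::tibble(
      organoid_id = roster$organoid_id[i], line_id = roster$line_id[i],
      genotype = roster$genotype[i], batch_id = roster$batch_id[i],
      day = design$kinetics_day,
      true_t_g1 = ph_true[i, "t_g1"], true_t_s = ph_true[i, "t_s"],
      true_t_g2m = ph_true[i, "t_g2m"],
      l_cells = lab$l_cells, s_cells = lab$s_cells, t_i = lab$t_i,
      n_total_singlets = fc$n_total_singlets, n_sox2 = fc$n_sox2,
      n_pcells = fc$n_pcells, n_g1 = fc$n_g1, n_s_flow = fc$n_s_flow,
      n_g2m = fc$n_g2m, n_tuj1_ki67 = fc$n_tuj1_ki67,
      gate_flagged = isTRUE(attr(fc, "flagged"))
    )
  })
  kinetics <- dplyr::bind_rows(kin)

  # --- qPCR: one late batch, one control + one deletion line -----------
  withr::with_seed(design$seed + 1L, {
    qpcr_lines <- c(
      design$lines$line_id[design$lines$genotype == "control"][1],
      design$lines$line_id[design$lines$genotype == "deletion"][1]
    )
    hk <- c("GAPDH", "ACTB")
    targets <- names(eff$qpcr_genes)
    qpcr <- dplyr::bind_rows(lapply(seq_along(qpcr_lines), function(i) {
      gt <- c("control", "deletion")[i]
      dplyr::bind_rows(lapply(1:5, function(s) {
        sid <- sprintf("RFq_%s_%02d", qpcr_lines[i], s)
        hk_ct <- 18 + stats::rnorm(2, 0, eff$qpcr_ct_sd)
        tibble::tibble(
          sample_id = sid, group = gt, line_id = qpcr_lines[i],
          gene = c(hk, targets),
          ct = c(hk_ct,
                 24 + unlist(eff$qpcr_genes) * (gt == "deletion") +
                   stats::rnorm(length(targets), 0, eff$qpcr_ct_sd))
        )
      }))
    }))
  })

  structure(
    list(growth = growth, morphometry = morphometry, kinetics = kinetics,
         qpcr = qpcr, design = design, effects = effects),
    class = "study_bundle"
  )
}

#' Deterministic worked-example fixture
#'
#' A small, fully deterministic bundle that exercises every reader and
#' estimator branch: a valid organoid whose counts give the hand-checkable
#' estimate (t_s = 6, t_c = 24, t_g1 = 12, t_g2m = 6 h), an organoid with
#' `l_cells = 0` (unidentifiable t_s, must raise), an organoid with an
#' empty G2M window (t_g2m = 0 boundary), and an all-G1 organoid (flagged
#' inconsistency). Under the flow-count partition invariant
#' (`n_g1 + n_s_flow + n_g2m == n_pcells`) the subtraction step satisfies
#' `t_g2m = t_s * n_g2m / n_s_flow >= 0`, so a negative t_g2m cannot arise
#' from a consistent count set; that branch of [estimate_tg2m()] is
#' reachable only with externally supplied, inconsistent durations.
#'
#' @return A tibble in the per-organoid kinetics CSV contract (columns
#'   `organoid_id`, `line_id`, `genotype`, `batch_id`, `l_cells`,
#'   `s_cells`, `t_i`, `n_total_singlets`, `n_sox2`, `n_pcells`, `n_g1`,
#'   `n_s_flow`, `n_g2m`, `n_tuj1_ki67`, `expect_error`).
#' @export
generate_worked_example <- function() {
  tibble::tibble(
    organoid_id = c("ORG_OK", "ORG_ZERO_L", "ORG_ZERO_G2M", "ORG_ALL_G1"),
    line_id = c("FACS51", "DELD5", "FACS52", "DELA3"),
    genotype = c("control", "deletion", "control", "deletion"),
    batch_id = c("RF1", "RF1", "RF2", "RF2"),
    l_cells = c(50L, 0L, 100L, 40L),
    s_cells = c(200L, 150L, 100L, 80L),
    t_i = 1.5,
    n_total_singlets = c(20000L, 8000L, 5000L, 4000L),
    n_sox2 = c(15000L, 6000L, 4000L, 3000L),
    n_pcells = c(12000L, 4000L, 2000L, 1000L),
    n_g1 = c(6000L, 2000L, 1500L, 1000L),
    n_s_flow = c(3000L, 1500L, 500L, 0L),
    n_g2m = c(3000L, 500L, 0L, 0L),
    n_tuj1_ki67 = c(1500L, 600L, 250L, 120L),
    expect_error = c(FALSE, TRUE, FALSE, TRUE)
  )
}
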