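kinetics_required_cols <- c(
  "organoid_id", "line_id", "genotype", "batch_id",
  "l_cells", "s_cells", "t_i",
  "n_total_singlets", "n_sox2", "n_pcells", "n_g1", "n_s_flow", "n_g2m",
  "n_tuj1_ki67"
)

#' Estimate cell-cycle durations for every organoid in a counts table
#'
#' Applies the full estimator chain ([estimate_all()]) row by row to a
#' per-organoid counts table (the kinetics CSV contract). Rows whose
#' counts violate a precondition (for example `l_cells == 0`) do not stop
#' the run: their durations are `NA` and the error message is recorded in
#' the `error` column, so one bad organoid costs one row, not the dataset.
#'
#' @param counts A data frame with at least the columns
#'   `organoid_id`, `line_id`, `genotype`, `batch_id`, `l_cells`,
#'   `s_cells`, `t_i`, `n_total_singlets`, `n_sox2`, `n_pcells`, `n_g1`,
#'   `n_s_flow`, `n_g2m`, `n_tuj1_ki67`.
#' @param clip_negative_tg2m Passed to [estimate_all()].
#' @return The input with columns `t_s`, `t_c`, `t_g1`, `t_g2m`, `flags`
#'   (semicolon-joined) and `error` appended.
#' @export
estimate_table <- function(counts, clip_negative_tg2m = FALSE) {
  missing_cols <- setdiff(kinetics_required_cols, names(counts))
  if (length(missing_cols)) {
    stop("counts table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(counts) == 0L) {
    stop("counts table is empty", call. = FALSE)
  }
  res <- lapply(seq_len(nrow(counts)), function(i) {
    row <- counts[i, ]
    tryCatch({
      est <- estimate_all(
        labeling_counts(row$l_cells, row$s_cells, row$t_i),
        flow_counts(row$n_total_singlets, row$n_sox2, row$n_pcells,
                    row$n_g1, row$n_s_flow, row$n_g2m, row$n_tuj1_ki67),
        clip_negative_tg2m = clip_negative_tg2m
      )
      tibble::tibble(
        t_s = est$t_s, t_c = est$t_c, t_g1 = est$t_g1, t_g2m = est$t_g2m,
        flags = paste(est$flags, collapse = ";"), error = NA_character_
      )
    }, error = function(e) {
      tibble::tibble(t_s = NA_real_, t_c = NA_real_, t_g1 = NA_real_,
                     t_g2m = NA_real_, flags = "",
                     error = conditionMessage(e))
    })
  })
  dplyr::bind_cols(counts, dplyr::bind_rows(res))
}

#' Simulate a study and write its dataset directory
#'
#' Runs [generate_study()] and writes the bundle as plain CSV files
#' (`growth.csv`, `morphometry.csv`, `kinetics.csv`, `qpcr.csv`) plus a
#' `manifest.yaml` recording the seed, design and package version, which
#' is sufficient to regenerate the directory bit-identically.
#'
#' @param out_dir Output directory (created if needed).
#' @param design A [study_design()].
#' @param effects An [effect_model()].
#' @return Invisibly, the list of file paths written.
#' @export
run_simulate <- function(out_dir, design = study_design(),
                         effects = effect_model()) {
  bundle <- generate_study(design, effects)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (nm in c("growth", "morphometry", "kinetics", "qpcr")) {
    paths[[nm]] <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(bundle[[nm]], paths[[nm]])
  }
  manifest <- list(
    tool = "orgcycle",
    version = as.character(utils::packageVersion("orgcycle")),
    seed = design$seed,
    organoids_per_line = design$organoids_per_line,
    days = design$days,
    kinetics_day = design$kinetics_day,
    lines = as.list(stats::setNames(design$lines$genotype,
                                    design$lines$line_id)),
    batches = design$batches
  )
  paths$manifest <- file.path(out_dir, "manifest.yaml")
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(manifest, paths$manifest)
  } else {
    writeLines(utils::capture.output(utils::str(manifest)),
               paths$manifest)
  }
  invisible(paths)
}

#' Estimate kinetics for a simulated or real dataset directory
#'
#' Reads the per-organoid counts table (`kinetics.csv`) from a dataset
#' directory written by [run_simulate()] (or assembled by hand to the same
#' contract) and applies [estimate_table()].
#'
#' @param input A dataset directory containing `kinetics.csv`, the path of
#'   a counts CSV, or a data frame already in the contract.
#' @param out Optional path: write the estimates CSV there.
#' @return The estimates tibble (invisibly if `out` is given).
#' @export
run_estimate <- function(input, out = NULL) {
  counts <- if (is.data.frame(input)) {
    input
  } else if (dir.exists(input)) {
    f <- file.path(input, "kinetics.csv")
    if (!file.exists(f)) {
      stop("dataset directory has no kinetics.csv", call. = FALSE)
    }
    readr::read_csv(f, show_col_types = FALSE)
  } else if (file.exists(input)) {
    readr::read_csv(input, show_col_types = FALSE)
  } else {
    stop("`input` is neither a data frame, a directory nor a file",
         call. = FALSE)
  }
  est <- estimate_table(counts)
  if (!is.null(out)) {
    readr::write_csv(est, out)
    return(invisible(est))
  }
  est
}

stat_battery_one <- function(values, genotype, batch, alpha = 0.05) {
  ok <- is.finite(values)
  values <- values[ok]; genotype <- genotype[ok]; batch <- batch[ok]
  a <- values[genotype == "deletion"]
  b <- values[genotype == "control"]
  welch <- welch_anova(values, genotype)
  fvar <- variance_ratio_test(a, b)
  lev <- levene_test(values, genotype)
  lme <- fit_genotype_lme(
    tibble::tibble(value = values, genotype = genotype, batch = batch),
    "value"
  )
  cd <- cliffs_delta(a, b)
  om <- omega_squared(stats::aov(values ~ factor(genotype)))
  tibble::tibble(
    n_control = length(b), n_deletion = length(a),
    mean_control = mean(b), mean_deletion = mean(a),
    var_ratio = stats::var(a) / stats::var(b),
    welch_p = welch$p_value,
    f_var_p = fvar$p_value,
    levene_p = lev$p_value,
    lme_estimate = lme$estimate,
    lme_p = lme$p_value,
    lme_random = lme$random_structure,
    cliffs_delta = cd$value,
    omega_squared = om$value,
    mean_significant = lme$p_value < alpha,
    variance_significant = fvar$p_value < alpha
  )
}

#' Genotype-effect statistical report for an organoid study
#'
#' Runs the full statistical battery per variable: Welch's ANOVA on
#' genotype means, the variance-ratio F-test and Levene's test on
#' genotype variability, the batch-aware mixed-effects contrast with a
#' type III test, Cliff's delta and omega-squared effect sizes. Kinetics
#' variables (`t_c`, `t_g1`, `t_s`, `t_g2m`) come from the estimates
#' table; morphometry variables (relative rosette area, COUPTFII density,
#' TUJ1/GAD67 relative intensity) are derived from the morphometry table
#' with the corresponding quantification functions. Also reports the
#' Spearman correlation between relative rosette area and total cycle
#' length per genotype (when both tables cover the same organoids) and a
#' PCA of the kinetics variables.
#'
#' @param estimates Output of [estimate_table()] / [run_estimate()].
#' @param morphometry Optional morphometry table (as written by
#'   [run_simulate()]).
#' @param alpha Significance level used for the convenience flag columns.
#' @return A list of class `study_stats`: `per_variable` (one row per
#'   variable), `rosette_tc_correlation`, `pca`, `alpha`, `version`.
#' @export
run_stats <- function(estimates, morphometry = NULL, alpha = 0.05) {
  req <- c("organoid_id", "genotype", "batch_id")
  missing_cols <- setdiff(req, names(estimates))
  if (length(missing_cols)) {
    stop("estimates are missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(estimates$organoid_id)) {
    stop("duplicate organoid_id in estimates: ",
         paste(unique(estimates$organoid_id[
           duplicated(estimates$organoid_id)]), collapse = ", "),
         call. = FALSE)
  }
  vars <- list()
  for (v in c("t_c", "t_g1", "t_s", "t_g2m")) {
    if (v %in% names(estimates)) vars[[v]] <- estimates[[v]]
  }
  geno <- estimates$genotype
  batch <- estimates$batch_id
  morpho_tbl <- NULL
  if (!is.null(morphometry)) {
    if (anyDuplicated(morphometry$organoid_id)) {
      stop("duplicate organoid_id in morphometry", call. = FALSE)
    }
    morpho_tbl <- tibble::tibble(
      organoid_id = morphometry$organoid_id,
      genotype = morphometry$genotype,
      batch_id = morphometry$batch_id,
      rel_rosette_area = relative_rosette_area(morphometry$rosette_area,
                                               morphometry$area),
      couptfii_density = marker_density(morphometry$couptfii_count,
                                        morphometry$area),
      tuj1_rel_intensity = relative_mean_intensity(
        morphometry$tuj1_mean_intensity, morphometry$area),
      gad67_rel_intensity = relative_mean_intensity(
        morphometry$gad67_mean_intensity, morphometry$area)
    )
  }
  per_variable <- dplyr::bind_rows(c(
    lapply(names(vars), function(v) {
      dplyr::bind_cols(tibble::tibble(variable = v),
                       stat_battery_one(vars[[v]], geno, batch, alpha))
    }),
    if (!is.null(morpho_tbl)) {
      lapply(c("rel_rosette_area", "couptfii_density",
               "tuj1_rel_intensity", "gad67_rel_intensity"),
             function(v) {
               dplyr::bind_cols(
                 tibble::tibble(variable = v),
                 stat_battery_one(morpho_tbl[[v]], morpho_tbl$genotype,
                                  morpho_tbl$batch_id, alpha))
             })
    }
  ))

  rosette_cor <- NULL
  if (!is.null(morpho_tbl) && "t_c" %in% names(estimates)) {
    joined <- dplyr::inner_join(
      dplyr::select(morpho_tbl, "organoid_id", "genotype",
                    "rel_rosette_area"),
      dplyr::select(estimates, "organoid_id", "t_c"),
      by = "organoid_id"
    )
    joined <- joined[is.finite(joined$t_c), ]
    if (nrow(joined) >= 6L) {
      rosette_cor <- dplyr::bind_rows(lapply(
        unique(joined$genotype), function(g) {
          sub <- joined[joined$genotype == g, ]
          sc <- spearman_cor(sub$rel_rosette_area, sub$t_c)
          tibble::tibble(genotype = g, rho = sc$rho,
                         p_value = sc$p_value, n = sc$n)
        }))
    }
  }

  pca <- NULL
  kin_vars <- intersect(c("t_s", "t_c", "t_g1", "t_g2m"), names(estimates))
  if (length(kin_vars) >= 2L) {
    m <- as.matrix(estimates[, kin_vars])
    keep <- stats::complete.cases(m)
    if (sum(keep) >= 3L) pca <- run_pca(m[keep, , drop = FALSE])
  }

  structure(
    list(per_variable = per_variable,
         rosette_tc_correlation = rosette_cor,
         pca = pca, alpha = alpha,
         version = as.character(utils::packageVersion("orgcycle"))),
    class = "study_stats"
  )
}

#' @export
print.study_stats <- function(x, ...) {
  cat("<study_stats> orgcycle", x$version, "| alpha =", x$alpha, "\n")
  print(as.data.frame(
    x$per_variable[, c("variable", "mean_control", "mean_deletion",
                       "lme_p", "f_var_p", "cliffs_delta",
                       "omega_squared")]
  ), digits = 3)
  invisible(x)
}
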