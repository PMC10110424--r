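#' Batch-normalised organoid area
#'
#' Normalises each organoid's projected area to the mean area of the
#' control organoids in the same batch at the same day, so growth can be
#' compared across batches with different baselines. Within every batch
#' the control organoids' normalised areas average exactly 1.
#'
#' @param records A data frame with columns `batch_id`, `genotype`
#'   (`"control"` / `"deletion"`), `day` and `area` (plus any identifier
#'   columns, carried through).
#' @param day The measurement day to normalise (one of the values present
#'   in `records$day`).
#' @return The rows of `records` at that day with a `norm_area` column
#'   appended.
#' @export
normalize_area <- function(records, day) {
  req <- c("batch_id", "genotype", "day", "area")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop("records are missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  recs <- dplyr::filter(records, .data$day == !!day)
  if (nrow(recs) == 0L) {
    stop("no records at day ", day, call. = FALSE)
  }
  if (any(!is.finite(recs$area) | recs$area <= 0)) {
    stop("all areas must be finite and positive", call. = FALSE)
  }
  ctrl_means <- recs |>
    dplyr::filter(.data$genotype == "control") |>
    dplyr::group_by(.data$batch_id) |>
    dplyr::summarise(ctrl_mean_area = mean(.data$area), .groups = "drop")
  missing_batches <- setdiff(unique(recs$batch_id), ctrl_means$batch_id)
  if (length(missing_batches)) {
    stop("no control organoids at day ", day, " in batch(es): ",
         paste(missing_batches, collapse = ", "), call. = FALSE)
  }
  recs |>
    dplyr::left_join(ctrl_means, by = "batch_id") |>
    dplyr::mutate(norm_area = .data$area / .data$ctrl_mean_area) |>
    dplyr::select(-"ctrl_mean_area")
}

#' Relative neural-rosette area
#'
#' The total area occupied by neural rosettes in an organoid section
#' divided by the area of the organoid, a size-independent measure of
#' rosette formation in `[0, 1]`.
#'
#' @param rosette_area Total rosette area per organoid (same units as
#'   `area`); an organoid without rosettes has 0.
#' @param area Organoid section area (> 0).
#' @return Proportions in `[0, 1]`, vectorised over organoids.
#' @examples
#' relative_rosette_area(c(0.2, 0), c(1, 2)) # 0.2 0
#' @export
relative_rosette_area <- function(rosette_area, area) {
  stopifnot(length(rosette_area) == length(area))
  if (any(!is.finite(area) | area <= 0)) {
    stop("organoid area must be finite and positive", call. = FALSE)
  }
  if (any(!is.finite(rosette_area) | rosette_area < 0)) {
    stop("rosette area must be finite and non-negative", call. = FALSE)
  }
  if (any(rosette_area > area)) {
    stop("total rosette area exceeds organoid area in ",
         sum(rosette_area > area), " record(s)", call. = FALSE)
  }
  rosette_area / area
}

#' Marker-positive cell areal density
#'
#' Cells positive for a marker in a whole-organoid section divided by the
#' section area (counts per unit area), taking variation in organoid size
#' into account.
#'
#' @param count Marker-positive cell count (>= 0).
#' @param area Organoid section area (> 0).
#' @return Densities, vectorised over organoids.
#' @export
marker_density <- function(count, area) {
  stopifnot(length(count) == length(area))
  if (any(!is.finite(area) | area <= 0)) {
    stop("organoid area must be finite and positive", call. = FALSE)
  }
  if (any(!is.finite(count) | count < 0)) {
    stop("marker counts must be finite and non-negative", call. = FALSE)
  }
  count / area
}

#' Relative mean fluorescence intensity
#'
#' Mean grey value of a marker channel over a whole-organoid section
#' divided by the organoid area, the size-relative expression measure used
#' for markers quantified by intensity rather than by counting.
#'
#' @param mean_intensity Mean grey value (>= 0).
#' @param area Organoid section area (> 0).
#' @return Intensity per unit area, vectorised over organoids.
#' @export
relative_mean_intensity <- function(mean_intensity, area) {
  stopifnot(length(mean_intensity) == length(area))
  if (any(!is.finite(area) | area <= 0)) {
    stop("organoid area must be finite and positive", call. = FALSE)
  }
  if (any(!is.finite(mean_intensity) | mean_intensity < 0)) {
    stop("mean intensity must be finite and non-negative", call. = FALSE)
  }
  mean_intensity / area
}
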