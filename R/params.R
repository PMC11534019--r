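# The seven scalar shape parameters of the posterior sclera. "Maxima" are
# 95th percentiles (robust to outlier surface points); D_var is the
# population variance of D (a shape descriptor, not an inferential
# estimate).

#' Compute the staphyloma shape parameters
#'
#' From a per-point topography, computes: `d_mean` (mm), `c_mean` (1/mm),
#' `d_max` and `c_max` (the `percentile`-th percentiles of D and C),
#' `d_var` (mm^2, variance of D), and `cd_mean` / `cd_max` (mean and
#' percentile of the per-point product `C*D`). Flagged points are excluded.
#' For a 24 mm eye with a spherical posterior surface centred on the
#' pre-elongation centre, `d_var` tends to 0 and `cd_max` to 1; elongation
#' raises `cd_max` above 1 and posterior protrusion inflates `d_var`.
#'
#' @param topo an `eye_topography` from [compute_topography()] (any data
#'   frame with `D`, `C`, `CD` and `flagged` columns works).
#' @param percentile percentile used for the robust maxima (default 95).
#' @param min_points minimum unflagged points required (default 200).
#' @param var_denominator `"population"` (1/N, default) or `"sample"`
#'   (1/(N-1)) for `d_var`.
#' @return a one-row `shape_parameters` tibble with columns `d_mean,
#'   c_mean, d_max, c_max, d_var, cd_mean, cd_max, n_points, n_flagged`.
#' @export
compute_parameters <- function(topo, percentile = 95, min_points = 200,
                               var_denominator = c("population", "sample")) {
  var_denominator <- match.arg(var_denominator)
  stopifnot(is.data.frame(topo), all(c("D", "C", "CD") %in% names(topo)))
  flagged <- if ("flagged" %in% names(topo)) topo$flagged else
    !is.finite(topo$D) | !is.finite(topo$C)
  ok <- !flagged & is.finite(topo$D) & is.finite(topo$C)
  if (sum(ok) < min_points) {
    abort(paste0("insufficient points: ", sum(ok),
                 " unflagged posterior points (need >= ", min_points, ")"))
  }
  D <- topo$D[ok]; C <- topo$C[ok]; CD <- topo$CD[ok]
  p <- percentile / 100
  pct <- function(x) quantile(x, p, type = 7, names = FALSE)
  dv <- if (var_denominator == "population") mean((D - mean(D))^2) else
    stats::var(D)
  out <- tibble::tibble(
    d_mean = mean(D), c_mean = mean(C),
    d_max = pct(D), c_max = pct(C),
    d_var = dv,
    cd_mean = mean(CD), cd_max = pct(CD),
    n_points = nrow(topo), n_flagged = sum(flagged)
  )
  class(out) <- c("shape_parameters", class(out))
  attr(out, "units") <- c(
    d_mean = "mm", c_mean = "1/mm", d_max = "mm", c_max = "1/mm",
    d_var = "mm^2", cd_mean = "", cd_max = ""
  )
  attr(out, "percentile") <- percentile
  out
}

#' @export
glance.shape_parameters <- function(x, ...) tibble::as_tibble(x)

shape_parameter_names <- c("d_mean", "c_mean", "d_max", "c_max", "d_var",
                           "cd_mean", "cd_max")

#' Long-format parameter report over a batch of eyes
#'
#' @param data tibble with one row per eye: an `eye_id` column, a `group`
#'   column (e.g. staphyloma type) and the seven parameter columns as
#'   produced by [compute_parameters()].
#' @return list with `values`, a long tibble `(eye_id, group, parameter,
#'   value)`, and `summary`, the per-group mean and SD of each parameter
#'   (SD is `NA`, not zero, for single-eye groups).
#' @export
parameters_table <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("eye_id", "group", shape_parameter_names)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(data$eye_id)) abort("duplicate eye ids")
  values <- data |>
    dplyr::select(dplyr::all_of(need)) |>
    tidyr::pivot_longer(dplyr::all_of(shape_parameter_names),
                        names_to = "parameter", values_to = "value") |>
    dplyr::mutate(parameter = factor(.data$parameter,
                                     levels = shape_parameter_names))
  summary <- values |>
    dplyr::group_by(.data$group, .data$parameter) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
  list(values = values, summary = summary)
}

#' Write a parameter batch to CSV
#' @param data one-row-per-eye parameter tibble (see [parameters_table()]).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_parameters <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}
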