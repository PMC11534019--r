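# Discrimination statistics for the shape parameters: ROC area via the
# Mann-Whitney identity (ties counted 1/2) and the normalized partial AUC
# over the high-specificity range (specificity 85-100%, i.e. false-positive
# rate 0-0.15, normalized by 0.15).

check_roc_input <- function(scores, labels) {
  if (any(!is.finite(scores))) abort("scores must be finite")
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) != 2) abort("labels must contain exactly two classes")
  labels
}

#' ROC area under the curve
#'
#' AUC via the Mann-Whitney U identity with ties counted as 1/2. The
#' orientation is chosen automatically so that AUC >= 0.5 (directionless
#' discriminability); the reported `positive` level is the group the larger
#' scores indicate under that orientation.
#'
#' @param scores numeric scores (e.g. a shape parameter).
#' @param labels two-class labels (factor, character or 0/1).
#' @return a `roc_result` with `auc`, `n_pos`, `n_neg`, `positive`,
#'   `flipped`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_roc_input(scores, labels)
  pos_level <- levels(labels)[2]
  is_pos <- labels == pos_level
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  flipped <- auc < 0.5
  if (flipped) {
    auc <- 1 - auc
    pos_level <- levels(labels)[1]
  }
  structure(
    list(auc = auc, pauc_normalized = NA_real_, spec_range = c(0.85, 1),
         n_pos = if (flipped) n0 else n1, n_neg = if (flipped) n1 else n0,
         positive = pos_level, flipped = flipped),
    class = "roc_result"
  )
}

# vertices of the empirical ROC (fpr, tpr), tie groups collapsed,
# starting at (0, 0)
roc_vertices <- function(scores, is_pos) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- is_pos[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / max(1, sum(is_pos)))
  fpr <- c(0, fp[last] / max(1, sum(!is_pos)))
  cbind(fpr = fpr, tpr = tpr)
}

#' Normalized partial AUC over the high-specificity range
#'
#' Integrates the empirical ROC (trapezoids on the step curve's vertices;
#' diagonal segments for tied scores) over false-positive rate in
#' `[0, 1 - spec_lo]` and divides by `1 - spec_lo` (0.15 at the default),
#' so a perfectly separating marker scores 1 and the chance diagonal scores
#' `(1 - spec_lo) / 2 / 1 = 0.075`. Reported alongside the full AUC, with
#' the same orientation (chosen so the full AUC >= 0.5).
#'
#' @inheritParams roc_auc
#' @param spec_lo lower bound of the specificity range (default 0.85).
#' @return a `roc_result` with both `auc` and `pauc_normalized`.
#' @export
roc_partial_auc <- function(scores, labels, spec_lo = 0.85) {
  stopifnot(spec_lo >= 0, spec_lo < 1)
  res <- roc_auc(scores, labels)
  labels <- check_roc_input(scores, labels)
  is_pos <- labels == res$positive
  v <- roc_vertices(scores, is_pos)
  fmax <- 1 - spec_lo
  area <- 0
  for (i in seq_len(nrow(v) - 1)) {
    f0 <- v[i, 1]; f1 <- v[i + 1, 1]
    t0 <- v[i, 2]; t1 <- v[i + 1, 2]
    if (f0 >= fmax) break
    if (f1 > fmax) {
      # clip the segment at the range boundary
      t1 <- t0 + (t1 - t0) * (fmax - f0) / (f1 - f0)
      f1 <- fmax
    }
    area <- area + (f1 - f0) * (t0 + t1) / 2
  }
  res$pauc_normalized <- as.numeric(area / fmax)
  res$spec_range <- c(spec_lo, 1)
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC = ", signif(x$auc, 4), sep = "")
  if (is.finite(x$pauc_normalized)) {
    cat(", normalized pAUC (specificity ", x$spec_range[1] * 100, "-100%) = ",
        signif(x$pauc_normalized, 4), sep = "")
  }
  cat("\n  positive class: ", x$positive,
      " (n = ", x$n_pos, " vs ", x$n_neg, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, pauc_normalized = x$pauc_normalized,
    spec_lo = x$spec_range[1], n_pos = x$n_pos, n_neg = x$n_neg,
    positive = x$positive, flipped = x$flipped
  )
}

#' @export
glance.roc_result <- function(x, ...) tidy(x)

#' Pairwise AUC report across groups and parameters
#'
#' For every unordered pair of groups and every parameter column, computes
#' the full AUC and the normalized partial AUC. Missing parameter values are
#' excluded pairwise with the remaining counts reported; groups with fewer
#' than two members are flagged.
#'
#' @param data tibble with a `group` column and parameter columns (defaults
#'   to the seven shape parameters present in the data).
#' @param parameters character vector of parameter columns.
#' @param spec_lo lower specificity bound for the partial AUC.
#' @return tibble `(parameter, group1, group2, n1, n2, auc,
#'   pauc_normalized, flagged)`.
#' @export
pairwise_auc_report <- function(data, parameters = NULL, spec_lo = 0.85) {
  stopifnot(is.data.frame(data), "group" %in% names(data))
  parameters <- parameters %||%
    intersect(shape_parameter_names, names(data))
  if (length(parameters) == 0) abort("no parameter columns found")
  groups <- if (is.factor(data$group)) levels(data$group)
            else unique(as.character(data$group))
  if (length(groups) < 2) abort("need at least two groups")
  counts <- table(factor(as.character(data$group), levels = groups))
  if (any(counts == 0)) abort("empty group")
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(gp) {
    purrr::map(parameters, function(pm) {
      sub <- data[as.character(data$group) %in% gp, c("group", pm)]
      sub <- sub[is.finite(sub[[pm]]), ]
      n1 <- sum(sub$group == gp[1]); n2 <- sum(sub$group == gp[2])
      flagged <- n1 < 2 || n2 < 2
      res <- if (n1 >= 1 && n2 >= 1) {
        roc_partial_auc(sub[[pm]], factor(sub$group, levels = gp), spec_lo)
      } else NULL
      tibble::tibble(
        parameter = pm, group1 = gp[1], group2 = gp[2], n1 = n1, n2 = n2,
        auc = if (is.null(res)) NA_real_ else res$auc,
        pauc_normalized = if (is.null(res)) NA_real_ else res$pauc_normalized,
        flagged = flagged
      )
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}
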