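## Rescaling of raw mutational effect scores to [-1, 0] and per-position
## aggregation. DMS studies report effect scores on heterogeneous scales
## (log enrichment ratios, fitness coefficients, ...); anchoring the 5th
## percentile of the score distribution to -1 and the wild-type peak
## (the mode populated by near-neutral mutations) to 0 makes positions
## comparable across datasets.

#' Fit rescaling anchors from a raw score distribution
#'
#' The lower anchor `min_M` is the `percentile`-th percentile of the
#' scores (linear interpolation between order statistics; R's default
#' quantile type 7). The upper anchor `max_M` is the wild-type peak,
#' estimated as the median of the scores falling in the most populated of
#' `n_bins` equal-width bins spanning the data range; ties between bins
#' break toward the bin with the larger midpoint, since wild-type-like
#' scores sit at the high end of DMS score distributions.
#'
#' Both anchors are equivariant under positive affine maps of the scores,
#' so downstream rescaled values are invariant to the dataset's raw units.
#'
#' @param scores Numeric vector of raw effect scores (>= 20 finite values,
#'   not all equal).
#' @param percentile Lower-anchor percentile, default 5.
#' @param n_bins Number of histogram bins for peak detection, default 100.
#' @return An object of class `rescale_params`: list with `min_M`,
#'   `max_M`, `a = -1`, `b = 0`, `percentile`, `n_bins`.
#' @export
fit_rescale_params <- function(scores, percentile = 5, n_bins = 100) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 20L) {
    stop_validation("fit_rescale_params: need >= 20 finite scores, got %d",
                    length(scores))
  }
  if (diff(range(scores)) == 0) {
    stop_degenerate("fit_rescale_params: all scores are equal (degenerate distribution)")
  }
  stopifnot(n_bins >= 1, percentile > 0, percentile < 100)
  min_M <- unname(stats::quantile(scores, percentile / 100, type = 7))
  breaks <- seq(min(scores), max(scores), length.out = n_bins + 1)
  bin <- findInterval(scores, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  # which.max on the reversed vector -> ties resolve to the larger midpoint
  peak_bin <- n_bins + 1L - which.max(rev(counts))
  max_M <- stats::median(scores[bin == peak_bin])
  if (min_M >= max_M) {
    stop_dmsites("dmsites_anchor_error",
                 paste("fit_rescale_params: lower anchor (%g) >= wild-type peak (%g);",
                       "distribution is pathological, supply manual anchors via",
                       "rescale_params()"), min_M, max_M)
  }
  rescale_params(min_M, max_M, percentile = percentile, n_bins = n_bins)
}

#' Manually specified rescaling anchors
#'
#' Published datasets use heterogeneous score conventions; when automatic
#' anchor fitting misbehaves (e.g. strongly bimodal distributions), the
#' anchors can be pinned per dataset.
#'
#' @param min_M,max_M Anchors with `min_M < max_M`; `min_M` maps to
#'   `a = -1` and `max_M` to `b = 0`.
#' @param percentile,n_bins Recorded for provenance only.
#' @return An object of class `rescale_params`.
#' @export
rescale_params <- function(min_M, max_M, percentile = NA_real_, n_bins = NA_integer_) {
  if (!is.finite(min_M) || !is.finite(max_M) || min_M >= max_M) {
    stop_validation("rescale_params: need finite min_M < max_M")
  }
  structure(list(min_M = min_M, max_M = max_M, a = -1, b = 0,
                 percentile = percentile, n_bins = n_bins),
            class = "rescale_params")
}

#' @export
print.rescale_params <- function(x, ...) {
  cat(sprintf("rescale_params: min_M = %g -> %g, max_M = %g -> %g\n",
              x$min_M, x$a, x$max_M, x$b))
  invisible(x)
}

#' Rescale raw effect scores to [-1, 0]
#'
#' Applies `M_rescaled = (b - a) * (M - min_M) / (max_M - min_M) + a`
#' with `a = -1`, `b = 0`: scores at the lower anchor map to -1 (fully
#' sensitive) and scores at the wild-type peak map to 0 (neutral). With
#' `clamp = TRUE` (default), scores outside the anchor interval are
#' clipped to [-1, 0], keeping downstream sensitivities bounded.
#'
#' @param table A [mut_effect_table] of raw scores.
#' @param params A `rescale_params` object.
#' @param clamp Clip rescaled scores into `[a, b]` (default `TRUE`).
#' @return A [mut_effect_table] whose `score` column is rescaled.
#' @export
rescale_scores <- function(table, params, clamp = TRUE) {
  stopifnot(inherits(params, "rescale_params"))
  m <- table$score
  r <- (params$b - params$a) * (m - params$min_M) /
    (params$max_M - params$min_M) + params$a
  if (clamp) r <- pmin(pmax(r, params$a), params$b)
  out <- table
  out$score <- r
  attr(out, "rescale_params") <- params
  out
}

#' Average rescaled scores per position
#'
#' Positions with fewer than `min_mutants` observed substitutions are
#' dropped (and reported via `message()`): a per-position mean over a
#' handful of mutants is too noisy to standardize against the rest of
#' the protein.
#'
#' @param rescaled A rescaled [mut_effect_table].
#' @param min_mutants Minimum mutants per retained position, default 10.
#' @return A `data.frame` of class `position_profile` with columns
#'   `position`, `mean_rescaled`, `n_mutants`, and
#'   `sensitivity = -mean_rescaled` (1 = fully sensitive, 0 = neutral).
#' @export
average_by_position <- function(rescaled, min_mutants = 10) {
  if (is.null(rescaled) || nrow(rescaled) == 0L) {
    stop_validation("average_by_position: empty input")
  }
  pos <- sort(unique(rescaled$position))
  means <- tapply(rescaled$score, rescaled$position, mean)
  ns <- tapply(rescaled$score, rescaled$position, length)
  prof <- data.frame(position = pos,
                     mean_rescaled = as.numeric(means[as.character(pos)]),
                     n_mutants = as.integer(ns[as.character(pos)]))
  dropped <- prof$position[prof$n_mutants < min_mutants]
  if (length(dropped) > 0L) {
    message(sprintf("average_by_position: dropping %d position(s) with < %d mutants: %s",
                    length(dropped), min_mutants,
                    paste(utils::head(dropped, 20), collapse = ", ")))
  }
  prof <- prof[prof$n_mutants >= min_mutants, , drop = FALSE]
  if (nrow(prof) == 0L) {
    stop_validation("average_by_position: no position passes the >= %d mutant filter",
                    min_mutants)
  }
  prof$sensitivity <- -prof$mean_rescaled
  rownames(prof) <- NULL
  structure(prof, class = c("position_profile", "data.frame"))
}
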