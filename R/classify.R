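## Combined Z-score classification of residues into active-site, buried
## and exposed non-active-site classes.
##
## Sign convention (documented, since "added/subtracted" alone is
## ambiguous): per-position sensitivity is positive (1 = fully sensitive,
## = minus the mean rescaled score), so after standardization
##   score_active = z_sens + z_acc   (sensitive AND exposed push it up)
##   score_buried = z_sens - z_acc   (sensitive AND buried push it up)
## and both classes use the single one-sided rule
##   score > mean(score) + k * sd(score),  k = 1 by default.
## With the raw negative-sensitive orientation, adding the Z-scores would
## make sensitive-exposed residues cancel to ~0, which cannot reproduce
## the observed behaviour; hence this orientation.

#' Z-score standardization
#'
#' Subtracts the mean and divides by the population (not sample) standard
#' deviation, so the output has mean 0 and population SD exactly 1.
#'
#' @param values Numeric vector, length >= 2, not constant.
#' @return Standardized numeric vector.
#' @export
standardize <- function(values) {
  if (length(values) < 2L || any(!is.finite(values))) {
    stop_validation("standardize: need >= 2 finite values")
  }
  s <- pop_sd(values)
  if (s == 0) stop_degenerate("standardize: zero standard deviation")
  (values - mean(values)) / s
}

# population SD (divisor n); the classification formulas state no ddof,
# and population SD keeps standardize() exact for tiny inputs
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Combine position profiles with predicted accessibility
#'
#' Restricts to positions present in both inputs (predictions are only
#' meaningful where both a sensitivity profile and a sequence-based
#' accessibility value exist), standardizes each input across those
#' positions, and forms the additive and subtractive combined scores.
#'
#' @param profiles A `position_profile` (see [average_by_position]).
#' @param acc An [accessibility_table] with `source = "sequence_predicted"`.
#' @return A `data.frame` of class `combined_scores` with columns
#'   `position`, `sensitivity`, `rel_acc`, `z_mut_sens`, `z_acc`,
#'   `score_active`, `score_buried`.
#' @export
combine_scores <- function(profiles, acc) {
  if (!identical(acc_source(acc), "sequence_predicted")) {
    stop_validation("combine_scores: accessibility must be sequence-predicted, got '%s'",
                    acc_source(acc) %||% "unknown")
  }
  common <- intersect(profiles$position, acc$position)
  if (length(common) < 3L) {
    stop_validation("combine_scores: only %d position(s) shared between profiles and accessibility (need >= 3)",
                    length(common))
  }
  common <- sort(common)
  p <- profiles[match(common, profiles$position), ]
  a <- acc[match(common, acc$position), ]
  z_sens <- standardize(p$sensitivity)
  z_acc <- standardize(a$rel_acc)
  structure(data.frame(position = common,
                       sensitivity = p$sensitivity,
                       rel_acc = a$rel_acc,
                       z_mut_sens = z_sens,
                       z_acc = z_acc,
                       score_active = z_sens + z_acc,
                       score_buried = z_sens - z_acc),
            class = c("combined_scores", "data.frame"))
}

#' One-sided SD-threshold call
#'
#' Returns which scores lie more than `k` standard deviations above their
#' own mean (population SD). High combined score = called.
#'
#' @param scores Numeric vector, length >= 3, not constant.
#' @param k Threshold in SD units, default 1.
#' @return Logical vector, `TRUE` for called entries.
#' @export
call_class <- function(scores, k = 1.0) {
  if (length(scores) < 3L) stop_validation("call_class: need >= 3 scores")
  s <- pop_sd(scores)
  if (s == 0) stop_degenerate("call_class: zero standard deviation")
  scores > mean(scores) + k * s
}

#' Assign the three residue classes
#'
#' Active-site calls come from `score_active`, buried calls from
#' `score_buried` (each thresholded at `k` SD above its mean); positions
#' in `exclusions` are removed from the buried call only. A residue
#' exceeding both cutoffs keeps the class whose combined score lies more
#' SDs above its mean and is flagged `ambiguous_dual_call`. Everything
#' else is exposed non-active-site, so the three classes partition the
#' evaluated residues.
#'
#' @param combined A `combined_scores` table (see [combine_scores]).
#' @param k Threshold in SD units, default 1.
#' @param exclusions Positions excluded from the buried call (flagged
#'   `excluded_by_list`).
#' @return A `data.frame` of class `prediction_table` with columns
#'   `position`, `z_mut_sens`, `z_acc`, `score_active`, `score_buried`,
#'   `predicted_class`, `flags`; threshold parameters in
#'   `attr(, "thresholds")`.
#' @export
assign_classes <- function(combined, k = 1.0, exclusions = integer()) {
  sa <- combined$score_active
  sb <- combined$score_buried
  act <- call_class(sa, k)
  bur <- call_class(sb, k)
  excl <- combined$position %in% exclusions
  bur[excl] <- FALSE

  sd_a <- pop_sd(sa); mu_a <- mean(sa)
  sd_b <- pop_sd(sb); mu_b <- mean(sb)
  cls <- rep("exposed_nonactive", nrow(combined))
  cls[bur] <- "buried"
  cls[act] <- "active_site"
  dual <- act & bur
  # tie-break dual calls by number of SDs above the respective mean
  cls[dual] <- ifelse((sa[dual] - mu_a) / sd_a >= (sb[dual] - mu_b) / sd_b,
                      "active_site", "buried")
  flags <- character(nrow(combined))
  flags[dual] <- "ambiguous_dual_call"
  flags[excl] <- ifelse(nzchar(flags[excl]),
                        paste(flags[excl], "excluded_by_list", sep = ";"),
                        "excluded_by_list")
  structure(data.frame(position = combined$position,
                       z_mut_sens = combined$z_mut_sens,
                       z_acc = combined$z_acc,
                       score_active = sa,
                       score_buried = sb,
                       predicted_class = cls,
                       flags = flags,
                       stringsAsFactors = FALSE),
            class = c("prediction_table", "data.frame"),
            thresholds = list(active = list(mean = mu_a, sd = sd_a, k = k),
                              buried = list(mean = mu_b, sd = sd_b, k = k)))
}

#' Two-state burial classification from structure accessibility
#'
#' The standard burial rule on structure-calculated accessibility: a
#' residue is buried when its relative side-chain accessibility is at
#' most `cutoff` percent (default 5), exposed when strictly above.
#'
#' @param acc An [accessibility_table] with `source = "structure"`.
#' @param cutoff Percent side-chain accessibility, default 5.
#' @return A `data.frame` with columns `position`, `burial`
#'   (`"buried"`/`"exposed"`).
#' @export
burial_truth_from_structure <- function(acc, cutoff = 5.0) {
  if (!identical(acc_source(acc), "structure")) {
    stop_validation("burial_truth_from_structure: accessibility must come from structure")
  }
  data.frame(position = acc$position,
             burial = ifelse(acc$rel_acc <= cutoff, "buried", "exposed"),
             stringsAsFactors = FALSE)
}
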