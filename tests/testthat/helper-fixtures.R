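# fixture builders and independent oracles shared across test files

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# small long-format score file
long_score_file <- function(rows) {
  write_lines_tmp(c("position\twt_aa\tmut_aa\tscore",
                    vapply(rows, function(r) paste(r, collapse = "\t"), "")))
}

# a deterministic mutation table: `n_mut` mutants at each position, scores
# supplied per position (recycled across mutants) or per record
make_table <- function(positions, scores_by_pos, n_mut = 12) {
  wt <- "A"
  recs <- do.call(rbind, lapply(seq_along(positions), function(i) {
    muts <- setdiff(dmsites::AA_ALPHABET, wt)[seq_len(n_mut)]
    data.frame(position = positions[i], wt_aa = wt, mut_aa = muts,
               score = rep_len(scores_by_pos[[i]], n_mut))
  }))
  mut_effect_table(recs$position, recs$wt_aa, recs$mut_aa, recs$score)
}

# independent percentile oracle: sort + linear interpolation by hand
oracle_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# brute-force three-class caller: recomputes every mean/SD by definition,
# independent of the package's vectorized path
oracle_assign <- function(sens, acc, k = 1, exclusions = integer(),
                          positions = seq_along(sens)) {
  psd <- function(v) sqrt(sum((v - sum(v) / length(v))^2) / length(v))
  zs <- (sens - sum(sens) / length(sens)) / psd(sens)
  za <- (acc - sum(acc) / length(acc)) / psd(acc)
  sa <- zs + za
  sb <- zs - za
  out <- character(length(sens))
  act <- sb_call <- logical(length(sens))
  for (i in seq_along(sens)) {
    act[i] <- sa[i] > sum(sa) / length(sa) + k * psd(sa)
    sb_call[i] <- sb[i] > sum(sb) / length(sb) + k * psd(sb) &&
      !(positions[i] %in% exclusions)
  }
  for (i in seq_along(sens)) {
    out[i] <- if (act[i] && sb_call[i]) {
      if ((sa[i] - mean(sa)) / psd(sa) >= (sb[i] - mean(sb)) / psd(sb))
        "active_site" else "buried"
    } else if (act[i]) "active_site"
    else if (sb_call[i]) "buried"
    else "exposed_nonactive"
  }
  out
}

# run the full pipeline on one synthetic dataset, return metrics report
synthetic_run <- function(seed, target_r = 0.9, n = 200,
                          wt_score_sd = 0.3, deleterious_sd = 1,
                          aliphatic_tolerance = 0.7, missing_rate = 0.1) {
  cfg <- synthetic_config(n_positions = n, wt_score_sd = wt_score_sd,
                          deleterious_sd = deleterious_sd,
                          aliphatic_tolerance = aliphatic_tolerance,
                          target_r = target_r, missing_rate = missing_rate,
                          seed = seed)
  gt <- generate_truth(cfg)
  dms <- generate_dms(gt$truth, cfg)
  pacc <- generate_predicted_accessibility(gt$acc, cfg$target_r, cfg$seed)
  pred <- suppressMessages(run_predict(dms, pacc))
  suppressMessages(evaluate_predictions(pred, gt$truth))
}
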