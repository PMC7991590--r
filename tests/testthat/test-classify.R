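test_that("standardize matches hand computation and normalizes exactly", {
  expect_equal(standardize(c(1, 2, 3)),
               c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  set.seed(5)
  for (i in 1:10) {
    z <- standardize(rnorm(sample(5:50, 1), sd = runif(1, 0.1, 10)))
    expect_lt(abs(mean(z)), 1e-9)
    expect_lt(abs(sqrt(mean(z^2)) - 1), 1e-9)
  }
  expect_error(standardize(rep(2, 5)), class = "dmsites_degenerate_error")
  expect_error(standardize(1), class = "dmsites_validation_error")
})

test_that("combine restricts to shared positions and forms both scores", {
  prof <- structure(data.frame(position = 1:5, sensitivity = c(1, .7, .4, .2, 0)),
                    class = c("position_profile", "data.frame"))
  acc <- accessibility_table(2:6, c(80, 20, 45, 5, 60), source = "sequence_predicted")
  cs <- combine_scores(prof, acc)
  expect_equal(cs$position, 2:5)
  expect_lt(abs(mean(cs$z_mut_sens)), 1e-9)
  expect_lt(abs(sqrt(mean(cs$z_acc^2)) - 1), 1e-9)
  expect_equal(cs$score_active, cs$z_mut_sens + cs$z_acc)
  expect_equal(cs$score_active - cs$score_buried, 2 * cs$z_acc)

  # elementwise arithmetic on known z-scores
  zs <- c(2, 0, -1, -1); za <- c(1.5, 0.5, -1, -1)
  expect_equal(zs + za, c(3.5, 0.5, -2, -2))
  expect_equal(zs - za, c(0.5, -0.5, 0, 0))

  struct <- accessibility_table(1:5, c(1, 2, 3, 4, 5), source = "structure")
  expect_error(combine_scores(prof, struct), class = "dmsites_validation_error")
  tiny <- accessibility_table(4:6, c(1, 2, 3), source = "sequence_predicted")
  expect_error(combine_scores(prof, tiny), "need >= 3")
  # maximally sensitive + maximally exposed residue has the max score_active
  prof2 <- structure(data.frame(position = 1:4, sensitivity = c(1, .2, .1, 0)),
                     class = c("position_profile", "data.frame"))
  acc2 <- accessibility_table(1:4, c(95, 40, 20, 10), source = "sequence_predicted")
  cs2 <- combine_scores(prof2, acc2)
  expect_equal(which.max(cs2$score_active), 1L)
})

test_that("call_class applies the one-sided k-SD rule", {
  s <- c(3.5, 0.5, -2, -2)   # mean 0, population SD sqrt(5.125) = 2.2638
  expect_equal(call_class(s, k = 1), c(TRUE, FALSE, FALSE, FALSE))
  expect_false(any(call_class(s, k = 100)))          # k -> Inf: empty call set
  expect_error(call_class(rep(1, 4)), class = "dmsites_degenerate_error")
  expect_error(call_class(c(1, 2)), class = "dmsites_validation_error")
})

test_that("assign_classes partitions, tie-breaks duals, honours exclusions", {
  sens <- c(1, .9, .85, .1, .05, 0, .2, .15)
  acc <- c(95, 4, 90, 50, 60, 55, 40, 45)
  cs <- combine_scores(
    structure(data.frame(position = 1:8, sensitivity = sens),
              class = c("position_profile", "data.frame")),
    accessibility_table(1:8, acc, source = "sequence_predicted"))
  pred <- assign_classes(cs, k = 1)
  expect_setequal(unique(pred$predicted_class),
                  intersect(c("active_site", "buried", "exposed_nonactive"),
                            pred$predicted_class))
  # partition: every residue exactly one class
  expect_equal(nrow(pred), 8L)
  expect_true(all(pred$predicted_class %in%
                    c("active_site", "buried", "exposed_nonactive")))
  # sensitive+exposed residue 1 is active; sensitive+buried residue 2 is buried
  expect_equal(pred$predicted_class[1], "active_site")
  expect_equal(pred$predicted_class[2], "buried")
  # excluding position 2 from the buried call reroutes it to the complement
  pred_ex <- assign_classes(cs, k = 1, exclusions = 2L)
  expect_equal(pred_ex$predicted_class[2], "exposed_nonactive")
  expect_match(pred_ex$flags[2], "excluded_by_list")
})

test_that("dual calls keep the class further above its mean, flagged", {
  # engineered so one residue exceeds both cutoffs
  sa <- c(5, 0.5, -2, -2, -1.5)
  sb <- c(3, 0.2, -1, -1, -1.2)
  act <- call_class(sa, 1); bur <- call_class(sb, 1)
  expect_true(act[1] && bur[1])
  cls <- if ((sa[1] - mean(sa)) / sqrt(mean((sa - mean(sa))^2)) >=
             (sb[1] - mean(sb)) / sqrt(mean((sb - mean(sb))^2))) "active_site" else "buried"
  # same decision through assign_classes on a table engineered to match
  cs <- data.frame(position = 1:5, z_mut_sens = (sa + sb) / 2,
                   z_acc = (sa - sb) / 2,
                   score_active = sa, score_buried = sb)
  pred <- assign_classes(structure(cs, class = c("combined_scores", "data.frame")), k = 1)
  expect_equal(pred$predicted_class[1], cls)
  expect_equal(pred$flags[1], "ambiguous_dual_call")
})

test_that("scale invariance: positive rescaling of inputs leaves calls unchanged", {
  set.seed(6)
  for (i in 1:10) {
    n <- sample(8:20, 1)
    sens <- runif(n); acc <- runif(n, 0, 100)
    mk <- function(s, a) assign_classes(combine_scores(
      structure(data.frame(position = 1:n, sensitivity = s),
                class = c("position_profile", "data.frame")),
      accessibility_table(1:n, a, source = "sequence_predicted")))
    p1 <- mk(sens, acc)
    p2 <- mk(sens * runif(1, 0.1, 7), acc * runif(1, 0.1, 7))
    expect_equal(p1$predicted_class, p2$predicted_class)
  }
})

test_that("calls equal brute-force oracle on small tables", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(5:12, 1)
    sens <- runif(n); acc <- runif(n, 0, 100)
    excl <- if (runif(1) < 0.3) sample(n, 1) else integer()
    cs <- combine_scores(
      structure(data.frame(position = 1:n, sensitivity = sens),
                class = c("position_profile", "data.frame")),
      accessibility_table(1:n, acc, source = "sequence_predicted"))
    pred <- assign_classes(cs, k = 1, exclusions = excl)
    expect_equal(pred$predicted_class, oracle_assign(sens, acc, 1, excl),
                 info = sprintf("case %d", i))
  }
})

test_that("raising sensitivity keeps a positive-z_acc residue in the active set", {
  set.seed(8)
  n <- 10
  sens <- runif(n); acc <- runif(n, 0, 100)
  i <- which.max(acc)           # guaranteed positive z_acc
  mk <- function(s) assign_classes(combine_scores(
    structure(data.frame(position = 1:n, sensitivity = s),
              class = c("position_profile", "data.frame")),
    accessibility_table(1:n, acc, source = "sequence_predicted")))
  base <- mk(sens)
  if (base$predicted_class[i] == "active_site") {
    for (bump in c(0.05, 0.15, 0.3)) {
      s2 <- sens; s2[i] <- min(sens[i] + bump, 1)
      expect_equal(mk(s2)$predicted_class[i], "active_site")
    }
  }
})

test_that("burial rule on structure accessibility uses <= 5 boundary", {
  acc <- accessibility_table(1:3, c(5.0, 5.1, 0), source = "structure")
  b <- burial_truth_from_structure(acc)
  expect_equal(b$burial, c("buried", "exposed", "buried"))
  seq_acc <- accessibility_table(1:3, c(5, 6, 7), source = "sequence_predicted")
  expect_error(burial_truth_from_structure(seq_acc),
               class = "dmsites_validation_error")
})
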