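test_that("dice matches set counting and handles degenerate masks", {
  a <- matrix(0L, 4, 4); b <- matrix(0L, 4, 4)
  a[1:2, 1:2] <- 1L
  expect_equal(dice(a, a), 1)
  b[3:4, 3:4] <- 1L
  expect_equal(dice(a, b), 0)
  # |A| = 4, |B| = 6, |A∩B| = 3 -> 2*3 / 10
  a2 <- matrix(0L, 4, 4); a2[1, 1:4] <- 1L
  b2 <- matrix(0L, 4, 4); b2[1, 2:4] <- 1L; b2[2, 1:3] <- 1L
  expect_equal(sum(a2), 4); expect_equal(sum(b2), 6)
  expect_equal(sum(a2 * b2), 3)
  expect_equal(dice(a2, b2), 0.6)
  expect_equal(dice(matrix(0L, 2, 2), matrix(0L, 2, 2)), 1.0)
  expect_error(dice(matrix(2L, 2, 2), matrix(0L, 2, 2)), "binary")
})

test_that("dice is symmetric and 1 only for identical masks", {
  set.seed(1)
  for (i in 1:20) {
    a <- matrix(rbinom(36, 1, 0.4), 6, 6)
    b <- matrix(rbinom(36, 1, 0.4), 6, 6)
    expect_equal(dice(a, b), dice(b, a))
    if (sum(a) > 0) {
      expect_equal(dice(a, b) == 1, identical(a + 0L, b + 0L))
    }
  }
})

test_that("auroc hits its worked examples", {
  expect_equal(auroc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(auroc(rep(0.5, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("auroc equals exhaustive pair counting for tie-inclusive inputs", {
  set.seed(2)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))[1:n]
    scores <- sample(1:4, n, replace = TRUE) / 4   # heavy ties
    expect_identical(auroc(scores, labels), oracle_auroc(scores, labels))
  }
})

test_that("auroc is invariant under strictly monotone transforms", {
  set.seed(3)
  scores <- runif(30); labels <- rbinom(30, 1, 0.5)
  labels[1:2] <- 0:1
  a <- auroc(scores, labels)
  expect_equal(auroc(exp(4 * scores) + 7, labels), a)
  expect_equal(auroc(qlogis((scores + 1) / 3), labels), a)
  expect_equal(auroc(-scores, 1 - labels), a)
  expect_equal(auroc(scores, 1 - labels), 1 - a)
})

test_that("patient scores average CC/MLO and fall back to other views", {
  expect_equal(patient_score(0.7, "MLO"), 0.7)
  expect_equal(patient_score(c(0.2, 0.6), c("CC", "MLO")), 0.4)
  # OTHER excluded when a standard view exists
  expect_equal(patient_score(c(0.2, 0.6, 0.9), c("CC", "MLO", "OTHER")), 0.4)
  expect_equal(patient_score(c(0.9, 0.5), c("OTHER", "OTHER")), 0.7)
  expect_error(patient_score(numeric(0), character(0)))
})

test_that("predictive values match contingency arithmetic", {
  perfect <- ppv_npv(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$npv, 1)
  # TP=2 FP=3 TN=10 FN=1
  scores <- c(rep(0.9, 2), rep(0.8, 3), rep(0.1, 10), rep(0.2, 1))
  labels <- c(rep(1, 2), rep(0, 3), rep(0, 10), rep(1, 1))
  pv <- ppv_npv(scores, labels)
  expect_equal(pv$ppv, 0.4)
  expect_equal(pv$npv, 10 / 11)
  # threshold 0: everything predicted positive, NPV undefined
  pv0 <- ppv_npv(scores, labels, threshold = 0)
  expect_true(is.na(pv0$npv))
  # the tie at the threshold counts positive
  pv5 <- ppv_npv(c(0.5, 0.4), c(1, 0))
  expect_equal(pv5$ppv, 1)
})

test_that("reports replay exactly from saved per-image predictions", {
  preds <- data.frame(
    patient_id = rep(c("A", "B", "C", "D"), each = 2),
    view = rep(c("CC", "MLO"), 4),
    prob = c(0.9, 0.8, 0.2, 0.3, 0.6, 0.7, 0.1, 0.15),
    label = rep(c(1, 0, 1, 0), each = 2),
    dice = runif(8))
  rep1 <- report_from_predictions(preds, "pure")
  # round trip through CSV (the saved artifact) and recompute
  path <- tempfile(fileext = ".csv")
  write.csv(preds, path, row.names = FALSE)
  rep2 <- report_from_predictions(read.csv(path), "pure")
  expect_equal(rep1$auroc, rep2$auroc)
  expect_equal(rep1$ppv, rep2$ppv)
  expect_equal(rep1$npv, rep2$npv)
  expect_equal(rep1$mean_dice, rep2$mean_dice)
  # oracle predictions give perfect metrics
  oracle <- data.frame(patient_id = letters[1:4], view = "CC",
                       prob = c(1, 0, 1, 0), label = c(1, 0, 1, 0),
                       dice = 1)
  r <- report_from_predictions(oracle)
  expect_equal(r$auroc, 1); expect_equal(r$ppv, 1); expect_equal(r$npv, 1)
})

test_that("evaluation drops excluded patients and errors when none remain", {
  mc <- micro_cohort()
  man <- mc$manifest
  net <- tiny_network(depth = 2, base = 2, input = 32, seed = 1)
  ac <- augmentation_config(crop_size = 32, max_perturb = 7)
  rep_up <- evaluate(list(net), man, "upstage", ac, root = mc$dir)
  expect_equal(rep_up$n_patients, 6)
  n_upstaged <- sum(tapply(man$upstaged, man$patient_id, any))
  rep_pure <- evaluate(list(net), man, "pure", ac, root = mc$dir)
  expect_equal(rep_pure$n_patients, 6 - n_upstaged)
  expect_true(rep_pure$auroc >= 0 && rep_pure$auroc <= 1)
  expect_true(rep_pure$mean_dice >= 0 && rep_pure$mean_dice <= 1)
  # replay oracle: the attached per-image table reproduces the report
  replay <- report_from_predictions(attr(rep_pure, "predictions"), "pure")
  expect_equal(replay$auroc, rep_pure$auroc)
  expect_equal(replay$mean_dice, rep_pure$mean_dice)
  # all-upstaged manifest leaves no eligible pure-scenario patients
  all_up <- man
  all_up$upstaged <- TRUE
  expect_error(evaluate(list(net), all_up, "pure", ac, root = mc$dir),
               "no eligible")
})

test_that("model averaging across folds averages probabilities", {
  mc <- micro_cohort()
  man <- mc$manifest[1, ]
  ac <- augmentation_config(crop_size = 32, max_perturb = 7)
  n1 <- tiny_network(depth = 2, base = 2, input = 32, seed = 1)
  n2 <- tiny_network(depth = 2, base = 2, input = 32, seed = 2)
  s <- read_image(file.path(mc$dir, man$image_path), man)
  m <- read_mask(file.path(mc$dir, man$mask_path))
  p1 <- dcisnet:::predict_image(list(n1), s, m, ac)
  p2 <- dcisnet:::predict_image(list(n2), s, m, ac)
  p12 <- dcisnet:::predict_image(list(n1, n2), s, m, ac)
  expect_equal(p12$prob, (p1$prob + p2$prob) / 2, tolerance = 1e-12)
  expect_equal(p12$seg_prob, (p1$seg_prob + p2$seg_prob) / 2,
               tolerance = 1e-12)
})
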