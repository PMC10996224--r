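# Evaluation: DICE overlap, rank-based AUROC, predictive values at the
# 0.5 likelihood threshold, per-patient multi-view averaging, and the
# scenario-wise evaluation report.

#' Dice similarity coefficient
#'
#' `2|A∩B| / (|A| + |B|)` between two binary masks. Two empty masks score
#' 1.0 (no lesion present, none predicted).
#'
#' @param pred,truth congruent binary matrices.
#' @return value in `[0, 1]`.
#' @export
dice <- function(pred, truth) {
  stopifnot(identical(dim(pred), dim(truth)))
  if (!is_binary(pred) || !is_binary(truth)) {
    stop("dice requires strictly binary masks", call. = FALSE)
  }
  sa <- sum(pred); sb <- sum(truth)
  if (sa + sb == 0) return(1.0)
  2 * sum(pred * truth) / (sa + sb)
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation with midrank tie handling:
#' `P(score+ > score-) + 0.5 P(score+ = score-)`. Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores numeric vector.
#' @param labels binary vector (0/1), both classes present.
#' @return value in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    stop("auroc requires both classes", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Patient-level score from per-view probabilities
#'
#' The final per-patient prediction is the arithmetic mean of the
#' available CC and MLO view probabilities; non-standard views (OTHER)
#' are excluded when a CC or MLO view exists and serve as fallback
#' otherwise, so every patient receives a score.
#'
#' @param probs numeric vector of per-image positive-class probabilities.
#' @param views character vector (`"CC"`, `"MLO"`, `"OTHER"`) parallel to
#'   `probs`.
#' @return scalar probability.
#' @export
patient_score <- function(probs, views) {
  stopifnot(length(probs) >= 1, length(probs) == length(views))
  std <- views %in% c("CC", "MLO")
  if (any(std)) mean(probs[std]) else mean(probs)
}

#' Positive and negative predictive value at a threshold
#'
#' Positive prediction is `score >= threshold` (the tie at the threshold
#' counts positive). A rate whose denominator is empty is reported as
#' `NA` (missing), not an error.
#'
#' @param scores numeric patient scores.
#' @param labels binary labels.
#' @param threshold decision threshold, default the clinical 0.5
#'   likelihood cut-off.
#' @return list with `ppv` and `npv`.
#' @export
ppv_npv <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  list(ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Rebuild an evaluation report from per-image predictions
#'
#' The report is a pure function of the per-image table, so a saved
#' prediction CSV replays to the identical report. AUROC is reported as
#' `NA` (missing) when the eligible patients form a single class.
#'
#' @param predictions data frame with columns `patient_id`, `view`,
#'   `prob`, `label`, `dice`.
#' @param scenario scenario tag carried into the report.
#' @param threshold decision threshold.
#' @return an `eval_report` list.
#' @export
report_from_predictions <- function(predictions, scenario = "pure",
                                    threshold = 0.5) {
  stopifnot(nrow(predictions) > 0)
  pids <- unique(predictions$patient_id)
  pscore <- vapply(pids, function(pid) {
    rows <- predictions[predictions$patient_id == pid, ]
    patient_score(rows$prob, rows$view)
  }, numeric(1))
  plabel <- vapply(pids, function(pid) {
    predictions$label[predictions$patient_id == pid][1]
  }, numeric(1))
  pv <- ppv_npv(pscore, plabel, threshold)
  au <- if (length(unique(plabel)) > 1) auroc(pscore, plabel) else NA_real_
  structure(list(scenario = scenario,
                 auroc = au,
                 ppv = pv$ppv, npv = pv$npv, threshold = threshold,
                 mean_dice = mean(predictions$dice),
                 n_patients = length(pids),
                 patient_scores = setNames(pscore, pids),
                 patient_labels = setNames(plabel, pids)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> scenario %s: n=%d patients, AUROC %.3f,",
                     " PPV %.3f, NPV %.3f (thr %.2f), mean DICE %.3f\n"),
              x$scenario, x$n_patients, x$auroc, x$ppv, x$npv, x$threshold,
              x$mean_dice))
  invisible(x)
}

# Per-image inference: eval transform, forward through each model,
# average the positive-class probability and the per-pixel lesion
# probability across models.
predict_image <- function(models, sample, mask, augment_cfg) {
  tr <- eval_transform(sample, mask, augment_cfg)
  probs_each <- numeric(length(models))
  seg_prob <- NULL
  for (i in seq_along(models)) {
    out <- net_forward(models[[i]], tr$image)
    probs_each[i] <- out$cls_probs[2]
    sp <- pixel_softmax_pos(out$seg_scores)
    seg_prob <- if (is.null(seg_prob)) sp / length(models)
                else seg_prob + sp / length(models)
  }
  list(prob = mean(probs_each), probs_each = probs_each,
       seg_prob = seg_prob, mask = tr$mask)
}

# per-pixel softmax probability of the lesion class (class 2)
pixel_softmax_pos <- function(seg_scores) {
  1 / (1 + exp(seg_scores[, , 1] - seg_scores[, , 2]))
}

#' Evaluate fold models on a test manifest
#'
#' For every eligible image: deterministic evaluation transform, forward
#' pass through each fold model, probability averaging across models,
#' then per-patient view averaging, AUROC and PPV/NPV at the 0.5
#' threshold, and mean DICE at a 0.5 per-pixel lesion probability.
#' `"pure"` drops upstaged patients before anything else.
#'
#' @param models list of `dcis_network` fold models.
#' @param manifest cohort manifest; rows with `split == "test"` are used
#'   (all rows if no split is assigned).
#' @param scenario `"pure"` or `"upstage"`.
#' @param augment_cfg an [augmentation_config()] (crop geometry).
#' @param root directory for the manifest's relative paths.
#' @param threshold decision threshold for PPV/NPV.
#' @return an `eval_report` including a `per_fold` breakdown (per-model
#'   patient-level AUROC); the per-image table is attached as attribute
#'   `"predictions"`.
#' @export
evaluate <- function(models, manifest, scenario = c("pure", "upstage"),
                     augment_cfg, root = attr(manifest, "root"),
                     threshold = 0.5) {
  scenario <- match.arg(scenario)
  rows <- manifest[manifest$split %in% c("test", "unassigned"), ]
  if (any(manifest$split == "test")) rows <- manifest[manifest$split == "test", ]
  rows$label <- scenario_label(rows$grade, rows$upstaged, scenario)
  rows <- rows[!is.na(rows$label), ]
  if (nrow(rows) == 0) {
    stop("no eligible patients for scenario '", scenario, "'", call. = FALSE)
  }
  per_model <- matrix(NA_real_, nrow(rows), length(models))
  preds <- lapply(seq_len(nrow(rows)), function(i) {
    sample <- read_image(file.path(root, rows$image_path[i]), rows[i, ])
    mask <- read_mask(file.path(root, rows$mask_path[i]),
                      expected_dim = dim(sample$image))
    pr <- predict_image(models, sample, mask, augment_cfg)
    per_model[i, ] <<- pr$probs_each
    data.frame(patient_id = rows$patient_id[i], view = rows$view[i],
               prob = pr$prob, label = rows$label[i],
               dice = dice((pr$seg_prob >= 0.5) + 0L, pr$mask),
               stringsAsFactors = FALSE)
  })
  preds <- do.call(rbind, preds)
  rep <- report_from_predictions(preds, scenario, threshold)
  # per-fold breakdown: patient-level AUROC of each fold model alone
  rep$per_fold <- data.frame(
    fold = seq_along(models),
    auroc = vapply(seq_along(models), function(m) {
      single <- preds
      single$prob <- per_model[, m]
      report_from_predictions(single, scenario, threshold)$auroc
    }, numeric(1)))
  attr(rep, "predictions") <- preds
  rep
}
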