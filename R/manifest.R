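# Cohort manifest: the patient-level table tying images, masks, labels,
# and partition assignments together. Serialised as versioned CSV.

MANIFEST_VERSION <- "dcisnet_manifest_v1"
MANIFEST_COLUMNS <- c("patient_id", "image_path", "mask_path", "view",
                      "laterality", "lesion_center_row", "lesion_center_col",
                      "grade", "upstaged", "split", "fold")

empty_manifest <- function() {
  data.frame(patient_id = character(), image_path = character(),
             mask_path = character(), view = character(),
             laterality = character(), lesion_center_row = integer(),
             lesion_center_col = integer(), grade = character(),
             upstaged = logical(), split = character(), fold = character(),
             stringsAsFactors = FALSE)
}

validate_manifest <- function(df) {
  if (!identical(names(df), MANIFEST_COLUMNS)) {
    stop("manifest columns must be exactly: ",
         paste(MANIFEST_COLUMNS, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) return(df)
  stopifnot(all(df$grade %in% c("I", "II", "III")),
            all(df$view %in% c("CC", "MLO", "OTHER")),
            all(df$laterality %in% c("L", "R")),
            is.logical(df$upstaged),
            all(df$split %in% c("train", "test", "unassigned")))
  split_per_pat <- tapply(df$split, df$patient_id,
                          function(s) length(unique(s)))
  if (any(split_per_pat > 1)) {
    bad <- names(split_per_pat)[split_per_pat > 1][1]
    stop("patient '", bad, "' appears in more than one split", call. = FALSE)
  }
  fold_per_pat <- tapply(df$fold, df$patient_id,
                         function(f) length(unique(f)))
  if (any(fold_per_pat > 1)) {
    bad <- names(fold_per_pat)[fold_per_pat > 1][1]
    stop("patient '", bad, "' appears in more than one fold", call. = FALSE)
  }
  df
}

#' Write a cohort manifest to versioned CSV
#'
#' @param manifest manifest data frame.
#' @param path output file.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(as.data.frame(manifest)[MANIFEST_COLUMNS])
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste0("#", MANIFEST_VERSION), con, sep = "\n")
  write.csv(manifest, con, row.names = FALSE, quote = TRUE, eol = "\n")
  invisible(path)
}

#' Read a cohort manifest from versioned CSV
#'
#' Rejects files with a missing/foreign version stamp, missing or extra
#' columns, or invariant violations (a patient in two splits or two
#' folds). The manifest's directory is attached as attribute `root`, the
#' base for its relative image/mask paths.
#'
#' @param path manifest file written by [write_manifest()].
#' @return validated manifest data frame.
#' @export
read_manifest <- function(path) {
  first <- readLines(path, n = 1)
  if (!identical(first, paste0("#", MANIFEST_VERSION))) {
    stop("'", path, "' is not a ", MANIFEST_VERSION, " file", call. = FALSE)
  }
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                 colClasses = c(patient_id = "character", fold = "character"))
  if (nrow(df) == 0) {
    df <- empty_manifest()
  } else {
    df$upstaged <- as.logical(df$upstaged)
  }
  structure(validate_manifest(df), root = dirname(normalizePath(path)))
}

#' Derive the binary label for an evaluation scenario
#'
#' Two ground-truth groupings are supported. `"pure"` excludes upstaged
#' cancers and contrasts grade III against grade I/II. `"upstage"` counts
#' grade III and/or upstaged disease as positive.
#'
#' @param grade character vector in `{"I","II","III"}`.
#' @param upstaged logical vector.
#' @param scenario `"pure"` or `"upstage"`.
#' @return integer vector: 1 (positive), 0 (negative), or `NA` (excluded).
#' @export
scenario_label <- function(grade, upstaged, scenario = c("pure", "upstage")) {
  scenario <- match.arg(scenario)
  stopifnot(all(grade %in% c("I", "II", "III")), is.logical(upstaged))
  if (scenario == "pure") {
    ifelse(upstaged, NA_integer_, as.integer(grade == "III"))
  } else {
    as.integer(grade == "III" | upstaged)
  }
}

# unique patient table (one row per patient) in first-appearance order
patient_table <- function(manifest) {
  idx <- !duplicated(manifest$patient_id)
  manifest[idx, c("patient_id", "grade", "upstaged", "split", "fold")]
}

#' Patient-level grade-stratified train/test split
#'
#' Assigns every patient (hence all of their images) to train or test.
#' The total test count is `round(n_patients * test_fraction)`,
#' apportioned across grade strata by largest-remainder quota, so each
#' stratum's test proportion is within one patient of the global fraction
#' (464 patients at 0.20 yield 93 test patients). A stratum too small to
#' appear on both sides is kept whole in train, with a warning.
#'
#' @param manifest cohort manifest.
#' @param test_fraction fraction of patients held out, in `[0, 1)`.
#' @param seed integer RNG seed; the assignment is deterministic given it.
#' @return the manifest with its `split` column populated.
#' @export
split_patient_level <- function(manifest, test_fraction = 0.20, seed = 1) {
  stopifnot(nrow(manifest) > 0, test_fraction >= 0, test_fraction < 1)
  pats <- patient_table(manifest)
  n <- nrow(pats)
  total_test <- round(n * test_fraction)
  strata <- c("I", "II", "III")
  sizes <- vapply(strata, function(g) sum(pats$grade == g), integer(1))
  present <- sizes > 0
  quota <- integer(3)
  if (total_test > 0) {
    quota[present] <- largest_remainder(total_test,
                                        sizes[present] / sum(sizes[present]))
    too_small <- present & quota >= sizes & sizes > 0 & quota > 0
    if (any(too_small)) {
      warning("stratum ", paste(strata[too_small], collapse = ","),
              " too small to split; assigned whole to train")
      quota[too_small] <- 0L
    }
  }
  test_ids <- with_seed(seed, {
    unlist(lapply(which(quota > 0), function(i) {
      ids <- pats$patient_id[pats$grade == strata[i]]
      sample(ids, quota[i])
    }))
  })
  manifest$split <- ifelse(manifest$patient_id %in% test_ids, "test", "train")
  validate_manifest(manifest)
}

#' Assign validation folds to training patients
#'
#' Each train-split patient is assigned one validation fold. Assignment is
#' stratified by grade: within each stratum patients are shuffled and
#' dealt round-robin, with the dealing position carried across strata so
#' fold sizes are balanced both per stratum (difference at most 1) and
#' globally.
#'
#' @param manifest manifest with the `split` column populated.
#' @param k number of folds (>= 2).
#' @param seed integer RNG seed.
#' @return the manifest with `fold` populated (`1..k` for train rows,
#'   `"unassigned"` otherwise).
#' @export
assign_folds <- function(manifest, k = 5, seed = 1) {
  stopifnot(k >= 2)
  pats <- patient_table(manifest)
  train_pats <- pats[pats$split == "train", ]
  if (nrow(train_pats) < k) {
    stop("fewer training patients (", nrow(train_pats), ") than folds (",
         k, ")", call. = FALSE)
  }
  assignment <- with_seed(seed, {
    pos <- 0
    out <- character(0)
    folds <- integer(0)
    for (g in c("I", "II", "III")) {
      ids <- train_pats$patient_id[train_pats$grade == g]
      if (!length(ids)) next
      ids <- sample(ids)
      f <- ((pos + seq_along(ids) - 1) %% k) + 1
      pos <- pos + length(ids)
      out <- c(out, ids)
      folds <- c(folds, f)
    }
    setNames(folds, out)
  })
  manifest$fold <- ifelse(manifest$split == "train",
                          as.character(assignment[manifest$patient_id]),
                          "unassigned")
  validate_manifest(manifest)
}
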