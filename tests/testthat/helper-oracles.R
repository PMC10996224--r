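# Independent oracles (plain, loop-based implementations kept deliberately
# separate from the package's vectorised/compiled code paths).

# naive per-pixel softmax cross-entropy via explicit loops
oracle_pixel_ce <- function(seg_scores, mask) {
  d <- dim(seg_scores)
  ce <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      s <- seg_scores[i, j, ]
      p <- exp(s) / sum(exp(s))
      ce[i, j] <- -log(p[mask[i, j] + 1])
    }
  }
  ce
}

# brute-force top-k cross-entropy: explicit sort of all per-pixel values
oracle_topk_ce <- function(seg_scores, mask, frac) {
  ce <- sort(as.vector(oracle_pixel_ce(seg_scores, mask)),
             decreasing = TRUE)
  k <- ceiling(frac * length(ce))
  mean(ce[seq_len(k)])
}

# exhaustive pairwise AUROC: count over every positive-negative pair
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# random small manifest (no image files) for partition tests
make_fake_manifest <- function(n_patients, grade_probs = c(.3, .416, .284),
                               upstage_rate = 0.147, views = c("CC", "MLO"),
                               seed = 1) {
  set.seed(seed)
  grades <- sample(c("I", "II", "III"), n_patients, replace = TRUE,
                   prob = grade_probs)
  counts <- dcisnet::largest_remainder(n_patients, grade_probs)
  grades <- sample(rep(c("I", "II", "III"), counts))
  upstaged <- seq_len(n_patients) %in%
    sample.int(n_patients, round(n_patients * upstage_rate))
  rows <- do.call(rbind, lapply(seq_len(n_patients), function(p) {
    data.frame(patient_id = sprintf("P%04d", p),
               image_path = sprintf("P%04d_%s.png", p, views),
               mask_path = sprintf("P%04d_%s_mask.png", p, views),
               view = views, laterality = "L",
               lesion_center_row = 10L, lesion_center_col = 10L,
               grade = grades[p], upstaged = upstaged[p],
               split = "unassigned", fold = "unassigned",
               stringsAsFactors = FALSE)
  }))
  rows
}

# a tiny trained-free network for inference-path tests
tiny_network <- function(depth = 2, base = 2, input = 16, seed = 1) {
  build_network(network_config(depth = depth, base_channels = base,
                               input_size = input), seed = seed)
}

# generate a micro image cohort on disk once per session (6 patients, 64 px)
micro_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "dcisnet-micro-cohort")
      cfg <- synthetic_cohort_config(6, image_size = 64, seed = 42)
      man <- generate_cohort(cfg, dir)
      cache <<- list(manifest = man, dir = dir)
    }
    cache
  }
})
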