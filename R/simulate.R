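#' Specification of a synthetic multimodal elderly cohort
#'
#' Describes the statistical shape of a simulated cohort of older subjects
#' carrying three feature modalities and a three-level health-risk label.
#' Class-conditional features are Gaussian: within each modality the class
#' means sit `effect_size * noise_sd` apart along seeded random directions,
#' with diagonal covariance `noise_sd^2`. The defaults mirror a small pilot
#' cohort: 50 subjects, balanced low/moderate/high risk classes, modality
#' widths 8 (physiological), 6 (behavioral), 4 (environmental), and a
#' decreasing informativeness ordering with physiological signals carrying
#' the strongest class signal.
#'
#' @param n_subjects cohort size (default 50).
#' @param class_proportions length-3 simplex vector over the risk classes.
#' @param modality_dims named integer vector of per-modality feature counts.
#' @param effect_size per-modality class-mean separation in units of
#'   `noise_sd` (recycled; 0 = that modality is pure noise).
#' @param noise_sd within-class standard deviation.
#' @param missing_rate fraction of raw cells blanked by [degrade_table()].
#' @param gap_rate expected sensor gaps per hour in
#'   [simulate_raw_physiology()].
#' @param seed integer seed; all generators are pure functions of
#'   (spec, seed).
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 50,
                        class_proportions = c(1, 1, 1) / 3,
                        modality_dims = c(physiological = 8, behavioral = 6,
                                          environmental = 4),
                        effect_size = c(2, 1.5, 1),
                        noise_sd = 1, missing_rate = 0.05, gap_rate = 2,
                        seed = 1) {
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stopf("class_proportions must sum to 1")
  }
  if (any(modality_dims < 1)) stopf("modality dims must be >= 1")
  effect_size <- rep_len(effect_size, length(modality_dims))
  if (any(effect_size < 0)) stopf("effect_size must be >= 0")
  if (noise_sd <= 0) stopf("noise_sd must be positive")
  if (missing_rate < 0 || missing_rate >= 1) stopf("missing_rate in [0, 1)")
  structure(list(n_subjects = n_subjects,
                 class_proportions = class_proportions,
                 modality_dims = modality_dims, effect_size = effect_size,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 gap_rate = gap_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Deterministic class counts: largest-remainder apportionment of
# n * proportions, so every class is always represented and stratified
# cross-validation preconditions hold at small n.
class_counts <- function(n, proportions) {
  raw <- n * proportions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Simulate a labeled multimodal cohort
#'
#' Draws one Gaussian class-conditional feature matrix per modality, labels
#' each subject with one of `C = 3` risk classes (counts allocated
#' deterministically from the class proportions, assignment shuffled by the
#' seed), and assigns a stratified 80/20 train/test split (40/10 at the
#' default `n = 50`).
#'
#' @param spec a [cohort_spec()].
#' @param seed overrides `spec$seed` when given.
#' @return List with `dataset` (a [multimodal_dataset()]) and `truth`
#'   (class labels, per-modality informative flags and generating means).
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- seed %||% spec$seed
  n <- spec$n_subjects
  counts <- class_counts(n, spec$class_proportions)
  if (any(counts == 0)) {
    stopf("class with zero expected members at n = %d", n)
  }
  C <- length(counts)
  with_seed(seed, {
    labels <- sample(rep.int(seq_len(C) - 1L, counts))
    ids <- sprintf("subj%03d", seq_len(n))

    tables <- vector("list", length(spec$modality_dims))
    means <- vector("list", length(spec$modality_dims))
    for (w in seq_along(spec$modality_dims)) {
      d <- spec$modality_dims[[w]]
      sep <- spec$effect_size[w] * spec$noise_sd
      mu <- matrix(0, C, d)
      for (cl in seq_len(C)) {
        u <- rnorm(d)
        mu[cl, ] <- sep * u / sqrt(sum(u^2))
      }
      X <- mu[labels + 1L, , drop = FALSE] +
        matrix(rnorm(n * d, sd = spec$noise_sd), n, d)
      colnames(X) <- paste0(names(spec$modality_dims)[w], "_f", seq_len(d))
      tables[[w]] <- modality_table(names(spec$modality_dims)[w], ids, X)
      means[[w]] <- mu
    }

    # stratified 80/20 split; per-class test counts by largest remainder
    n_test_target <- round(0.2 * n)
    raw <- 0.2 * counts
    test_counts <- floor(raw)
    short <- n_test_target - sum(test_counts)
    if (short > 0) {
      extra <- order(raw - test_counts, decreasing = TRUE)[seq_len(short)]
      test_counts[extra] <- test_counts[extra] + 1
    }
    split <- rep("train", n)
    for (cl in seq_len(C)) {
      members <- which(labels == cl - 1L)
      split[sample(members, test_counts[cl])] <- "test"
    }

    list(
      dataset = multimodal_dataset(tables, labels, split),
      truth = list(labels = labels,
                   informative = spec$effect_size > 0,
                   class_means = means, spec = spec)
    )
  })
}

#' Simulate raw wearable-style physiological streams
#'
#' Emits one timestamped heart-rate-like series per subject: a sinusoid at
#' the native 1 Hz rate (period 15 s, amplitude 5) around a class-dependent
#' baseline (60 / 75 / 90 beats per minute for low / moderate / high risk),
#' plus Gaussian noise, with 10-second sensor dropouts injected at
#' `spec$gap_rate` gaps per hour. Feeding the streams through
#' [summarize_timeseries()] recovers class-ordered window means.
#'
#' @param spec a [cohort_spec()].
#' @param labels integer class labels per subject (defaults to a fresh
#'   [simulate_cohort()] labeling under the same seed).
#' @param duration seconds of signal per subject (default 600).
#' @param seed overrides `spec$seed`.
#' @return Named list of `data.frame(time, value)`, one per subject.
#' @export
simulate_raw_physiology <- function(spec = cohort_spec(), labels = NULL,
                                    duration = 600, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- seed %||% spec$seed
  baselines <- c(60, 75, 90)
  amplitude <- 5
  period <- 15
  gap_len <- 10
  with_seed(seed, {
    if (is.null(labels)) {
      counts <- class_counts(spec$n_subjects, spec$class_proportions)
      labels <- sample(rep.int(seq_along(counts) - 1L, counts))
    }
    out <- vector("list", length(labels))
    for (i in seq_along(labels)) {
      t <- seq(0, duration - 1)
      v <- baselines[labels[i] + 1L] +
        amplitude * sin(2 * pi * t / period)
      if (spec$noise_sd > 0) v <- v + rnorm(length(t), sd = spec$noise_sd)
      n_gaps <- stats::rpois(1, spec$gap_rate * duration / 3600)
      if (n_gaps > 0) {
        starts <- runif(n_gaps, 0, duration - gap_len)
        drop <- rep(FALSE, length(t))
        for (s in starts) drop <- drop | (t > s & t < s + gap_len)
        t <- t[!drop]; v <- v[!drop]
      }
      out[[i]] <- data.frame(time = t, value = v)
    }
    names(out) <- sprintf("subj%03d", seq_along(labels))
    out
  })
}

#' Blank random cells of a raw table
#'
#' Each non-identifier cell is independently set to `NA` with probability
#' `missing_rate`; the `node_id` column is never blanked. Used to produce
#' realistic raw inputs for [preprocess_table()].
#'
#' @param table data frame with a `node_id` column (or id in column 1).
#' @param missing_rate probability in `[0, 1)`.
#' @param seed integer seed.
#' @return The degraded data frame.
#' @export
degrade_table <- function(table, missing_rate, seed = 1) {
  if (missing_rate < 0 || missing_rate >= 1) stopf("missing_rate in [0, 1)")
  table <- as.data.frame(table)
  id_col <- if ("node_id" %in% names(table)) "node_id" else names(table)[1]
  with_seed(seed, {
    for (cn in setdiff(names(table), id_col)) {
      hit <- runif(nrow(table)) < missing_rate
      table[[cn]][hit] <- NA
    }
    table
  })
}

#' Write a simulated cohort to delimited files
#'
#' Emits one `<modality>.csv` feature table per modality (first column
#' `node_id`, header row) plus `labels.csv` (`node_id,label`) — the same
#' formats [read_modality_table()] and [read_labels()] consume.
#'
#' @param dataset a [multimodal_dataset()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(dataset, dir) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tb in dataset$tables) {
    df <- data.frame(node_id = tb$node_ids, tb$features,
                     check.names = FALSE)
    write.table(df, file.path(dir, paste0(tb$modality_name, ".csv")),
                sep = ",", row.names = FALSE, quote = FALSE)
  }
  lab <- data.frame(node_id = dataset$node_ids, label = dataset$labels,
                    split = dataset$split)
  write.table(lab, file.path(dir, "labels.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}
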