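# Fast end-to-end checks of cross_validate on a small synthetic dataset
# with a compact encoder and model; the full-scale signal-recovery runs
# live in test-acceptance.R.

tiny_cv <- function(signal, seed = 1, k = 3) {
  ds <- generate_ppi_dataset(synthetic_config(
    n_pairs = 60, length_range = c(30L, 50L), signal_strength = signal,
    seed = seed))
  cross_validate(
    ds,
    encoder = encoder_config(sct_alphabet = "class7", use_pssm = FALSE,
                             use_aaindex = FALSE),
    model = model_config(hidden_sizes = c(16L, 8L), max_epochs = 12L,
                         early_stop_patience = 4L, batch_size = 16L,
                         seed = seed),
    k = k, seed = seed, keep_fold_details = TRUE)
}

test_that("cross_validate covers every pair once and reports coherent metrics", {
  rep <- tiny_cv(signal = 1)
  expect_s3_class(rep, "cv_report")
  expect_equal(sort(unique(rep$assignments)), 1:3)
  expect_equal(length(rep$assignments), 60L)
  # pooled counts add up to the dataset size
  expect_equal(rep$pooled$tp + rep$pooled$tn + rep$pooled$fp + rep$pooled$fn,
               60)
  expect_equal(nrow(rep$folds), 3L)
  # tidiers
  expect_equal(nrow(tidy(rep)), 3L)
  expect_true("accuracy" %in% names(glance(rep)))
  st <- cv_summary_table(rep)
  expect_equal(st$metric[1], "accuracy")
  expect_true(all(c("mean", "sd", "pooled") %in% names(st)))
})

test_that("per-fold standardization centers training portions only", {
  rep <- tiny_cv(signal = 1)
  for (d in rep$details) {
    expect_lt(d$train_feature_mean_max, 1e-6)
  }
  # held-out means are generally nonzero (no recentring with test data)
  expect_gt(max(vapply(rep$details, function(d) d$test_feature_mean_max,
                       numeric(1))), 1e-6)
})

test_that("cross_validate is reproducible from its seeds", {
  r1 <- tiny_cv(signal = 1, seed = 4)
  r2 <- tiny_cv(signal = 1, seed = 4)
  expect_equal(r1$folds, r2$folds)
  expect_identical(r1$assignments, r2$assignments)
})

test_that("fold-wise PSSM fitting uses training-pair sequences only", {
  ds <- generate_ppi_dataset(synthetic_config(
    n_pairs = 30, length_range = c(20L, 30L), seed = 2))
  enc <- encoder_config(use_ct = FALSE, use_sct = FALSE, use_aaindex = FALSE,
                        use_hydropathy = FALSE, use_aapd = FALSE,
                        pssm_L_max = 30)
  # feature matrices differ between leakage-free and global PSSM fits
  static <- NULL
  f_train <- ppitriad:::.fold_feature_matrix(
    ds, enc, static, NULL, train_rows = 1:20)
  gp <- build_dataset_pssm(ds$sequences, enc)
  f_all <- ppitriad:::.pssm_block_matrix(ds$sequences, gp, enc)
  expect_false(isTRUE(all.equal(unname(f_train[, 1:30]), unname(f_all))))
  # training-only fit reproduces a PSSM built from those sequences alone
  train_ids <- unique(c(ds$pairs$id_a[1:20], ds$pairs$id_b[1:20]))
  p_ref <- build_dataset_pssm(
    ds$sequences[ds$sequences$id %in% train_ids, ], enc)
  f_ref <- ppitriad:::.pssm_block_matrix(ds$sequences, p_ref, enc)
  expect_equal(unname(f_train[, 1:30]), unname(f_ref))
})

test_that("balanced-class accuracy equals (recall + specificity) / 2", {
  # integer-count identity on any balanced evaluation
  set.seed(31)
  for (i in 1:30) {
    n <- 2 * sample(5:40, 1)
    y <- rep(c(0L, 1L), each = n / 2)
    p <- rbinom(n, 1, 0.5)
    m <- compute_metrics(confusion_counts(y, p))
    expect_equal(m$accuracy, (m$recall + m$specificity) / 2,
                 tolerance = 1e-12)
  }
})
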