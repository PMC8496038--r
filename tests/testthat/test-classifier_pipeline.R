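# small world reused by several blocks: 5 informative motifs + 40 decoys
make_small_run <- function(seed = 19, n_pos = 150, n_neg = 150) {
  spec <- synthetic_spec(n_tfs = 45, seed = seed)
  mono <- make_monomer_catalog(spec)
  true_idx <- 1:5
  ds0 <- make_labeled_sequences(mono[true_idx], "billboard", n_pos = n_pos,
                                n_neg = n_neg, length = 200,
                                sites_per_positive = 5, spec = spec)
  cfg <- scan_config(p_value = 1e-4)
  pos <- ds0$sequences$seq[ds0$sequences$label == "positive"]
  neg <- ds0$sequences$seq[ds0$sequences$label == "negative"]
  ds <- build_dataset(pos, neg, mono, cfg,
                      chromosomes = ds0$sequences$chrom)
  list(spec = spec, mono = mono, ds = ds, cfg = cfg,
       true_ids = vapply(mono[true_idx], function(m) m$id, character(1)))
}

run <- make_small_run()

test_that("build_dataset assembles balanced scaled features", {
  ds <- run$ds
  expect_s3_class(ds, "LabeledDataset")
  expect_false(ds$imbalanced)
  expect_equal(nrow(ds$features), 300)
  expect_equal(ncol(ds$features), 45)
  expect_equal(nrow(ds$sequences), nrow(ds$features))
  # scaled features have mean ~0 and sd ~1 (or exactly 0 if constant)
  mu <- colMeans(ds$scaled)
  expect_true(all(abs(mu) < 1e-8))
  sds <- apply(ds$scaled, 2, sd)
  expect_true(all(abs(sds - 1) < 1e-8 | sds == 0))
  expect_warning(build_dataset(c("ACGT"), c("ACGT", "TTTT", "GGGG"),
                               run$mono[1:2], run$cfg), "imbalanced")
})

test_that("zero-variance features scale to zeros, not NaN", {
  f <- matrix(c(1, 1, 1, 0, 2, 4), ncol = 2)
  s <- regspec:::scale_features(f, colMeans(f), apply(f, 2, sd))
  expect_true(all(is.finite(s)))
  expect_equal(s[, 1], rep(0, 3))
})

test_that("chromosome-held-out training recovers implanted motifs", {
  trc <- paste0("chr", 1:16)
  tec <- paste0("chr", 17:23)
  model <- chromosome_split_train(run$ds, trc, tec, selection = "none")
  expect_gt(model$auroc, 0.9)
  top10 <- names(sort(abs(model$weights), decreasing = TRUE))[1:10]
  expect_true(all(run$true_ids %in% top10))
  expect_error(chromosome_split_train(run$ds, trc, c("chr16", "chr20"),
                                      selection = "none"), "overlap")
})

test_that("shuffled labels give chance AUROC", {
  # mean over shuffles: null AUROC sd on ~90 held-out sequences is ~0.06
  aucs <- withr::with_seed(5, vapply(1:5, function(i) {
    ds <- run$ds
    ds$sequences$label <- sample(ds$sequences$label)
    chromosome_split_train(ds, paste0("chr", 1:16), paste0("chr", 17:23),
                           selection = "none")$auroc
  }, numeric(1)))
  expect_lt(abs(mean(aucs) - 0.5), 0.08)
})

test_that("feature selection modes return the promised feature counts", {
  trc <- paste0("chr", 1:16); tec <- paste0("chr", 17:23)
  m_all <- chromosome_split_train(run$ds, trc, tec, selection = "none")
  m_rfe <- chromosome_split_train(run$ds, trc, tec, selection = "rfe",
                                  params = list(k = 10))
  expect_length(m_rfe$selected_features, 10)
  expect_true(all(run$true_ids %in% m_rfe$selected_features))
  # rfe with k = n_motifs is identical to no selection
  m_rfe_all <- chromosome_split_train(run$ds, trc, tec, selection = "rfe",
                                      params = list(k = 45))
  expect_equal(m_rfe_all$weights, m_all$weights)
  expect_equal(m_rfe_all$auroc, m_all$auroc)
  # sparse penalties select a subset
  m_l1 <- chromosome_split_train(run$ds, trc, tec, selection = "l1",
                                 params = list(C = 0.05))
  expect_lt(length(m_l1$selected_features), 45)
  expect_gt(length(m_l1$selected_features), 0)
  m_en <- chromosome_split_train(run$ds, trc, tec, selection = "elasticnet",
                                 params = list(C = 0.05, l1_ratio = 0.5))
  expect_gt(length(m_en$selected_features), 0)
})

test_that("auroc is rank-based and monotone-invariant", {
  withr::with_seed(31, {
    sc <- c(rnorm(50, 1), rnorm(50))
    lab <- rep(c("positive", "negative"), each = 50)
    a1 <- auroc(sc, lab)
    expect_equal(auroc(exp(sc), lab), a1)        # strictly monotone map
    expect_equal(auroc(rank(sc), lab), a1)
    expect_equal(auroc(-sc, lab), 1 - a1)
  })
  expect_equal(auroc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
})

test_that("tile_and_score localizes an implanted cluster", {
  model <- chromosome_split_train(run$ds, paste0("chr", 1:16),
                                  paste0("chr", 17:23), selection = "none")
  region_len <- 6000
  bg <- random_background(region_len, seed = 77)
  ins <- make_labeled_sequences(run$mono[1:5], "billboard", n_pos = 1,
                                n_neg = 0, length = 200,
                                sites_per_positive = 5, spec = run$spec)
  at <- 3000
  region <- paste0(substr(bg, 1, at), ins$sequences$seq[1],
                   substr(bg, at + 201, region_len))
  track <- tile_and_score(model, region, run$mono, window = 200,
                          stride = 20, cfg = run$cfg)
  best <- track$start[which.max(track$score)]
  expect_lt(abs(best - at), 220)
  # homogeneous background scores stay below the implant score
  expect_gt(max(track$score),
            max(track$score[track$start < 2500 | track$start > 3700]))
})

test_that("region tiling features equal per-window scanning", {
  reg <- random_background(2500, seed = 55)
  rf <- region_hit_count_features(reg, run$mono[1:15], run$cfg, 200, 20)
  wins <- substring(reg, rf$starts + 1, rf$starts + 200)
  f2 <- hit_count_features(wins, run$mono[1:15], run$cfg)
  expect_identical(unname(rf$features), unname(f2))
  # stride equal to window: non-overlapping partition
  rf2 <- region_hit_count_features(reg, run$mono[1:5], run$cfg, 200, 200)
  expect_equal(length(rf2$starts), 12)
})

test_that("calibrate_threshold hits the target quantile", {
  withr::with_seed(9, scores <- runif(5000))
  thr <- calibrate_threshold(scores, 0.01)
  expect_equal(thr, quantile(scores, 0.99, names = FALSE), tolerance = 0.01)
  expect_lte(mean(scores >= thr), 0.01)
  expect_equal(calibrate_threshold(scores, 1), min(scores))
  expect_error(calibrate_threshold(rep(1, 10), 0.01), "all scores")
  # ties broken toward fewer positives
  tied <- c(rep(5, 50), 1:50)
  thr2 <- calibrate_threshold(tied, 0.3)
  expect_lte(mean(tied >= thr2), 0.3)
})

test_that("predict_scores matches the training-time linear predictor", {
  model <- chromosome_split_train(run$ds, paste0("chr", 1:16),
                                  paste0("chr", 17:23), selection = "none")
  sc1 <- predict_scores(model, run$ds$features)
  sc2 <- score_sequences(model, run$ds$seqs, run$mono, run$cfg)
  expect_equal(sc1, sc2)
  path <- withr::local_tempfile()
  write_model(model, path)
  expect_true(file.exists(paste0(path, ".weights.tsv")))
  hdr <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(hdr$intercept, model$intercept, tolerance = 1e-9)
})
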