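#' Build a labeled dataset of hit-count features
#'
#' Scans positive and negative sequences with a motif set (default p = 1e-4)
#' and z-scores each hit-count feature (standard scaling; zero-variance
#' features scale to zeros, not NaN).
#'
#' @param positives,negatives character vectors of DNA sequences (or a single
#'   FASTA path each).
#' @param motifs list of MotifRecord.
#' @param cfg ScanConfig (default p = 1e-4, both strands).
#' @param chromosomes optional character vector of chromosome tags, one per
#'   sequence (positives then negatives); default round-robin over
#'   chr1..chr23 within each label so chromosome splits are exercisable.
#' @return object of class `LabeledDataset`: list(sequences = data.frame(id,
#'   chrom, label), seqs, features, scaled, scaler, motif_ids).
#' @export
build_dataset <- function(positives, negatives, motifs, cfg = scan_config(),
                          chromosomes = NULL) {
  read_if_path <- function(x) {
    if (length(x) == 1 && nchar(x) < 500 && file.exists(x)) {
      s <- Biostrings::readDNAStringSet(x)
      stats::setNames(as.character(s), names(s))
    } else x
  }
  positives <- read_if_path(positives)
  negatives <- read_if_path(negatives)
  np <- length(positives); nn <- length(negatives)
  if (np == 0 || nn == 0) stop("need at least one positive and one negative")
  imbalanced <- abs(np - nn) / (np + nn) > 0.01
  if (imbalanced) {
    warning("dataset imbalanced: ", np, " positives vs ", nn, " negatives")
  }
  seqs <- c(positives, negatives)
  label <- c(rep("positive", np), rep("negative", nn))
  if (is.null(chromosomes)) {
    chromosomes <- c(paste0("chr", (seq_len(np) - 1) %% 23 + 1),
                     paste0("chr", (seq_len(nn) - 1) %% 23 + 1))
  }
  stopifnot(length(chromosomes) == np + nn)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq%05d", seq_along(seqs))
  features <- hit_count_features(seqs, motifs, cfg)
  mu <- colMeans(features)
  sdv <- apply(features, 2, stats::sd)
  scaled <- scale_features(features, mu, sdv)
  structure(list(
    sequences = data.frame(id = ids, chrom = chromosomes, label = label,
                           stringsAsFactors = FALSE),
    seqs = unname(seqs),
    features = features,
    scaled = scaled,
    scaler = list(mean = mu, sd = sdv),
    motif_ids = colnames(features),
    imbalanced = imbalanced
  ), class = "LabeledDataset")
}

scale_features <- function(x, mu, sdv) {
  s <- sweep(x, 2, mu, "-")
  sdv_safe <- ifelse(sdv > 0, sdv, 1)
  s <- sweep(s, 2, sdv_safe, "/")
  s[, sdv == 0] <- 0
  s
}

#' Area under the ROC curve
#'
#' Rank-based (Wilcoxon) AUROC; invariant under strictly monotone transforms
#' of the scores.
#'
#' @param scores numeric prediction scores.
#' @param labels logical or "positive"/"negative" labels.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "positive"
  n1 <- sum(pos); n0 <- sum(!pos)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

fit_lr <- function(X, y, alpha, lambda) {
  # features constant within the training split get weight 0
  keep <- apply(X, 2, function(col) any(col != col[1]))
  w <- stats::setNames(numeric(ncol(X)), colnames(X))
  if (!any(keep)) {
    p1 <- mean(y)
    return(list(weights = w, intercept = stats::qlogis(min(max(p1, 1e-12),
                                                           1 - 1e-12))))
  }
  fit <- glmnet::glmnet(X[, keep, drop = FALSE], y, family = "binomial",
                        alpha = alpha, lambda = lambda, standardize = FALSE)
  w[rownames(fit$beta)] <- as.numeric(fit$beta[, 1])
  list(weights = w, intercept = as.numeric(fit$a0[1]))
}

#' Train a logistic-regression model on a chromosome-held-out split
#'
#' Fits on sequences from `train_chroms` only and reports AUROC on
#' `test_chroms`. Feature selection: "none" (ridge, the sklearn-default L2
#' analog), "rfe" (recursive feature elimination to exactly `k` features),
#' "l1" (lasso at strength C), or "elasticnet" (C and l1_ratio).
#'
#' @param ds LabeledDataset.
#' @param train_chroms,test_chroms disjoint chromosome tag sets.
#' @param selection one of "none", "rfe", "l1", "elasticnet".
#' @param params list; recognised: `k` (rfe feature count, default 150),
#'   `C` (inverse regularization; defaults 1 for none/rfe, 0.00125 for l1,
#'   0.0007 for elasticnet), `l1_ratio` (default 0.5).
#' @return object of class `TrainedModel`: weights, intercept,
#'   selected_features, decision_threshold (logit scale, 0), scaler,
#'   motif_ids, auroc, selection.
#' @export
chromosome_split_train <- function(ds, train_chroms, test_chroms,
                                   selection = c("none", "rfe", "l1",
                                                 "elasticnet"),
                                   params = list()) {
  selection <- match.arg(selection)
  if (length(intersect(train_chroms, test_chroms)) > 0) {
    stop("train and test chromosome sets overlap: ",
         paste(intersect(train_chroms, test_chroms), collapse = ","))
  }
  tr <- ds$sequences$chrom %in% train_chroms
  te <- ds$sequences$chrom %in% test_chroms
  if (!any(tr) || !any(te)) stop("empty train or test split")
  y <- as.integer(ds$sequences$label == "positive")
  X <- ds$scaled
  n <- sum(tr)
  C_default <- switch(selection, l1 = 0.00125, elasticnet = 0.0007, 1)
  C <- if (!is.null(params$C)) params$C else C_default
  lam <- 1 / (n * C)
  alpha <- switch(selection, l1 = 1,
                  elasticnet = if (!is.null(params$l1_ratio))
                    params$l1_ratio else 0.5,
                  0)
  sel <- colnames(X)
  if (selection == "rfe") {
    k <- if (!is.null(params$k)) params$k else 150
    stopifnot(k >= 1, k <= ncol(X))
    while (length(sel) > k) {
      f <- fit_lr(X[tr, sel, drop = FALSE], y[tr], alpha = 0, lambda = lam)
      drop_n <- min(max(1L, ceiling(0.1 * length(sel))), length(sel) - k)
      sel <- sel[rank(abs(f$weights), ties.method = "first") > drop_n]
    }
  }
  f <- fit_lr(X[tr, sel, drop = FALSE], y[tr], alpha = alpha, lambda = lam)
  if (selection %in% c("l1", "elasticnet")) {
    keep <- abs(f$weights) > 0
    sel <- sel[keep]
  }
  w <- f$weights[match(sel, names(f$weights))]
  scores_test <- as.numeric(X[te, sel, drop = FALSE] %*% w + f$intercept)
  model <- structure(list(
    weights = w,
    intercept = f$intercept,
    selected_features = sel,
    decision_threshold = 0,
    scaler = ds$scaler,
    motif_ids = ds$motif_ids,
    selection = selection,
    auroc = auroc(scores_test, ds$sequences$label[te])
  ), class = "TrainedModel")
  model
}

#' @export
print.TrainedModel <- function(x, ...) {
  cat(sprintf("TrainedModel: %d/%d features (%s), held-out AUROC %.3f\n",
              length(x$selected_features), length(x$motif_ids), x$selection,
              x$auroc))
  invisible(x)
}

#' Score raw hit-count features with a trained model
#'
#' @param model TrainedModel.
#' @param features integer count matrix with the model's motif columns.
#' @return numeric scores on the logit scale.
#' @export
predict_scores <- function(model, features) {
  idx <- match(model$selected_features, colnames(features))
  if (anyNA(idx)) stop("feature matrix lacks model features")
  mu <- model$scaler$mean[model$selected_features]
  sdv <- model$scaler$sd[model$selected_features]
  Xs <- scale_features(features[, idx, drop = FALSE], mu, sdv)
  as.numeric(Xs %*% model$weights + model$intercept)
}

#' Score raw sequences with a trained model
#'
#' @param model TrainedModel.
#' @param sequences character vector of DNA sequences.
#' @param motifs motif list covering the model's selected features.
#' @param cfg ScanConfig (must match the training scan settings).
#' @return numeric scores on the logit scale.
#' @export
score_sequences <- function(model, sequences, motifs, cfg = scan_config()) {
  ids <- vapply(motifs, function(m) m$id, character(1))
  need <- ids %in% model$selected_features
  feats <- hit_count_features(sequences, motifs[need], cfg)
  predict_scores(model, feats)
}

#' Per-window hit-count features over a tiled region
#'
#' Scans the whole region once per motif and bins hits into overlapping
#' windows (a hit is counted in every window that fully contains it) —
#' identical counts to scanning each window separately.
#'
#' @param region DNA string.
#' @param motifs list of MotifRecord.
#' @param cfg ScanConfig.
#' @param window window size in bp.
#' @param stride window start increment in bp.
#' @return list(starts, features): 0-based window starts and the
#'   n_windows x n_motifs count matrix.
#' @export
region_hit_count_features <- function(region, motifs, cfg = scan_config(),
                                      window = 200, stride = 20) {
  len <- nchar(region)
  stopifnot(len >= window, stride >= 1)
  starts <- seq(0, len - window, by = stride)
  nw <- length(starts)
  ids <- vapply(motifs, function(m) m$id, character(1))
  codes <- encode_dna(region)
  out <- matrix(0L, nrow = nw, ncol = length(ids),
                dimnames = list(NULL, ids))
  for (k in seq_along(motifs)) {
    prep <- prepare_scan(motifs[[k]], cfg)
    if (len < prep$L) next
    h <- scan_codes(codes, prep, cfg)
    for (p in h$start) {
      lo <- max(0L, as.integer(ceiling((p + prep$L - window) / stride)))
      hi <- min(nw - 1L, as.integer(floor(p / stride)))
      if (hi >= lo) {
        idx <- (lo:hi) + 1L
        out[idx, k] <- out[idx, k] + 1L
      }
    }
  }
  list(starts = starts, features = out)
}

#' Tile a region into overlapping windows and score each
#'
#' @param model TrainedModel.
#' @param region DNA string (>= window long).
#' @param motifs motif list covering the model's selected features.
#' @param window window size in bp (default 200).
#' @param stride window start increment in bp (default 20).
#' @param cfg ScanConfig.
#' @return data.frame (start, end, score), 0-based half-open coordinates.
#' @export
tile_and_score <- function(model, region, motifs, window = 200, stride = 20,
                           cfg = scan_config()) {
  ids <- vapply(motifs, function(m) m$id, character(1))
  need <- ids %in% model$selected_features
  rf <- region_hit_count_features(region, motifs[need], cfg, window, stride)
  data.frame(start = rf$starts, end = rf$starts + window,
             score = predict_scores(model, rf$features))
}

#' Per-base positive fraction of a scored tiling
#'
#' Fraction of region bases covered by at least one positive-scoring window.
#'
#' @param track data.frame from [tile_and_score()].
#' @param threshold decision threshold (positive means score >= threshold).
#' @param region_length total region length in bp.
#' @return fraction in [0, 1].
#' @export
positive_base_fraction <- function(track, threshold, region_length) {
  pos <- track[track$score >= threshold, , drop = FALSE]
  if (nrow(pos) == 0) return(0)
  cov <- logical(region_length)
  for (i in seq_len(nrow(pos))) {
    cov[(pos$start[i] + 1):min(pos$end[i], region_length)] <- TRUE
  }
  mean(cov)
}

#' Calibrate a decision threshold to a target positive rate
#'
#' Returns the (1 - target) empirical quantile of the scores: the smallest
#' observed score such that the fraction of scores at or above it does not
#' exceed the target (ties broken toward fewer positives). Positive means
#' score >= threshold.
#'
#' @param scores numeric scores (non-empty, not all equal).
#' @param target_positive_fraction target positive rate (default 0.01).
#' @return decision threshold.
#' @export
calibrate_threshold <- function(scores, target_positive_fraction = 0.01) {
  stopifnot(length(scores) > 0, target_positive_fraction > 0,
            target_positive_fraction <= 1)
  us <- sort(unique(scores), decreasing = TRUE)
  if (length(us) == 1) stop("cannot calibrate: all scores are equal")
  n <- length(scores)
  frac <- cumsum(tabulate(match(scores, us), nbins = length(us))) / n
  ok <- which(frac <= target_positive_fraction)
  thr <- if (length(ok) == 0) us[1] else us[max(ok)]
  achieved <- mean(scores >= thr)
  if (abs(achieved - target_positive_fraction) > 0.002 &&
      target_positive_fraction < 1) {
    warning(sprintf("calibrated positive fraction %.4f is > 0.2 pp from target %.4f",
                    achieved, target_positive_fraction))
  }
  thr
}

#' Save a trained model as TSV weights plus a JSON header
#'
#' @param model TrainedModel.
#' @param prefix output path prefix; writes `<prefix>.weights.tsv` and
#'   `<prefix>.json`.
#' @export
write_model <- function(model, prefix) {
  wtsv <- paste0(prefix, ".weights.tsv")
  write.table(data.frame(motif_id = model$selected_features,
                         weight = unname(model$weights)),
              wtsv, sep = "\t", quote = FALSE, row.names = FALSE)
  hdr <- list(intercept = model$intercept,
              decision_threshold = model$decision_threshold,
              selection = model$selection, auroc = model$auroc,
              scaler_mean = as.list(model$scaler$mean),
              scaler_sd = as.list(model$scaler$sd))
  jsonlite::write_json(hdr, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}
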