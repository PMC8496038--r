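#' Neutral mutation of an integer-encoded sequence
#'
#' Each base is independently substituted with probability `rate`; the
#' replacement is drawn uniformly from the three alternative bases (so at
#' rate 1 no position retains its original base). Ambiguous positions are
#' left untouched. Length is preserved.
#'
#' @param codes integer base codes (see [encode_dna()]).
#' @param rate per-base substitution probability in [0, 1].
#' @return mutated integer codes.
#' @export
mutate_codes <- function(codes, rate) {
  stopifnot(rate >= 0, rate <= 1)
  n <- length(codes)
  if (n == 0 || rate == 0) return(codes)
  hit <- which(runif(n) < rate & codes >= 0)
  if (length(hit)) {
    codes[hit] <- (codes[hit] + sample.int(3, length(hit),
                                           replace = TRUE)) %% 4L
  }
  codes
}

#' Neutral mutation of a DNA string
#'
#' @param seq DNA string.
#' @param rate per-base substitution probability (defaults of interest:
#'   0.06 human/macaque, 0.49 human/mouse neutral rates).
#' @return mutated DNA string of the same length.
#' @export
mutate_sequence <- function(seq, rate) {
  decode_dna(mutate_codes(encode_dna(seq), rate))
}

pool_ci <- function(retained, n) {
  if (n == 0) return(c(NA_real_, NA_real_))
  ci <- stats::binom.test(retained, n)$conf.int
  c(ci[1], ci[2])
}

#' Classifier-defined element dropout under neutral mutation
#'
#' Mutates positive-scoring elements at each rate, re-scores them with the
#' trained model, and reports the fraction still at or above the model's
#' decision threshold.
#'
#' @param model TrainedModel with a calibrated `decision_threshold`.
#' @param elements character vector of sequences, all scoring at or above
#'   the threshold pre-mutation (validated).
#' @param motifs motif list covering the model's selected features.
#' @param rates substitution rates (default c(0.06, 0.49)).
#' @param replicates mutation replicates per rate (default 10).
#' @param cfg ScanConfig.
#' @param seed optional RNG seed (same seed + inputs gives an identical
#'   report).
#' @return object of class `TurnoverReport`: data.frame (rate, n_elements,
#'   n_retained, retained_fraction, ci_lo, ci_hi) with a `replicates`
#'   attribute holding the per-replicate breakdown.
#' @export
classifier_dropout <- function(model, elements, motifs,
                               rates = c(0.06, 0.49), replicates = 10,
                               cfg = scan_config(), seed = NULL) {
  if (length(elements) == 0) stop("element set must be non-empty")
  pre <- score_sequences(model, elements, motifs, cfg)
  if (any(pre < model$decision_threshold)) {
    stop(sum(pre < model$decision_threshold),
         " input elements score below the decision threshold pre-mutation")
  }
  run <- function() {
    det <- do.call(rbind, lapply(rates, function(r) {
      do.call(rbind, lapply(seq_len(replicates), function(rep) {
        mut <- vapply(elements, mutate_sequence, character(1), rate = r,
                      USE.NAMES = FALSE)
        sc <- score_sequences(model, mut, motifs, cfg)
        data.frame(rate = r, replicate = rep, n = length(elements),
                   retained = sum(sc >= model$decision_threshold))
      }))
    }))
    det
  }
  det <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  pooled <- do.call(rbind, lapply(split(det, det$rate), function(d) {
    n <- sum(d$n); ret <- sum(d$retained)
    ci <- pool_ci(ret, n)
    data.frame(rate = d$rate[1], n_elements = n, n_retained = ret,
               retained_fraction = ret / n, ci_lo = ci[1], ci_hi = ci[2])
  }))
  rownames(pooled) <- NULL
  structure(pooled, replicates = det, class = c("TurnoverReport",
                                                "data.frame"))
}

#' Multimeric-motif hit turnover under neutral mutation
#'
#' Scans a large random background corpus for multimer hits at several
#' stringent p-value cutoffs, mutates each hit locus (plus a one-motif-length
#' flank on each side) at each rate, rescans the window at the same
#' threshold, and reports the retained fraction per (arity, cutoff, rate)
#' stratum. Strata with zero pre-mutation hits are reported as NA.
#'
#' The corpus is streamed in chunks and generation stops early once
#' `min_hits` hits at the loosest cutoff have been collected (the scaled-down
#' stand-in for the paper-scale 32-Gb scan).
#'
#' @param motifs list of multimeric MotifRecord (arity >= 3).
#' @param p_cutoffs p-value cutoffs (default c(1e-11, 1e-10, 1e-9)).
#' @param rates substitution rates (default c(0.06, 0.49)).
#' @param corpus_size total corpus size in bp (default 1e8).
#' @param chunk_size streaming chunk size in bp.
#' @param gc corpus GC fraction.
#' @param min_hits stop streaming once this many loosest-cutoff hits are
#'   found (0 means scan the full corpus).
#' @param replicates mutation replicates per rate (default 10).
#' @param cfg ScanConfig; its p_value field is ignored in favor of
#'   `p_cutoffs`.
#' @param seed RNG seed (byte-identical report for identical inputs).
#' @return object of class `TurnoverReport`: data.frame (arity, cutoff, rate,
#'   n, retained, fraction, ci_lo, ci_hi); attributes `corpus_bp` and `hits`.
#' @export
multimer_turnover <- function(motifs, p_cutoffs = c(1e-11, 1e-10, 1e-9),
                              rates = c(0.06, 0.49), corpus_size = 1e8,
                              chunk_size = 5e6, gc = 0.5, min_hits = 0,
                              replicates = 10, cfg = scan_config(),
                              seed = 1) {
  stopifnot(length(motifs) > 0, all(p_cutoffs > 0), corpus_size >= 1)
  p_loose <- max(p_cutoffs)
  base_p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  preps <- lapply(motifs, function(m) {
    S <- log_odds(m$matrix, cfg$background, cfg$pseudocount)
    thr <- lapply(p_cutoffs, function(pv) {
      attr(suppressWarnings(
        threshold_from_pvalue(S, cfg$background, pv, cfg$granularity)),
        "int_threshold")
    })
    I <- int_scores(S, cfg$granularity)
    list(id = m$id, arity = m$arity, L = ncol(I), fwd = I,
         rev = I[4:1, rev(seq_len(ncol(I))), drop = FALSE],
         t_int = unlist(thr))
  })
  maxL <- max(vapply(preps, `[[`, numeric(1), "L"))
  withr::with_seed(seed, {
    hits <- list()
    scanned <- 0
    carry <- integer(0)
    while (scanned < corpus_size &&
           (min_hits == 0 || length(hits) < min_hits)) {
      this <- min(chunk_size, corpus_size - scanned)
      chunk <- sample.int(4L, this, replace = TRUE, prob = base_p) - 1L
      codes <- c(carry, chunk)
      new_start <- length(carry)  # hits starting before this are duplicates
      for (pr in preps) {
        t_loose <- min(pr$t_int)
        for (strand in c("fwd", "rev")) {
          h <- cpp_scan_int(codes, pr[[strand]], t_loose)
          if (length(h$pos) == 0) next
          keep <- h$pos >= max(0, new_start - pr$L + 1)
          for (ii in which(keep)) {
            s0 <- h$pos[ii]
            lo <- max(0, s0 - pr$L)
            hi <- min(length(codes), s0 + 2 * pr$L)
            hits[[length(hits) + 1]] <- list(
              motif = pr$id, arity = pr$arity, L = pr$L,
              score_int = h$score[ii],
              window = codes[(lo + 1):hi],
              hit_off = s0 - lo,  # 0-based start of the hit in the window
              prep = pr
            )
          }
        }
      }
      scanned <- scanned + this
      carry <- codes[max(1, length(codes) - maxL + 2):length(codes)]
    }
    strata <- expand.grid(arity = sort(unique(vapply(preps, `[[`,
                                                     numeric(1), "arity"))),
                          cutoff = p_cutoffs, rate = rates)
    rows <- lapply(seq_len(nrow(strata)), function(si) {
      a <- strata$arity[si]; pv <- strata$cutoff[si]; r <- strata$rate[si]
      ci_idx <- match(pv, p_cutoffs)
      sel <- Filter(function(h) {
        h$arity == a && h$score_int >= h$prep$t_int[ci_idx]
      }, hits)
      if (length(sel) == 0) {
        return(data.frame(arity = a, cutoff = pv, rate = r, n = 0L,
                          retained = NA_integer_, fraction = NA_real_,
                          ci_lo = NA_real_, ci_hi = NA_real_))
      }
      ret <- 0L; tot <- 0L
      for (rep in seq_len(replicates)) {
        for (h in sel) {
          mut <- mutate_codes(h$window, r)
          t_here <- h$prep$t_int[ci_idx]
          got <- length(cpp_scan_int(mut, h$prep$fwd, t_here)$pos) > 0 ||
            length(cpp_scan_int(mut, h$prep$rev, t_here)$pos) > 0
          ret <- ret + as.integer(got)
          tot <- tot + 1L
        }
      }
      ci <- pool_ci(ret, tot)
      data.frame(arity = a, cutoff = pv, rate = r, n = tot, retained = ret,
                 fraction = ret / tot, ci_lo = ci[1], ci_hi = ci[2])
    })
    out <- do.call(rbind, rows)
    structure(out, corpus_bp = scanned, n_hits_loose = length(hits),
              class = c("TurnoverReport", "data.frame"))
  })
}

#' Write a turnover report as TSV
#'
#' @param report TurnoverReport.
#' @param path output path.
#' @export
write_turnover_tsv <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
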