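#' Scan configuration
#'
#' @param p_value match p-value cutoff in (0, 1]; the score threshold is set
#'   so that P(word score >= threshold | i.i.d. background) <= p_value.
#' @param background base probabilities (A,C,G,T); must sum to 1.
#' @param granularity score discretization, bins per unit (bit) of log-odds
#'   score. Log-odds are rounded to this grid; the threshold DP is exact for
#'   the discretized matrix.
#' @param strands "both" or "forward".
#' @param pseudocount probability pseudocount added before taking log-odds.
#' @return object of class `ScanConfig`.
#' @export
scan_config <- function(p_value = 1e-4,
                        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                        granularity = 1000,
                        strands = c("both", "forward"),
                        pseudocount = 1e-3) {
  strands <- match.arg(strands)
  stopifnot(p_value > 0, p_value <= 1, length(background) == 4,
            all(background > 0), abs(sum(background) - 1) < 1e-6,
            granularity >= 1, pseudocount >= 0)
  structure(list(p_value = p_value, background = unname(background),
                 granularity = granularity, strands = strands,
                 pseudocount = pseudocount),
            class = "ScanConfig")
}

#' Log-odds (PWM) score matrix from a position matrix
#'
#' cell = log2((p + pseudocount) / background). The maximum-scoring word is
#' the consensus.
#'
#' @param m position matrix or MotifRecord.
#' @param background base probabilities, all > 0.
#' @param pseudocount added to probabilities before the log.
#' @return 4 x L numeric matrix of scores in bits.
#' @export
log_odds <- function(m, background = rep(0.25, 4), pseudocount = 1e-3) {
  m <- as_pfm(m)
  stopifnot(all(background > 0), length(background) == 4)
  log2((m + pseudocount) / background)
}

# Integer-discretized score matrix at `granularity` bins per bit.
# -Inf cells (pseudocount 0 on a zero probability) are floored so that any
# word containing one scores below every finite-only word.
int_scores <- function(S, granularity) {
  I <- round(S * granularity)
  if (any(!is.finite(I))) {
    fin <- is.finite(I)
    if (!any(fin)) stop("score matrix has no finite entries")
    colmax <- apply(I, 2, function(x) max(x[is.finite(x)]))
    colmin <- apply(I, 2, function(x) {
      f <- x[is.finite(x)]; if (length(f)) min(f) else 0
    })
    floorv <- sum(colmin) - sum(colmax) - granularity
    I[!fin] <- floorv
  }
  storage.mode(I) <- "integer"
  I
}

#' Score threshold for a target p-value, by dynamic programming
#'
#' Computes the exact distribution of word scores under an i.i.d. background
#' by column-by-column convolution over the integer-discretized score grid,
#' and returns the smallest score t with P(score >= t) <= p. This is the
#' MOODS-style threshold computation.
#'
#' @param scores 4 x L log-odds matrix (bits), as from [log_odds()].
#' @param background base probabilities.
#' @param p target p-value in (0, 1].
#' @param granularity bins per bit (see [scan_config()]).
#' @return threshold in bits, with attributes `int_threshold` (grid units),
#'   `p_attained` (the tail probability actually achieved), and
#'   `granularity`. If no word qualifies (p below the probability of the
#'   single best word) the maximum score plus one grid step is returned with
#'   a warning.
#' @export
threshold_from_pvalue <- function(scores, background = rep(0.25, 4), p,
                                  granularity = 1000) {
  stopifnot(p > 0, p <= 1)
  I <- int_scores(scores, granularity)
  dist <- score_distribution(I, background)
  tail <- rev(cumsum(rev(dist$prob)))
  # snap to the support: the smallest attainable score whose tail is <= p
  # (the exact quantile of the discretized word-score distribution)
  ok <- which(tail <= p * (1 + 1e-9) & dist$prob > 0)
  if (length(ok) == 0) {
    warning("no word attains p-value ", p, "; returning max score + 1 step")
    t_int <- dist$min_sum + length(dist$prob)  # max + 1
    p_att <- 0
  } else {
    t_int <- dist$min_sum + ok[1] - 1
    p_att <- tail[ok[1]]
  }
  structure(t_int / granularity, int_threshold = t_int,
            p_attained = p_att, granularity = granularity)
}

# Exact DP over integer scores: returns list(min_sum, prob) where prob[i] is
# P(word score == min_sum + i - 1) under the i.i.d. background.
score_distribution <- function(I, background) {
  L <- ncol(I)
  mins <- apply(I, 2, min)
  maxs <- apply(I, 2, max)
  prob <- 1
  cur_min <- 0
  for (j in seq_len(L)) {
    w <- maxs[j] - mins[j]
    new <- numeric(length(prob) + w)
    for (b in 1:4) {
      sh <- I[b, j] - mins[j]
      idx <- seq_along(prob) + sh
      new[idx] <- new[idx] + prob * background[b]
    }
    prob <- new
    cur_min <- cur_min + mins[j]
  }
  list(min_sum = cur_min, prob = prob)
}

#' Encode a DNA string as integer base codes
#'
#' A,C,G,T (either case) map to 0..3; any other character to -1 (ambiguous,
#' never matched by the scanner).
#'
#' @param seq DNA string.
#' @return integer vector.
#' @export
encode_dna <- function(seq) {
  if (nchar(seq) == 0) return(integer(0))
  lut <- rep(-1L, 256)
  lut[utf8ToInt("A") + 1] <- 0L; lut[utf8ToInt("a") + 1] <- 0L
  lut[utf8ToInt("C") + 1] <- 1L; lut[utf8ToInt("c") + 1] <- 1L
  lut[utf8ToInt("G") + 1] <- 2L; lut[utf8ToInt("g") + 1] <- 2L
  lut[utf8ToInt("T") + 1] <- 3L; lut[utf8ToInt("t") + 1] <- 3L
  lut[utf8ToInt(seq) + 1]
}

#' Decode integer base codes to a DNA string
#'
#' @param codes integer vector (0..3; negatives become N).
#' @return DNA string.
#' @export
decode_dna <- function(codes) {
  if (length(codes) == 0) return("")
  ch <- utf8ToInt("N")
  map <- utf8ToInt(paste(DNA_BASES, collapse = ""))
  out <- rep(ch, length(codes))
  ok <- codes >= 0
  out[ok] <- map[codes[ok] + 1]
  intToUtf8(out)
}

# Prepared scanning state for one motif: integer score matrices (forward and
# reverse-complement) and integer threshold.
prepare_scan <- function(motif, cfg) {
  m <- as_pfm(motif)
  S <- log_odds(m, cfg$background, cfg$pseudocount)
  thr <- threshold_from_pvalue(S, cfg$background, cfg$p_value,
                               cfg$granularity)
  If <- int_scores(S, cfg$granularity)
  list(fwd = If, rev = If[4:1, rev(seq_len(ncol(If))), drop = FALSE],
       t_int = attr(thr, "int_threshold"), threshold = as.numeric(thr),
       L = ncol(If))
}

scan_codes <- function(codes, prep, cfg, t_int = prep$t_int) {
  hits_f <- cpp_scan_int(codes, prep$fwd, t_int)
  res <- data.frame(start = hits_f$pos, score_int = hits_f$score,
                    strand = rep("+", length(hits_f$pos)),
                    stringsAsFactors = FALSE)
  if (cfg$strands == "both") {
    hits_r <- cpp_scan_int(codes, prep$rev, t_int)
    res <- rbind(res, data.frame(start = hits_r$pos,
                                 score_int = hits_r$score,
                                 strand = rep("-", length(hits_r$pos)),
                                 stringsAsFactors = FALSE))
  }
  res[order(res$start, res$strand), , drop = FALSE]
}

#' Scan a sequence with a motif
#'
#' All positions on the requested strands whose discretized log-odds score
#' meets the p-value threshold are reported, in 0-based half-open forward-
#' strand coordinates regardless of hit strand. A plus and a minus hit at the
#' same interval are both kept.
#'
#' @param sequence DNA string (or named length-1 character; the name becomes
#'   the sequence id).
#' @param motif MotifRecord or position matrix.
#' @param cfg ScanConfig.
#' @param seq_id sequence identifier for the hit list.
#' @return data.frame (HitList) with columns seq_id, start, end, strand,
#'   motif_id, score (bits).
#' @export
scan_sequence <- function(sequence, motif, cfg = scan_config(),
                          seq_id = NULL) {
  if (is.null(seq_id)) {
    seq_id <- if (!is.null(names(sequence))) names(sequence)[1] else "seq"
  }
  motif_id <- if (inherits(motif, "MotifRecord")) motif$id else "motif"
  prep <- prepare_scan(motif, cfg)
  codes <- encode_dna(sequence[[1]])
  if (length(codes) < prep$L) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      motif_id = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  h <- scan_codes(codes, prep, cfg)
  data.frame(seq_id = rep(seq_id, nrow(h)), start = h$start,
             end = h$start + prep$L, strand = h$strand,
             motif_id = rep(motif_id, nrow(h)),
             score = h$score_int / cfg$granularity,
             stringsAsFactors = FALSE)
}

#' Per-sequence, per-motif hit-count feature matrix
#'
#' @param sequences character vector of DNA strings (names become row names).
#' @param motif_set non-empty list of MotifRecord with unique ids.
#' @param cfg ScanConfig.
#' @return integer matrix, n_sequences x n_motifs.
#' @export
hit_count_features <- function(sequences, motif_set, cfg = scan_config()) {
  if (length(motif_set) == 0) stop("motif set must be non-empty")
  if (inherits(motif_set, "MotifRecord")) motif_set <- list(motif_set)
  ids <- vapply(motif_set, function(m) m$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate motif ids: ", paste(unique(ids[duplicated(ids)]),
                                        collapse = ", "))
  }
  preps <- lapply(motif_set, prepare_scan, cfg = cfg)
  n <- length(sequences)
  out <- matrix(0L, nrow = n, ncol = length(ids),
                dimnames = list(names(sequences), ids))
  for (i in seq_len(n)) {
    codes <- encode_dna(sequences[[i]])
    for (k in seq_along(preps)) {
      p <- preps[[k]]
      if (length(codes) < p$L) next
      cnt <- cpp_count_int(codes, p$fwd, p$t_int)
      if (cfg$strands == "both") {
        cnt <- cnt + cpp_count_int(codes, p$rev, p$t_int)
      }
      out[i, k] <- cnt
    }
  }
  out
}

#' Write a hit list as BED6
#'
#' name = motif id, score = round(100 * log-odds), strand column used.
#'
#' @param hits HitList data.frame from [scan_sequence()].
#' @param path output path.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(chrom = hits$seq_id, start = hits$start, end = hits$end,
                    name = hits$motif_id, score = round(100 * hits$score),
                    strand = hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
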