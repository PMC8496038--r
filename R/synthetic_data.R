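#' Specification of a synthetic regulatory world
#'
#' The generator defaults emulate the human-scale inputs: monomeric motifs
#' with IC near 12 bits (effective length 6), ~3% of TF pairs cooperating
#' with fixed spacing/orientation, a fraction of shared members palindromic
#' (which is what makes 3-TF chaining possible), and GC-balanced background.
#'
#' @param n_tfs number of TFs in the catalog.
#' @param monomer_length monomer length in bp (>= 4; default 8: long enough
#'   that a p = 1e-4 scanning threshold is attainable, while the IC target
#'   keeps the effective length at 6).
#' @param target_ic_bits target mean motif IC in bits (default 12; capped at
#'   2 * monomer_length).
#' @param cooperativity_fraction fraction of TF pairs forming dimers
#'   (default 0.03).
#' @param palindrome_fraction fraction of dimer-participating TFs made
#'   palindromic (default 0.3).
#' @param gc background GC fraction in (0, 1).
#' @param seed RNG seed; everything downstream is deterministic in it.
#' @return object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_tfs = 100, monomer_length = 8,
                           target_ic_bits = 12,
                           cooperativity_fraction = 0.03,
                           palindrome_fraction = 0.3, gc = 0.5, seed = 1) {
  stopifnot(n_tfs >= 0, monomer_length >= 4,
            cooperativity_fraction >= 0, cooperativity_fraction <= 1,
            palindrome_fraction >= 0, palindrome_fraction <= 1,
            gc > 0, gc < 1)
  if (target_ic_bits > 2 * monomer_length) {
    stop("infeasible spec: target IC ", target_ic_bits, " bits exceeds 2 x ",
         monomer_length, " = ", 2 * monomer_length)
  }
  structure(list(n_tfs = n_tfs, monomer_length = monomer_length,
                 target_ic_bits = target_ic_bits,
                 cooperativity_fraction = cooperativity_fraction,
                 palindrome_fraction = palindrome_fraction, gc = gc,
                 seed = seed),
            class = "SyntheticSpec")
}

# Per-column IC (bits) of a column with dominant-base probability d and the
# remainder split evenly.
column_ic <- function(d) {
  e <- (1 - d) / 3
  terms <- c(d * log2(d), rep(ifelse(e > 0, e * log2(e), 0), 3))
  2 + sum(terms)
}

# Dominant-base probability achieving a per-column IC target (<= cap 0.998).
solve_dominant <- function(ic_per_col) {
  ic_per_col <- min(ic_per_col, column_ic(0.998))
  if (ic_per_col <= column_ic(0.26)) return(0.26)
  stats::uniroot(function(d) column_ic(d) - ic_per_col,
                 c(0.26, 0.998), tol = 1e-9)$root
}

# One random motif column: dominant base b at probability ~d, remainder
# split unevenly (keeps the word-score distribution dense).
random_column <- function(b, d) {
  rest <- runif(3) + 0.05
  rest <- rest / sum(rest) * (1 - d)
  col <- numeric(4)
  col[-b] <- rest
  col[b] <- d
  col
}

#' Generate a catalog of monomeric motifs
#'
#' @param spec SyntheticSpec.
#' @return list of MotifRecord (arity 1), deterministic in `spec$seed`.
#' @export
make_monomer_catalog <- function(spec) {
  if (spec$n_tfs == 0) return(list())
  L <- spec$monomer_length
  d_star <- solve_dominant(spec$target_ic_bits / L)
  withr::with_seed(spec$seed, {
    lapply(seq_len(spec$n_tfs), function(i) {
      cons <- sample.int(4, L, replace = TRUE)
      d <- pmin(0.998, pmax(0.9, d_star + runif(L, -0.007, 0.004)))
      m <- vapply(seq_len(L), function(j) random_column(cons[j], d[j]),
                  numeric(4))
      motif_record(sprintf("TF%03d", i), position_matrix(m))
    })
  })
}

#' Generate a dimer catalog with cooperativity structure
#'
#' floor(cooperativity_fraction * n_pairs) random TF pairs are joined with a
#' random 0-4 bp gap and random half orientations; palindrome_fraction of the
#' participating TFs have their matrix palindromized (mirrored halves) inside
#' the dimers, so that chaining into multimers is possible.
#'
#' @param monomers list of MotifRecord from [make_monomer_catalog()].
#' @param spec SyntheticSpec.
#' @return list of DimerAnnotation.
#' @export
make_dimer_catalog <- function(monomers, spec) {
  n <- length(monomers)
  stopifnot(n >= 2)
  n_pairs <- choose(n, 2)
  n_dimers <- floor(spec$cooperativity_fraction * n_pairs)
  if (n_dimers == 0) return(list())
  pair_idx <- t(combn(n, 2))
  withr::with_seed(spec$seed + 1, {
    pick <- sample.int(nrow(pair_idx), n_dimers)
    used_tfs <- unique(as.vector(pair_idx[pick, , drop = FALSE]))
    n_pal <- ceiling(spec$palindrome_fraction * length(used_tfs))
    pal_set <- if (n_pal > 0) sample(used_tfs, n_pal) else integer(0)
    half_matrix <- function(i) {
      m <- monomers[[i]]$matrix
      if (i %in% pal_set) m <- palindromize(m)
      if (runif(1) < 0.5) m <- reverse_complement(m)
      m
    }
    lapply(seq_len(n_dimers), function(di) {
      ij <- pair_idx[pick[di], ]
      hA <- half_matrix(ij[1])
      hB <- half_matrix(ij[2])
      g <- sample(0:4, 1)
      gap <- matrix(0.25, 4, g)
      mat <- position_matrix(cbind(hA, gap, hB))
      LA <- ncol(hA); LB <- ncol(hB)
      ids <- c(monomers[[ij[1]]]$id, monomers[[ij[2]]]$id)
      rec <- motif_record(paste(ids, collapse = "-"), mat, tf_members = ids)
      dimer_annotation(
        rec,
        half_spans = list(c(0, LA), c(LA + g, LA + g + LB)),
        # flags are measured, not assumed: accidental palindromes count too
        palindromic_halves = c(is_palindromic(hA, 0.8),
                               is_palindromic(hB, 0.8)),
        member_order = ids
      )
    })
  })
}

#' Convenience: synthetic multimer catalog via chain enumeration
#'
#' @param dimers list of DimerAnnotation.
#' @param max_arity chain up to this arity (3..6).
#' @param n_per_arity motifs retained per arity (seeded subsample).
#' @param seed RNG seed for the subsample.
#' @return list of multimeric MotifRecord.
#' @export
make_multimer_catalog <- function(dimers, max_arity = 6, n_per_arity = 8,
                                  seed = 1) {
  chains <- enumerate_chains(dimers, max_arity = max_arity, limit = Inf,
                             seed = seed)
  arities <- vapply(chains, function(r) r$arity, numeric(1))
  out <- list()
  withr::with_seed(seed, {
    for (a in sort(unique(arities))) {
      idx <- which(arities == a)
      if (length(idx) > n_per_arity) {
        idx <- sort(sample(idx, n_per_arity))
      }
      out <- c(out, chains[idx])
    }
  })
  out
}

#' Random i.i.d. background sequence
#'
#' @param length sequence length in bp.
#' @param gc GC fraction in (0, 1); P(G) = P(C) = gc/2.
#' @param seed optional RNG seed.
#' @return DNA string.
#' @export
random_background <- function(length, gc = 0.5, seed = NULL) {
  stopifnot(gc > 0, gc < 1, length >= 0)
  if (length == 0) return("")
  gen <- function() {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    decode_dna(sample.int(4L, length, replace = TRUE, prob = p) - 1L)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

sample_site <- function(m) {
  m <- as_pfm(m)
  codes <- vapply(seq_len(ncol(m)), function(j) {
    sample.int(4L, 1, prob = m[, j]) - 1L
  }, integer(1))
  decode_dna(codes)
}

implant <- function(seq, site, at) {
  paste0(substr(seq, 1, at), site, substr(seq, at + nchar(site) + 1,
                                          nchar(seq)))
}

#' Generate labeled positive/negative sequence sets with known ground truth
#'
#' Billboard mode implants `sites_per_positive` sites sampled from monomer
#' PFMs at uniform random non-overlapping positions and strands (no geometry
#' constraint); saoc mode implants a single instance sampled from one
#' multimeric PFM (fixed internal geometry). Negatives are GC-matched pure
#' background. Chromosome tags are assigned round-robin over 23 synthetic
#' chromosomes.
#'
#' @param motifs motif list: monomers for billboard, multimers for saoc.
#' @param mode "billboard" or "saoc".
#' @param n_pos,n_neg numbers of positive and negative sequences.
#' @param length sequence length in bp (default 200).
#' @param sites_per_positive sites implanted per positive (billboard mode).
#' @param spec SyntheticSpec (gc and seed are used).
#' @return list(sequences = data.frame(id, chrom, label, seq),
#'   truth = BED-like data.frame of implants, manifest = list).
#' @export
make_labeled_sequences <- function(motifs, mode = c("billboard", "saoc"),
                                   n_pos, n_neg, length = 200,
                                   sites_per_positive = 5,
                                   spec = synthetic_spec()) {
  mode <- match.arg(mode)
  stopifnot(n_pos >= 1, n_neg >= 0, length >= 1)
  if (inherits(motifs, "MotifRecord")) motifs <- list(motifs)
  widths <- vapply(motifs, function(m) ncol(m$matrix), numeric(1))
  if (mode == "billboard" && sites_per_positive * max(widths) > length) {
    stop("sites cannot fit: ", sites_per_positive, " x ", max(widths),
         " bp exceeds sequence length ", length)
  }
  if (mode == "saoc" && max(widths) > length) {
    stop("multimer instance longer than the sequence")
  }
  withr::with_seed(spec$seed + 2, {
    truth <- list()
    place_nonoverlapping <- function(ws) {
      for (attempt in 1:1000) {
        starts <- vapply(ws, function(w) {
          sample.int(length - w + 1, 1) - 1L
        }, integer(1))
        ends <- starts + ws
        o <- order(starts)
        if (all(head(ends[o], -1) <= tail(starts[o], -1))) return(starts)
      }
      stop("placement error: could not place sites without overlap ",
           "after 1000 attempts")
    }
    pos_seqs <- vapply(seq_len(n_pos), function(i) {
      s <- random_background(length, spec$gc)
      if (mode == "billboard") {
        ks <- if (length(motifs) >= sites_per_positive) {
          sample(seq_along(motifs), sites_per_positive)
        } else {
          sample(seq_along(motifs), sites_per_positive, replace = TRUE)
        }
        ws <- widths[ks]
        starts <- place_nonoverlapping(ws)
        for (j in seq_along(ks)) {
          site <- sample_site(motifs[[ks[j]]])
          strand <- if (runif(1) < 0.5) "+" else "-"
          if (strand == "-") site <- reverse_complement(site)
          s <- implant(s, site, starts[j])
          truth[[base::length(truth) + 1]] <<- data.frame(
            id = sprintf("pos%05d", i), start = starts[j],
            end = starts[j] + ws[j], motif_id = motifs[[ks[j]]]$id,
            strand = strand, stringsAsFactors = FALSE)
        }
      } else {
        k <- sample(seq_along(motifs), 1)
        w <- widths[k]
        at <- sample.int(length - w + 1, 1) - 1L
        site <- sample_site(motifs[[k]])
        strand <- if (runif(1) < 0.5) "+" else "-"
        if (strand == "-") site <- reverse_complement(site)
        s <- implant(s, site, at)
        truth[[base::length(truth) + 1]] <<- data.frame(
          id = sprintf("pos%05d", i), start = at, end = at + w,
          motif_id = motifs[[k]]$id, strand = strand,
          stringsAsFactors = FALSE)
      }
      s
    }, character(1))
    neg_seqs <- if (n_neg > 0) {
      vapply(seq_len(n_neg), function(i) random_background(length, spec$gc),
             character(1))
    } else character(0)
    ids <- c(sprintf("pos%05d", seq_len(n_pos)),
             if (n_neg > 0) sprintf("neg%05d", seq_len(n_neg)))
    chrom <- c(paste0("chr", (seq_len(n_pos) - 1) %% 23 + 1),
               if (n_neg > 0) paste0("chr", (seq_len(n_neg) - 1) %% 23 + 1))
    list(
      sequences = data.frame(
        id = ids, chrom = chrom,
        label = c(rep("positive", n_pos), rep("negative", n_neg)),
        seq = c(pos_seqs, neg_seqs), stringsAsFactors = FALSE),
      truth = if (length(truth)) do.call(rbind, truth) else
        data.frame(id = character(0), start = integer(0), end = integer(0),
                   motif_id = character(0), strand = character(0)),
      manifest = list(mode = mode, n_pos = n_pos, n_neg = n_neg,
                      length = length,
                      sites_per_positive = sites_per_positive,
                      gc = spec$gc, seed = spec$seed)
    )
  })
}

#' Export a labeled dataset as FASTA + BED6 + JSON manifest
#'
#' @param ds result of [make_labeled_sequences()].
#' @param dir output directory (created if needed).
#' @return invisible vector of written paths.
#' @export
export_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "sequences.fa")
  ss <- Biostrings::DNAStringSet(ds$sequences$seq)
  names(ss) <- ds$sequences$id
  Biostrings::writeXStringSet(ss, fa)
  bed <- file.path(dir, "truth.bed")
  tr <- ds$truth
  write.table(data.frame(tr$id, tr$start, tr$end, tr$motif_id, 0, tr$strand),
              bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(ds$manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(c(fa, bed, mf))
}
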