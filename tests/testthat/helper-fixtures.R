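# Shared fixtures, all built in code.

# random probability matrix (columns sum to 1)
random_pfm <- function(L, seed = NULL) {
  gen <- function() {
    m <- matrix(rexp(4 * L), 4)
    position_matrix(sweep(m, 2, colSums(m), "/"))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# brute-force word-score machinery over all 4^L words
all_word_scores <- function(I) {
  L <- ncol(I)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  apply(words, 1, function(w) sum(I[cbind(w, seq_len(L))]))
}

# independent exhaustive-offset alignment oracle (same scoring convention)
oracle_align <- function(a, b, min_overlap) {
  a <- regspec:::as_pfm(a); b <- regspec:::as_pfm(b)
  La <- ncol(a); Lb <- ncol(b)
  best <- NULL
  for (orient in c("forward", "revcomp")) {
    bb <- if (orient == "forward") b else reverse_complement(b)
    for (off in -(Lb - 1):(La - 1)) {
      lo <- max(0, off); hi <- min(La, off + Lb); ov <- hi - lo
      if (ov < min_overlap) next
      sc <- 0
      for (i in seq_len(ov)) {
        x <- a[, lo + i]; y <- bb[, lo + i - off]
        sc <- sc + if (var(x) == 0 && var(y) == 0) 1 else
          if (var(x) == 0 || var(y) == 0) 0 else cor(x, y)
      }
      cand <- list(offset = off, orientation = orient, overlap_length = ov,
                   score = sc)
      if (is.null(best) || regspec:::better_alignment(cand, best)) {
        best <- cand
      }
    }
  }
  best
}

# a hand-built deterministic dimer: TF a site + gap + TF b site, with
# palindromized halves where flagged
toy_dimer <- function(id_a, id_b, cons_a, cons_b, gap = 2,
                      pal = c(FALSE, FALSE), strength = 0.97) {
  ha <- consensus_matrix(cons_a, strength)
  hb <- consensus_matrix(cons_b, strength)
  if (pal[1]) ha <- regspec:::palindromize(ha)
  if (pal[2]) hb <- regspec:::palindromize(hb)
  LA <- ncol(ha); LB <- ncol(hb)
  m <- position_matrix(cbind(ha, matrix(0.25, 4, gap), hb))
  rec <- motif_record(paste0(id_a, "-", id_b), m,
                      tf_members = c(id_a, id_b))
  dimer_annotation(rec, list(c(0, LA), c(LA + gap, LA + gap + LB)),
                   palindromic_halves = pal, member_order = c(id_a, id_b))
}

# small synthetic world reused across tests
tiny_world <- function(n_tfs = 30, seed = 11) {
  spec <- synthetic_spec(n_tfs = n_tfs, seed = seed)
  mono <- make_monomer_catalog(spec)
  dimers <- make_dimer_catalog(mono, spec)
  list(spec = spec, mono = mono, dimers = dimers)
}
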