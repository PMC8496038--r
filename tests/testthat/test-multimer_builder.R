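test_that("align_pfms recovers self- and reverse-complement alignments", {
  a <- consensus_matrix("ACGTTGCA", 0.95)
  al <- align_pfms(a, a, min_overlap = 4)
  expect_equal(al$offset, 0)
  expect_equal(al$orientation, "forward")
  expect_equal(al$overlap_length, 8)
  expect_equal(al$score, 8, tolerance = 1e-6)
  # a vs rc(a) for a non-palindromic matrix: revcomp at offset 0
  b <- consensus_matrix("AACGTC", 0.95)
  al2 <- align_pfms(b, reverse_complement(b), min_overlap = 4)
  expect_equal(al2$orientation, "revcomp")
  expect_equal(al2$offset, 0)
  expect_error(align_pfms(a, b, min_overlap = 7), "min_overlap")
})

test_that("align_pfms equals the exhaustive oracle on random matrices", {
  for (s in 1:8) {
    a <- random_pfm(10, seed = 100 + s)
    b <- random_pfm(sample(5:12, 1), seed = 200 + s)
    got <- align_pfms(a, b, min_overlap = 3)
    want <- oracle_align(a, b, min_overlap = 3)
    expect_equal(got$score, want$score, tolerance = 1e-9)
    expect_equal(got$offset, want$offset)
    expect_equal(got$orientation, want$orientation)
  }
})

test_that("merge_dimers averages overlapping columns and chains members", {
  # forced by the averaging rule: (1,0,0,0) with (0,0,0,1) -> (.5,0,0,.5)
  ov <- regspec:::overlay_average(consensus_matrix("A"),
                                  consensus_matrix("T"), 0L)
  expect_equal(as.numeric(ov$matrix), c(0.5, 0, 0, 0.5))

  ab <- toy_dimer("A", "B", "ACGTTG", "AATGCA", gap = 2,
                  pal = c(FALSE, TRUE))
  cb <- toy_dimer("C", "B", "GGATCC", "AATGCA", gap = 1,
                  pal = c(FALSE, TRUE))
  rec <- merge_dimers(ab, cb, min_overlap = 4)
  expect_s3_class(rec, "MotifRecord")
  expect_equal(rec$arity, 3)
  expect_setequal(rec$tf_members, c("A", "B", "C"))
  expect_equal(rec$tf_members[2], "B")  # shared member is interior
  L1 <- ncol(ab$motif$matrix); L2 <- ncol(cb$motif$matrix)
  expect_lte(ncol(rec$matrix), L1 + L2 - 4)
  # per-column normalization survives averaging
  expect_equal(colSums(rec$matrix), rep(1, ncol(rec$matrix)))
  # IC subadditivity: averaging cannot create information
  expect_lte(information_content(rec$matrix),
             information_content(ab$motif$matrix) +
               information_content(cb$motif$matrix) + 1e-9)
})

test_that("merging a dimer with an identical copy returns the input", {
  ab <- toy_dimer("A", "B", "ACGTTG", "AATGCA", gap = 2,
                  pal = c(TRUE, TRUE))
  ab2 <- toy_dimer("C", "B", "ACGTTG", "AATGCA", gap = 2,
                   pal = c(TRUE, TRUE))  # same matrix, different first id
  rec <- merge_dimers(ab, ab2, min_overlap = 4)
  # overlap columns are means of equal values wherever the copies align
  expect_equal(dim(rec$matrix)[2] >= ncol(ab$motif$matrix), TRUE)
  al <- align_pfms(ab$motif$matrix, rec$matrix, min_overlap = 6)
  expect_gt(al$score / al$overlap_length, 0.95)
})

test_that("merge is symmetric up to reverse complement", {
  ab <- toy_dimer("A", "B", "ACGTTG", "AATGCA", gap = 2,
                  pal = c(FALSE, TRUE))
  cb <- toy_dimer("C", "B", "GGATCC", "AATGCA", gap = 1,
                  pal = c(FALSE, TRUE))
  r1 <- merge_dimers(ab, cb, min_overlap = 4)
  r2 <- merge_dimers(cb, ab, min_overlap = 4)
  expect_equal(regspec:::chain_key(r1$tf_members),
               regspec:::chain_key(r2$tf_members))
  al <- align_pfms(r1$matrix, r2$matrix,
                   min_overlap = min(ncol(r1$matrix), ncol(r2$matrix)) - 2)
  expect_gt(al$score / al$overlap_length, 0.9)
})

test_that("merge preconditions are enforced", {
  ab <- toy_dimer("A", "B", "ACGTTG", "AATGCA", gap = 2,
                  pal = c(FALSE, FALSE))
  cb <- toy_dimer("C", "B", "GGATCC", "AATGCA", gap = 1,
                  pal = c(FALSE, TRUE))
  expect_error(merge_dimers(ab, cb), "palindromic")
  xy <- toy_dimer("X", "Y", "ACGTTG", "AATGCA", gap = 2,
                  pal = c(TRUE, TRUE))
  expect_error(merge_dimers(ab, xy), "share exactly one member")
})

test_that("extend_multimer grows chains and conserves normalization", {
  ab <- toy_dimer("A", "B", "ACGTTG", "AATGCA", gap = 2, pal = c(FALSE, TRUE))
  cb <- toy_dimer("C", "B", "GGATCC", "AATGCA", gap = 1, pal = c(TRUE, TRUE))
  tri <- merge_dimers(ab, cb, min_overlap = 4)
  cd <- toy_dimer("C", "D", "GGATCC", "TTAACC", gap = 2, pal = c(TRUE, TRUE))
  quad <- extend_multimer(tri, cd, min_overlap = 4)
  expect_equal(quad$arity, 4)
  expect_setequal(quad$tf_members, c("A", "B", "C", "D"))
  # extending with a dimer lacking a terminal member fails
  xz <- toy_dimer("X", "Z", "ACGTTG", "AATGCA", gap = 2, pal = c(TRUE, TRUE))
  expect_error(extend_multimer(tri, xz), "chaining error")
  # iterate to arity 6: columns stay normalized
  de <- toy_dimer("D", "E", "TTAACC", "CCGGTT", gap = 1, pal = c(TRUE, TRUE))
  ef <- toy_dimer("E", "F", "CCGGTT", "ACACAC", gap = 0, pal = c(TRUE, FALSE))
  hex <- extend_multimer(extend_multimer(quad, de), ef)
  expect_equal(hex$arity, 6)
  expect_equal(colSums(hex$matrix), rep(1, ncol(hex$matrix)))
  expect_lt(ncol(hex$matrix), 100)
})

test_that("enumerate_chains finds exactly the legal 3-TF chains", {
  ab <- toy_dimer("A", "B", "ACGTTG", "AATGCA", gap = 2, pal = c(FALSE, TRUE))
  cb <- toy_dimer("C", "B", "GGATCC", "AATGCA", gap = 1, pal = c(FALSE, TRUE))
  chains <- enumerate_chains(list(ab, cb), max_arity = 3)
  # A-B-C and C-B-A collapse to one up to reversal
  expect_length(chains, 1)
  expect_setequal(chains[[1]]$tf_members, c("A", "B", "C"))
  # no palindromic shared member -> no chains
  ab2 <- toy_dimer("A", "B", "ACGTTG", "AATGCA", gap = 2,
                   pal = c(FALSE, FALSE))
  cb2 <- toy_dimer("C", "B", "GGATCC", "AATGCA", gap = 1,
                   pal = c(FALSE, FALSE))
  expect_length(enumerate_chains(list(ab2, cb2), max_arity = 3), 0)
  expect_length(enumerate_chains(list(), max_arity = 3), 0)
})

test_that("annotate_dimer infers half-spans from member monomers", {
  w <- tiny_world(n_tfs = 20, seed = 23)
  ids <- vapply(w$mono, function(m) m$id, character(1))
  for (d in w$dimers[1:5]) {
    ma <- w$mono[[match(d$member_order[1], ids)]]
    mb <- w$mono[[match(d$member_order[2], ids)]]
    # palindromized halves differ from the raw monomer, so annotate with the
    # matrices actually embedded (extracted via the ground-truth spans)
    emb <- function(h) {
      sp <- d$half_spans[[h]]
      motif_record(d$member_order[h],
                   d$motif$matrix[, (sp[1] + 1):sp[2], drop = FALSE])
    }
    ann <- annotate_dimer(d$motif, emb(1), emb(2))
    expect_equal(ann$half_spans, d$half_spans)
    expect_equal(ann$member_order, d$member_order)
    expect_equal(ann$palindromic_halves, d$palindromic_halves)
  }
  # also recovers spans from the raw (un-palindromized) monomers
  d <- w$dimers[[1]]
  ann2 <- annotate_dimer(d$motif, w$mono[[match(d$member_order[1], ids)]],
                         w$mono[[match(d$member_order[2], ids)]])
  expect_equal(vapply(ann2$half_spans, diff, numeric(1)),
               vapply(d$half_spans, diff, numeric(1)))
})

test_that("synthetic dimer catalogs chain into valid multimers", {
  w <- tiny_world(n_tfs = 30, seed = 11)
  chains <- enumerate_chains(w$dimers, max_arity = 4, limit = 50, seed = 5)
  expect_gt(length(chains), 0)
  for (rec in chains) {
    expect_gte(rec$arity, 3)
    expect_equal(rec$arity, length(rec$tf_members))
    expect_equal(colSums(rec$matrix), rep(1, ncol(rec$matrix)))
    # merged IC cannot exceed the summed component ICs (~12 bits each)
    expect_lte(information_content(rec$matrix), rec$arity * 12 + 4)
  }
  prov <- write_chain_provenance(chains, withr::local_tempfile())
  expect_equal(nrow(prov), length(chains))
})
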