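test_that("synthetic_spec validates its stated world", {
  expect_error(synthetic_spec(target_ic_bits = 13, monomer_length = 6),
               "infeasible")
  expect_s3_class(synthetic_spec(), "SyntheticSpec")
})

test_that("monomer catalog hits the IC target deterministically", {
  # length 6 caps IC at 12: every motif lands in [10, 12]
  spec6 <- synthetic_spec(n_tfs = 40, monomer_length = 6, seed = 21)
  ics6 <- vapply(make_monomer_catalog(spec6),
                 function(m) information_content(m$matrix), numeric(1))
  expect_true(all(ics6 >= 10 & ics6 <= 12))
  spec <- synthetic_spec(n_tfs = 50, seed = 21)
  cat1 <- make_monomer_catalog(spec)
  expect_length(cat1, 50)
  ics <- vapply(cat1, function(m) information_content(m$matrix), numeric(1))
  expect_lt(abs(mean(ics) - spec$target_ic_bits), 1)
  # same seed -> identical catalogs; empty spec -> empty catalog
  cat2 <- make_monomer_catalog(spec)
  expect_identical(cat1, cat2)
  expect_length(make_monomer_catalog(synthetic_spec(n_tfs = 0)), 0)
})

test_that("dimer catalog has the expected size and structure", {
  spec <- synthetic_spec(n_tfs = 100, seed = 13)
  mono <- make_monomer_catalog(spec)
  dimers <- make_dimer_catalog(mono, spec)
  expect_length(dimers, 148)  # floor(0.03 * choose(100, 2))
  expect_length(make_dimer_catalog(mono,
    synthetic_spec(n_tfs = 100, cooperativity_fraction = 0, seed = 13)), 0)
  # half spans cover their monomers; flags agree with is_palindromic
  for (d in dimers[1:20]) {
    expect_s3_class(d, "DimerAnnotation")
    L <- ncol(d$motif$matrix)
    expect_lte(d$half_spans[[2]][2], L)
    for (h in 1:2) {
      sp <- d$half_spans[[h]]
      half <- d$motif$matrix[, (sp[1] + 1):sp[2], drop = FALSE]
      expect_equal(d$palindromic_halves[h], is_palindromic(half, 0.8))
    }
  }
})

test_that("dimer halves recover their source monomers by alignment", {
  w <- tiny_world(n_tfs = 30, seed = 17)
  for (d in w$dimers) {
    for (h in 1:2) {
      tf <- d$member_order[h]
      mono <- w$mono[[which(vapply(w$mono, function(m) m$id, character(1))
                            == tf)]]
      src <- if (d$palindromic_halves[h]) {
        regspec:::palindromize(mono$matrix)
      } else {
        mono$matrix
      }
      al <- align_pfms(src, d$motif$matrix, min_overlap = ncol(src))
      expect_gt(al$score, 0.9 * ncol(src))
    }
  }
})

test_that("chaining feasibility: palindromic shared members yield 3-TF chains", {
  w <- tiny_world(n_tfs = 30, seed = 11)
  shared <- table(unlist(lapply(w$dimers, function(d) d$member_order)))
  expect_gt(sum(shared >= 2), 0)
  chains <- enumerate_chains(w$dimers, max_arity = 3, limit = 20, seed = 2)
  expect_gt(length(chains), 0)
})

test_that("random_background is seeded and GC-calibrated", {
  s1 <- random_background(1e5, gc = 0.5, seed = 8)
  s2 <- random_background(1e5, gc = 0.5, seed = 8)
  expect_identical(s1, s2)
  expect_equal(random_background(0), "")
  gcf <- mean(strsplit(s1, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gcf - 0.5), 3 * sqrt(0.25 / 1e5))
  s3 <- random_background(1e5, gc = 0.7, seed = 8)
  gcf3 <- mean(strsplit(s3, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gcf3 - 0.7), 3 * sqrt(0.21 / 1e5))
})

test_that("labeled sequences carry exact ground truth and matched GC", {
  w <- tiny_world(n_tfs = 30, seed = 11)
  ds <- make_labeled_sequences(w$mono[1:10], "billboard", n_pos = 60,
                               n_neg = 60, length = 200,
                               sites_per_positive = 5, spec = w$spec)
  expect_equal(nrow(ds$truth), 5 * 60)  # bookkeeping
  expect_equal(sum(ds$sequences$label == "positive"), 60)
  expect_true(all(nchar(ds$sequences$seq) == 200))
  expect_true(all(ds$truth$end <= 200 & ds$truth$start >= 0))
  # implanted site really sits at the recorded coordinates
  r <- ds$truth[1, ]
  s <- ds$sequences$seq[ds$sequences$id == r$id]
  site <- substr(s, r$start + 1, r$end)
  mot <- w$mono[[which(vapply(w$mono, function(m) m$id, character(1))
                       == r$motif_id)]]
  h <- scan_sequence(site, mot, scan_config(p_value = 1e-3))
  expect_gt(nrow(h), 0)
  # GC matching between labels (expectation gap < 0.02)
  gc_of <- function(x) mean(strsplit(paste(x, collapse = ""), "")[[1]]
                            %in% c("G", "C"))
  gp <- gc_of(ds$sequences$seq[ds$sequences$label == "positive"])
  gn <- gc_of(ds$sequences$seq[ds$sequences$label == "negative"])
  expect_lt(abs(gp - gn), 0.02)
  # chromosome tags spread over 23 synthetic chromosomes
  expect_gt(length(unique(ds$sequences$chrom)), 20)
})

test_that("saoc mode implants one multimer instance per positive", {
  w <- tiny_world(n_tfs = 30, seed = 11)
  mm <- make_multimer_catalog(w$dimers, max_arity = 4, n_per_arity = 3,
                              seed = 4)
  ds <- make_labeled_sequences(mm, "saoc", n_pos = 25, n_neg = 25,
                               length = 200, spec = w$spec)
  expect_equal(nrow(ds$truth), 25)
  widths <- ds$truth$end - ds$truth$start
  expect_true(all(widths >= min(vapply(mm, function(m) ncol(m$matrix),
                                       numeric(1)))))
})

test_that("placement and sizing errors are raised", {
  w <- tiny_world(n_tfs = 10, seed = 3)
  expect_error(
    make_labeled_sequences(w$mono, "billboard", n_pos = 5, n_neg = 5,
                           length = 20, sites_per_positive = 5,
                           spec = w$spec),
    "fit")
})

test_that("export writes FASTA, BED and manifest", {
  w <- tiny_world(n_tfs = 10, seed = 3)
  ds <- make_labeled_sequences(w$mono[1:5], "billboard", n_pos = 6, n_neg = 6,
                               length = 120, sites_per_positive = 3,
                               spec = w$spec)
  dir <- withr::local_tempdir()
  paths <- export_dataset(ds, dir)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "sequences.fa"))
  expect_length(fa, 12)
  bed <- read.table(file.path(dir, "truth.bed"), sep = "\t")
  expect_equal(nrow(bed), nrow(ds$truth))
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(mf$mode, "billboard")
})
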