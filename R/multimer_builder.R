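#' Annotate a dimeric motif with its monomer half-spans
#'
#' @param motif MotifRecord of arity 2.
#' @param half_spans list of two integer pairs c(start, end), 0-based
#'   half-open column ranges locating each monomer half; disjoint, in order.
#' @param palindromic_halves logical(2): is each half's site palindromic?
#' @param member_order character(2), the TF ids in half order.
#' @return object of class `DimerAnnotation`.
#' @export
dimer_annotation <- function(motif, half_spans, palindromic_halves,
                             member_order = motif$tf_members) {
  stopifnot(inherits(motif, "MotifRecord"), motif$arity == 2,
            length(half_spans) == 2, length(palindromic_halves) == 2,
            length(member_order) == 2)
  L <- ncol(motif$matrix)
  s <- do.call(rbind, half_spans)
  if (any(s < 0) || any(s > L) || any(s[, 2] <= s[, 1])) {
    stop("half_spans must be non-empty 0-based half-open ranges within the motif")
  }
  if (s[1, 2] > s[2, 1]) stop("half_spans must be disjoint or abutting, in order")
  obj <- list(motif = motif, half_spans = half_spans,
              palindromic_halves = as.logical(palindromic_halves),
              member_order = as.character(member_order))
  class(obj) <- "DimerAnnotation"
  obj
}

#' @export
print.DimerAnnotation <- function(x, ...) {
  cat(sprintf("DimerAnnotation %s: %s[%d,%d) %s - %s[%d,%d) %s\n",
              x$motif$id,
              x$member_order[1], x$half_spans[[1]][1], x$half_spans[[1]][2],
              if (x$palindromic_halves[1]) "(pal)" else "",
              x$member_order[2], x$half_spans[[2]][1], x$half_spans[[2]][2],
              if (x$palindromic_halves[2]) "(pal)" else ""))
  invisible(x)
}

#' Annotate a dimer automatically from its member monomers
#'
#' Replaces manual dimer annotation: each half-span is the member monomer's
#' best [align_pfms()] placement within the dimer matrix, and palindromy is
#' measured on the placed half.
#'
#' @param motif MotifRecord of arity 2 (member order = `tf_members`).
#' @param monomer_a,monomer_b MotifRecord or position matrix of the two
#'   member monomers, in `tf_members` order.
#' @param min_correlation palindromy threshold passed to [is_palindromic()].
#' @return DimerAnnotation.
#' @export
annotate_dimer <- function(motif, monomer_a, monomer_b,
                           min_correlation = 0.8) {
  stopifnot(inherits(motif, "MotifRecord"), motif$arity == 2)
  place <- function(mono) {
    m <- as_pfm(mono)
    al <- align_pfms(motif$matrix, m, min_overlap = min(ncol(m),
                                                        ncol(motif$matrix)))
    c(start = max(0L, al$offset),
      end = min(ncol(motif$matrix), al$offset + ncol(m)))
  }
  spans <- list(place(monomer_a), place(monomer_b))
  order_lr <- order(vapply(spans, `[`, numeric(1), 1))
  spans <- spans[order_lr]
  members <- motif$tf_members[order_lr]
  if (spans[[2]][1] < spans[[1]][2]) {
    # overlapping placements: split at the midpoint of the overlap
    cut <- floor((spans[[2]][1] + spans[[1]][2]) / 2)
    spans[[1]][2] <- cut
    spans[[2]][1] <- cut
  }
  half <- function(sp) motif$matrix[, (sp[1] + 1):sp[2], drop = FALSE]
  dimer_annotation(
    motif,
    half_spans = lapply(spans, unname),
    palindromic_halves = c(is_palindromic(half(spans[[1]]), min_correlation),
                           is_palindromic(half(spans[[2]]), min_correlation)),
    member_order = members
  )
}

#' Ungapped alignment of two position matrices
#'
#' Exhaustive search over all ungapped offsets of `b` (and its reverse
#' complement) against `a`, maximizing the summed per-column Pearson
#' correlation over the overlap (the Smith-Waterman-ungapped analog of
#' STAMP's PCC scoring). Ties are broken by larger overlap, then forward
#' orientation, then smaller offset. Uniform (zero-variance) column pairs
#' contribute 1 when both are uniform, else 0.
#'
#' @param a,b position matrices or MotifRecords.
#' @param min_overlap minimum number of overlapping columns (>= 1).
#' @return object of class `AlignmentResult`: list(offset, orientation,
#'   overlap_length, score). `offset` is the 0-based position of b's first
#'   column relative to a's first column (may be negative).
#' @export
align_pfms <- function(a, b, min_overlap = 4) {
  a <- as_pfm(a); b <- as_pfm(b)
  La <- ncol(a); Lb <- ncol(b)
  if (min_overlap < 1 || min_overlap > min(La, Lb)) {
    stop("min_overlap must be in [1, min(length a, length b)]")
  }
  best <- NULL
  for (orientation in c("forward", "revcomp")) {
    bb <- if (orientation == "forward") b else reverse_complement(b)
    for (off in seq(-(Lb - min_overlap), La - min_overlap)) {
      lo <- max(0L, off)
      hi <- min(La, off + Lb)
      ov <- hi - lo
      if (ov < min_overlap) next
      sc <- sum(vapply(seq_len(ov), function(i) {
        column_pcc(a[, lo + i], bb[, lo + i - off])
      }, numeric(1)))
      cand <- list(offset = off, orientation = orientation,
                   overlap_length = ov, score = sc)
      if (is.null(best) || better_alignment(cand, best)) best <- cand
    }
  }
  class(best) <- "AlignmentResult"
  best
}

better_alignment <- function(x, y, tol = 1e-9) {
  if (x$score > y$score + tol) return(TRUE)
  if (x$score < y$score - tol) return(FALSE)
  if (x$overlap_length != y$overlap_length) {
    return(x$overlap_length > y$overlap_length)
  }
  if (x$orientation != y$orientation) return(x$orientation == "forward")
  x$offset < y$offset
}

# Average two matrices placed at a relative offset: overlapping columns are
# the per-base arithmetic mean, non-overlapping columns pass through.
# Returns list(matrix, a_start, b_start): 0-based starts of a and b in the
# merged coordinate system.
overlay_average <- function(a, b, offset) {
  La <- ncol(a); Lb <- ncol(b)
  lo <- min(0L, offset)
  hi <- max(La, offset + Lb)
  L <- hi - lo
  acc <- matrix(0, 4, L)
  n <- integer(L)
  ai <- (0:(La - 1)) - lo + 1
  acc[, ai] <- acc[, ai] + a
  n[ai] <- n[ai] + 1L
  bi <- (offset + 0:(Lb - 1)) - lo + 1
  acc[, bi] <- acc[, bi] + b
  n[bi] <- n[bi] + 1L
  m <- sweep(acc, 2, n, "/")
  list(matrix = position_matrix(m), a_start = -lo, b_start = offset - lo)
}

rc_dimer <- function(d) {
  L <- ncol(d$motif$matrix)
  flip <- function(sp) c(L - sp[2], L - sp[1])
  dimer_annotation(
    motif = {
      m <- d$motif
      m$matrix <- reverse_complement(m$matrix)
      m$tf_members <- rev(m$tf_members)
      m
    },
    half_spans = list(flip(d$half_spans[[2]]), flip(d$half_spans[[1]])),
    palindromic_halves = rev(d$palindromic_halves),
    member_order = rev(d$member_order)
  )
}

# Which half (1/2) of dimer d carries TF `tf`; 0 if absent.
half_of <- function(d, tf) {
  w <- which(d$member_order == tf)
  if (length(w) == 0) 0L else w[1]
}

# Core shared-site merge used by merge_dimers and extend_multimer.
# `host`: list(matrix, members_info). `d`: DimerAnnotation sharing TF `shared`
# whose site in the host spans host_span. `side`: -1 to extend left, +1 right.
merge_at_shared <- function(host_matrix, host_info, d, shared, side,
                            min_overlap) {
  hd <- half_of(d, shared)
  if (hd == 0) stop("chaining error: dimer ", d$motif$id,
                    " lacks shared member ", shared)
  # orient the dimer so its non-shared half extends to `side`
  other_side <- if (hd == 1) 1 else -1   # side the non-shared half lies on
  if (other_side != side) d <- rc_dimer(d)
  hd <- half_of(d, shared)
  dspan <- d$half_spans[[hd]]
  hspan <- host_info[host_info$tf == shared, c("start", "end")]
  hspan <- c(hspan$start[1], hspan$end[1])
  # fine alignment of the shared member's half matrices
  hhalf <- host_matrix[, (hspan[1] + 1):hspan[2], drop = FALSE]
  dhalf <- d$motif$matrix[, (dspan[1] + 1):dspan[2], drop = FALSE]
  al <- align_pfms(hhalf, dhalf,
                   min_overlap = min(ncol(hhalf), ncol(dhalf)))
  fine <- if (al$orientation == "forward") al$offset else 0L
  offset <- hspan[1] + fine - dspan[1]
  ov <- min(ncol(host_matrix), offset + ncol(d$motif$matrix)) - max(0, offset)
  if (ov < min_overlap) {
    stop("merge refused: alignment overlap ", ov, " < min_overlap ",
         min_overlap)
  }
  mg <- overlay_average(host_matrix, d$motif$matrix, offset)
  # updated member table in merged coordinates
  info <- host_info
  info$start <- info$start + mg$a_start
  info$end <- info$end + mg$a_start
  onew <- if (hd == 1) 2L else 1L
  nspan <- d$half_spans[[onew]]
  newrow <- data.frame(tf = d$member_order[onew],
                       start = mg$b_start + nspan[1],
                       end = mg$b_start + nspan[2],
                       palindromic = d$palindromic_halves[onew],
                       stringsAsFactors = FALSE)
  info <- rbind(info, newrow)
  info <- info[order(info$start), , drop = FALSE]
  rownames(info) <- NULL
  list(matrix = mg$matrix, members_info = info, overlap = ov)
}

#' Merge two dimeric motifs sharing a palindromic member into a 3-TF motif
#'
#' Given dimers A-B and C-B with B palindromic in both, the dimers are
#' superimposed on the shared member's site (second dimer reverse-complemented
#' as needed so A and C extend on opposite sides); at overlapping positions
#' the two matrices are averaged per base, per position, and non-overlapping
#' positions pass through unchanged.
#'
#' @param ab,cb DimerAnnotation sharing exactly one member.
#' @param min_overlap minimum columns of overlap for the merge.
#' @return MotifRecord of arity 3 with a `members_info` table.
#' @export
merge_dimers <- function(ab, cb, min_overlap = 4) {
  stopifnot(inherits(ab, "DimerAnnotation"), inherits(cb, "DimerAnnotation"))
  shared <- intersect(ab$member_order, cb$member_order)
  if (length(shared) != 1) {
    stop("chaining error: dimers must share exactly one member (shared: ",
         paste(shared, collapse = ","), ")")
  }
  h1 <- half_of(ab, shared); h2 <- half_of(cb, shared)
  if (!ab$palindromic_halves[h1] || !cb$palindromic_halves[h2]) {
    stop("chaining error: shared member ", shared,
         " must be palindromic in both dimers")
  }
  # host = ab; extend on the side opposite ab's non-shared half
  host_info <- data.frame(
    tf = ab$member_order,
    start = vapply(ab$half_spans, `[`, numeric(1), 1),
    end = vapply(ab$half_spans, `[`, numeric(1), 2),
    palindromic = ab$palindromic_halves,
    stringsAsFactors = FALSE
  )
  side <- if (half_of(ab, shared) == 1) -1 else 1
  mg <- merge_at_shared(ab$motif$matrix, host_info, cb, shared, side,
                        min_overlap)
  members <- mg$members_info$tf
  rec <- motif_record(paste(members, collapse = "+"), mg$matrix,
                      tf_members = members, members_info = mg$members_info)
  attr(rec, "source_dimers") <- c(ab$motif$id, cb$motif$id)
  rec
}

#' Extend a multimeric motif with one more dimer
#'
#' The dimer must share its overlap member with a terminal member of the
#' multimer, and that shared site must be flagged palindromic on both sides;
#' merge semantics are as in [merge_dimers()].
#'
#' @param multi MotifRecord with a `members_info` table (arity >= 3).
#' @param dimer DimerAnnotation.
#' @param min_overlap minimum columns of overlap.
#' @return MotifRecord with arity incremented by 1.
#' @export
extend_multimer <- function(multi, dimer, min_overlap = 4) {
  stopifnot(inherits(multi, "MotifRecord"), inherits(dimer, "DimerAnnotation"))
  info <- multi$members_info
  if (is.null(info)) stop("multimer lacks members_info; build it via merge_dimers")
  terminals <- c(info$tf[1], info$tf[nrow(info)])
  shared <- intersect(dimer$member_order, terminals)
  shared <- setdiff(shared, info$tf[-c(1, nrow(info))])
  if (length(shared) == 0) {
    stop("chaining error: dimer ", dimer$motif$id,
         " shares no terminal member with ", multi$id)
  }
  shared <- shared[1]
  side <- if (shared == info$tf[1]) -1 else 1
  hd <- half_of(dimer, shared)
  if (!dimer$palindromic_halves[hd] ||
      !info$palindromic[match(shared, info$tf)]) {
    stop("chaining error: shared terminal member ", shared,
         " must be palindromic in both the multimer and the dimer")
  }
  mg <- merge_at_shared(multi$matrix, info, dimer, shared, side, min_overlap)
  members <- mg$members_info$tf
  rec <- motif_record(paste(members, collapse = "+"), mg$matrix,
                      tf_members = members, members_info = mg$members_info)
  attr(rec, "source_dimers") <- c(attr(multi, "source_dimers"),
                                  dimer$motif$id)
  rec
}

chain_key <- function(members) {
  a <- paste(members, collapse = "+")
  b <- paste(rev(members), collapse = "+")
  min(a, b)
}

#' Enumerate legal multimeric motifs from a dimer catalog
#'
#' All 3-TF motifs buildable from dimer pairs sharing one member palindromic
#' in both, iteratively extended up to `max_arity`. Chains are deduplicated up
#' to full reverse complement of the member sequence, and no chain uses the
#' same dimer record twice consecutively. When a level exceeds `limit`, a
#' seeded random subset of size `limit` is kept.
#'
#' @param dimer_catalog list of DimerAnnotation.
#' @param max_arity integer in 3..6.
#' @param limit maximum number of chains retained per arity level.
#' @param seed RNG seed used when sampling under `limit`.
#' @param min_overlap minimum merge overlap.
#' @return list of MotifRecord (arities 3..max_arity).
#' @export
enumerate_chains <- function(dimer_catalog, max_arity = 3, limit = Inf,
                             seed = 1, min_overlap = 4) {
  stopifnot(max_arity >= 3, max_arity <= 6)
  if (length(dimer_catalog) == 0) return(list())
  take_limit <- function(lst) {
    if (length(lst) <= limit) return(lst)
    withr::with_seed(seed, lst[sort(sample.int(length(lst), limit))])
  }
  level <- list()
  seen <- character(0)
  nd <- length(dimer_catalog)
  for (i in seq_len(nd)) {
    for (j in seq_len(nd)) {
      if (i == j) next
      rec <- tryCatch(
        merge_dimers(dimer_catalog[[i]], dimer_catalog[[j]], min_overlap),
        error = function(e) NULL)
      if (is.null(rec)) next
      key <- chain_key(rec$tf_members)
      if (key %in% seen) next
      seen <- c(seen, key)
      attr(rec, "last_dimer") <- dimer_catalog[[j]]$motif$id
      level <- c(level, list(rec))
    }
  }
  level <- take_limit(level)
  out <- level
  arity <- 3
  while (arity < max_arity && length(level) > 0) {
    nxt <- list()
    for (rec in level) {
      for (d in dimer_catalog) {
        if (identical(d$motif$id, attr(rec, "last_dimer"))) next
        ext <- tryCatch(extend_multimer(rec, d, min_overlap),
                        error = function(e) NULL)
        if (is.null(ext)) next
        key <- chain_key(ext$tf_members)
        if (key %in% seen) next
        seen <- c(seen, key)
        attr(ext, "last_dimer") <- d$motif$id
        nxt <- c(nxt, list(ext))
      }
    }
    nxt <- take_limit(nxt)
    out <- c(out, nxt)
    level <- nxt
    arity <- arity + 1
  }
  out
}

#' Write chain provenance as a TSV sidecar
#'
#' @param records list of multimeric MotifRecord from [enumerate_chains()].
#' @param path output TSV path.
#' @export
write_chain_provenance <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r) {
    data.frame(chain_id = r$id, arity = r$arity,
               members = paste(r$tf_members, collapse = "+"),
               source_dimers = paste(attr(r, "source_dimers"), collapse = ","),
               length = ncol(r$matrix), ic = information_content(r$matrix),
               stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
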