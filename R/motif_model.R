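#' @useDynLib regspec, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor ppois dpois runif binom.test
#' @importFrom utils head tail write.table combn
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Validate and construct a position frequency matrix
#'
#' A position matrix is a plain numeric 4 x L matrix with rows A, C, G, T;
#' every column is a probability distribution over the four bases.
#'
#' @param x numeric matrix (4 x L, or L x 4 which is transposed).
#' @param tol tolerance on column sums.
#' @return validated 4 x L matrix with rownames A,C,G,T.
#' @export
position_matrix <- function(x, tol = 1e-9) {
  x <- as.matrix(x)
  if (nrow(x) != 4 && ncol(x) == 4) x <- t(x)
  if (nrow(x) != 4) stop("position matrix must have 4 rows (A,C,G,T)")
  if (ncol(x) < 1) stop("position matrix must have length >= 1")
  storage.mode(x) <- "double"
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("position matrix entries must be finite and non-negative")
  }
  cs <- colSums(x)
  if (any(abs(cs - 1) > tol)) {
    stop("position matrix columns must sum to 1 (max deviation ",
         format(max(abs(cs - 1))), ")")
  }
  if (any(cs != 1)) x <- sweep(x, 2, cs, "/")  # exact renormalization
  dimnames(x) <- list(DNA_BASES, NULL)
  x
}

#' Normalize a count matrix into a position frequency matrix
#'
#' Each column becomes (count + pseudocount) / (colsum + 4 * pseudocount).
#'
#' @param counts non-negative 4 x L numeric matrix.
#' @param pseudocount non-negative per-base pseudocount.
#' @return position matrix (columns sum to 1).
#' @export
normalize_counts <- function(counts, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4 && ncol(counts) == 4) counts <- t(counts)
  if (nrow(counts) != 4) stop("count matrix must have 4 rows (A,C,G,T)")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  cs <- colSums(counts)
  if (any(cs == 0) && pseudocount == 0) {
    stop("degenerate column: all-zero counts with zero pseudocount (column ",
         which(cs == 0)[1], ")")
  }
  m <- sweep(counts + pseudocount, 2, cs + 4 * pseudocount, "/")
  position_matrix(m)
}

#' Motif record: a position matrix plus provenance
#'
#' @param id motif identifier.
#' @param matrix position matrix (validated).
#' @param tf_members ordered character vector of member TF ids; arity is its
#'   length (1 = monomer, 2 = dimer, >= 3 multimer).
#' @param members_info optional data.frame (tf, start, end, palindromic) giving
#'   the 0-based half-open column span of each member site and whether that
#'   member's site is palindromic; used when chaining multimers.
#' @param orientation_notes optional per-member strand flags.
#' @return object of class `MotifRecord`.
#' @export
motif_record <- function(id, matrix, tf_members = id, members_info = NULL,
                         orientation_notes = NULL) {
  stopifnot(is.character(id), length(id) == 1)
  if (length(tf_members) < 1) stop("arity must be >= 1")
  rec <- list(
    id = id,
    tf_members = as.character(tf_members),
    arity = length(tf_members),
    matrix = position_matrix(matrix),
    members_info = members_info,
    orientation_notes = orientation_notes
  )
  class(rec) <- "MotifRecord"
  rec
}

#' @export
print.MotifRecord <- function(x, ...) {
  cat(sprintf("MotifRecord %s: arity %d (%s), length %d, IC %.2f bits\n",
              x$id, x$arity, paste(x$tf_members, collapse = "+"),
              ncol(x$matrix), information_content(x$matrix)))
  invisible(x)
}

as_pfm <- function(x) {
  if (inherits(x, "MotifRecord")) x$matrix else position_matrix(x)
}

#' Information content of a position matrix, in bits
#'
#' IC = sum over columns of (2 + sum_b p_b log2 p_b), with 0 log 0 = 0 and a
#' uniform background. Bounded by [0, 2L].
#'
#' @param m position matrix or MotifRecord.
#' @return total information content in bits.
#' @export
information_content <- function(m) {
  m <- as_pfm(m)
  pl <- m * log2(m)
  pl[m == 0] <- 0
  sum(2 + colSums(pl))
}

#' Effective motif length in base-pair equivalents
#'
#' IC / 2: the length of a deterministic site carrying the same information.
#' A 12-bit monomer has effective length 6.
#'
#' @param m position matrix or MotifRecord.
#' @return effective length (real).
#' @export
effective_length <- function(m) information_content(m) / 2

#' Reverse complement
#'
#' For a position matrix: columns reversed, A<->T and C<->G swapped
#' (an involution). For a character DNA string: the usual reverse complement
#' (IUPAC ambiguity codes other than N are left untouched).
#'
#' @param x position matrix, MotifRecord, or character vector of DNA strings.
#' @return object of the same kind.
#' @export
reverse_complement <- function(x) UseMethod("reverse_complement")

#' @export
reverse_complement.default <- function(x) {
  m <- as_pfm(x)
  position_matrix(m[4:1, rev(seq_len(ncol(m))), drop = FALSE])
}

#' @export
reverse_complement.MotifRecord <- function(x) {
  x$matrix <- reverse_complement(x$matrix)
  x$tf_members <- rev(x$tf_members)
  if (!is.null(x$members_info)) {
    L <- ncol(x$matrix)
    mi <- x$members_info
    newstart <- L - mi$end
    mi$end <- L - mi$start
    mi$start <- newstart
    x$members_info <- mi[rev(seq_len(nrow(mi))), , drop = FALSE]
    rownames(x$members_info) <- NULL
  }
  x
}

#' @export
reverse_complement.character <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0) return("")
    intToUtf8(rev(utf8ToInt(chartr("ACGTacgtN", "TGCAtgcaN", s))))
  }, character(1), USE.NAMES = FALSE)
}

# Pearson correlation between two 4-vectors with the zero-variance convention:
# both columns uniform -> 1, exactly one uniform -> 0.
column_pcc <- function(x, y) {
  vx <- stats::var(x) > 0
  vy <- stats::var(y) > 0
  if (!vx && !vy) return(1)
  if (!vx || !vy) return(0)
  stats::cor(x, y)
}

# Mean per-column PCC between two equal-length matrices at zero offset.
mean_column_pcc <- function(a, b) {
  stopifnot(ncol(a) == ncol(b))
  mean(vapply(seq_len(ncol(a)), function(j) column_pcc(a[, j], b[, j]),
              numeric(1)))
}

#' Is a motif palindromic?
#'
#' A matrix is called palindromic when the mean per-column Pearson correlation
#' between the matrix and its reverse complement (at zero offset) reaches
#' `min_correlation`. Zero-variance (uniform) columns contribute 1 when both
#' compared columns are uniform and 0 otherwise.
#'
#' @param m position matrix or MotifRecord.
#' @param min_correlation threshold in [-1, 1]; default 0.8.
#' @return logical.
#' @export
is_palindromic <- function(m, min_correlation = 0.8) {
  m <- as_pfm(m)
  stopifnot(min_correlation >= -1, min_correlation <= 1)
  mean_column_pcc(m, reverse_complement(m)) >= min_correlation
}

# Make an even-length matrix exactly palindromic by mirroring its left half;
# odd lengths get a self-complement-symmetrized center column.
palindromize <- function(m) {
  m <- as_pfm(m)
  L <- ncol(m)
  h <- L %/% 2
  left <- m[, seq_len(h), drop = FALSE]
  right <- reverse_complement(left)
  if (L %% 2 == 0) {
    out <- cbind(left, right)
  } else {
    ctr <- (m[, h + 1] + m[4:1, h + 1]) / 2
    out <- cbind(left, ctr, right)
  }
  position_matrix(out)
}

#' Build a position matrix from a consensus string
#'
#' @param consensus DNA string over ACGT.
#' @param strength probability assigned to the consensus base per column; the
#'   remainder is split evenly over the other bases. 1 gives a deterministic
#'   matrix.
#' @return position matrix.
#' @export
consensus_matrix <- function(consensus, strength = 1) {
  b <- match(strsplit(toupper(consensus), "")[[1]], DNA_BASES)
  if (anyNA(b)) stop("consensus must contain only A,C,G,T")
  m <- matrix((1 - strength) / 3, nrow = 4, ncol = length(b))
  m[cbind(b, seq_along(b))] <- strength
  position_matrix(m)
}

## ---------------------------------------------------------------------------
## Motif file I/O: MEME minimal, JASPAR pfm, TSV (`pos A C G T` blocks)
## ---------------------------------------------------------------------------

members_to_string <- function(rec) paste(rec$tf_members, collapse = "+")
members_from_string <- function(id, alt) {
  if (!is.na(alt) && nzchar(alt) && grepl("+", alt, fixed = TRUE)) {
    strsplit(alt, "+", fixed = TRUE)[[1]]
  } else if (!is.na(alt) && nzchar(alt)) {
    alt
  } else {
    id
  }
}

#' Read motifs from a file
#'
#' Supported dialects: MEME minimal, JASPAR pfm (4 count rows per motif,
#' optionally bracketed), and a TSV dialect of blocks headed by
#' `# motif: <id> <members>` with a `pos A C G T` table. Member TF lists are
#' carried in the MEME alternate name / JASPAR name field joined by `+`.
#'
#' @param path file path.
#' @param format one of "meme", "jaspar", "tsv".
#' @param pseudocount pseudocount applied when normalizing count inputs.
#' @return list of MotifRecord.
#' @export
read_motifs <- function(path, format = c("meme", "jaspar", "tsv"),
                        pseudocount = 0) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(lines)))) {
    warning("no motifs found in ", path)
    return(list())
  }
  switch(format,
    meme = read_meme(lines, path),
    jaspar = read_jaspar(lines, path, pseudocount),
    tsv = read_tsv_motifs(lines, path)
  )
}

read_meme <- function(lines, path) {
  idx <- grep("^MOTIF\\b", lines)
  if (length(idx) == 0) stop("no MOTIF blocks in MEME file ", path)
  out <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    hdr <- strsplit(trimws(lines[idx[i]]), "\\s+")[[1]]
    id <- hdr[2]
    alt <- if (length(hdr) >= 3) hdr[3] else NA_character_
    j <- idx[i] + 1
    while (j <= length(lines) &&
           !grepl("^letter-probability matrix", lines[j])) j <- j + 1
    if (j > length(lines)) {
      stop("malformed MEME file ", path, ": no probability matrix for motif ",
           id, " (line ", idx[i], ")")
    }
    w <- sub(".*w=\\s*(\\d+).*", "\\1", lines[j])
    w <- suppressWarnings(as.integer(w))
    if (is.na(w)) stop("malformed MEME header at line ", j, " in ", path)
    rows <- lines[(j + 1):(j + w)]
    vals <- lapply(seq_along(rows), function(r) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(rows[r]), "\\s+")[[1]]))
      if (length(v) != 4 || anyNA(v)) {
        stop("malformed MEME matrix row at line ", j + r, " in ", path)
      }
      v
    })
    m <- t(do.call(rbind, vals))
    out[[i]] <- motif_record(id, position_matrix(m, tol = 1e-4),
                             tf_members = members_from_string(id, alt))
  }
  out
}

read_jaspar <- function(lines, path, pseudocount) {
  idx <- grep("^>", lines)
  if (length(idx) == 0) stop("no '>' headers in JASPAR file ", path)
  bounds <- c(idx, length(lines) + 1)
  out <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    hdr <- strsplit(sub("^>\\s*", "", lines[idx[i]]), "\\s+")[[1]]
    id <- hdr[1]
    alt <- if (length(hdr) >= 2) hdr[2] else NA_character_
    block <- lines[(idx[i] + 1):(bounds[i + 1] - 1)]
    block <- block[nzchar(trimws(block))]
    if (length(block) != 4) {
      stop("JASPAR motif ", id, " at line ", idx[i], " in ", path,
           " must have 4 rows, found ", length(block))
    }
    rows <- lapply(seq_along(block), function(r) {
      txt <- gsub("^[ACGTacgt]\\s*|\\[|\\]", " ", block[r])
      v <- suppressWarnings(as.numeric(strsplit(trimws(txt), "\\s+")[[1]]))
      if (anyNA(v) || length(v) == 0) {
        stop("malformed JASPAR row at line ", idx[i] + r, " in ", path)
      }
      v
    })
    if (length(unique(lengths(rows))) != 1) {
      stop("JASPAR motif ", id, ": row length mismatch at line ", idx[i],
           " in ", path)
    }
    counts <- do.call(rbind, rows)
    m <- normalize_counts(counts, pseudocount = pseudocount)
    out[[i]] <- motif_record(id, m, tf_members = members_from_string(id, alt))
  }
  out
}

read_tsv_motifs <- function(lines, path) {
  idx <- grep("^#\\s*motif:", lines)
  if (length(idx) == 0) stop("no '# motif:' blocks in TSV file ", path)
  bounds <- c(idx, length(lines) + 1)
  out <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    hdr <- strsplit(trimws(sub("^#\\s*motif:\\s*", "", lines[idx[i]])),
                    "\\s+")[[1]]
    id <- hdr[1]
    alt <- if (length(hdr) >= 2) hdr[2] else NA_character_
    block <- lines[(idx[i] + 1):(bounds[i + 1] - 1)]
    block <- block[nzchar(trimws(block))]
    if (length(block) < 2 ||
        !identical(tolower(strsplit(trimws(block[1]), "\\s+")[[1]]),
                   c("pos", "a", "c", "g", "t"))) {
      stop("TSV motif block at line ", idx[i], " in ", path,
           " must start with header 'pos A C G T'")
    }
    vals <- lapply(seq_along(block[-1]), function(r) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(block[r + 1]),
                                                "\\s+")[[1]]))
      if (length(v) != 5 || anyNA(v)) {
        stop("malformed TSV motif row at line ", idx[i] + 1 + r, " in ", path)
      }
      v[-1]
    })
    m <- t(do.call(rbind, vals))
    out[[i]] <- motif_record(id, position_matrix(m, tol = 1e-4),
                             tf_members = members_from_string(id, alt))
  }
  out
}

#' Write motifs to a file
#'
#' @param records list of MotifRecord.
#' @param path output path.
#' @param format one of "meme", "jaspar", "tsv".
#' @export
write_motifs <- function(records, path, format = c("meme", "jaspar", "tsv")) {
  format <- match.arg(format)
  if (inherits(records, "MotifRecord")) records <- list(records)
  fmtm <- function(m) apply(m, 2, function(col) {
    paste(formatC(col, digits = 8, format = "f"), collapse = " ")
  })
  lines <- switch(format,
    meme = {
      hdr <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", "")
      body <- unlist(lapply(records, function(r) {
        c(sprintf("MOTIF %s %s", r$id, members_to_string(r)),
          sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                  ncol(r$matrix)),
          fmtm(r$matrix), "")
      }))
      c(hdr, body)
    },
    jaspar = unlist(lapply(records, function(r) {
      rows <- vapply(1:4, function(b) {
        paste0(DNA_BASES[b], " [ ",
               paste(formatC(r$matrix[b, ], digits = 8, format = "f"),
                     collapse = " "), " ]")
      }, character(1))
      c(sprintf(">%s %s", r$id, members_to_string(r)), rows)
    })),
    tsv = unlist(lapply(records, function(r) {
      rows <- vapply(seq_len(ncol(r$matrix)), function(j) {
        paste(c(j - 1, formatC(r$matrix[, j], digits = 8, format = "f")),
              collapse = "\t")
      }, character(1))
      c(sprintf("# motif: %s %s", r$id, members_to_string(r)),
        "pos\tA\tC\tG\tT", rows)
    }))
  )
  writeLines(lines, path)
  invisible(path)
}
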