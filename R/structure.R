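# Quadripartite structure detection on circular plastomes.
#
# A land-plant plastome is a circle of ~150-160 kb holding two near-identical
# inverted repeats (IRa/IRb, ~26 kb) that separate a large (LSC, ~86 kb) and
# a small (SSC, ~19 kb) single-copy region.  Detection proceeds by exact
# k-mer seeding between the doubled sequence and its reverse complement,
# merging of collinear seed runs into maximal inverted matches, and selection
# of the longest disjoint repeat pair.  All reported coordinates live on the
# canonical rotation: position 0 is the first LSC base and the region order
# is LSC, IRb, SSC, IRa.

#' Construct a plastome sequence object
#'
#' @param seq nucleotide string (IUPAC codes, case-insensitive).
#' @param sample_id label for the accession.
#' @param circular logical; plastomes are circular molecules.
#' @return object of class `plastome` (list with `sample_id`, `seq`,
#'   `circular`).
#' @export
plastome <- function(seq, sample_id = "plastome", circular = TRUE) {
  seq <- toupper(seq)
  assert_nucleotides(seq, paste0("plastome '", sample_id, "'"))
  structure(list(sample_id = sample_id, seq = seq, circular = circular),
            class = "plastome")
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("<plastome> %s: %s bp, %s\n", x$sample_id,
              format(nchar(x$seq), big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

as_plastome <- function(x, sample_id = "plastome") {
  if (inherits(x, "plastome")) return(x)
  plastome(x, sample_id = sample_id)
}

# All maximal exact inverted repeat pairs of length >= min_len on the circle.
# Returns a data.frame with 0-based circular starts of the two copies and
# the repeat length.  Low-complexity explosions are cut off early.
find_inverted_repeats <- function(s, min_len, max_pairs = 2e7) {
  n <- nchar(s)
  k <- as.integer(min(min_len, 25L))
  s2 <- paste0(s, s)
  r2 <- revcomp(s2)
  m <- 2L * n - k + 1L
  starts <- seq_len(m)
  kS <- substring(s2, starts, starts + k - 1L)
  kR <- substring(r2, starts, starts + k - 1L)
  keys <- unique(kS)
  iS <- match(kS, keys)
  iR <- match(kR, keys)
  posS <- split(starts, iS)
  posR <- split(starts, iR)
  sid <- as.integer(names(posS))
  rid <- as.integer(names(posR))
  common <- intersect(sid, rid)
  if (length(common) == 0L) return(NULL)
  si <- match(common, sid)
  ri <- match(common, rid)
  lenS <- lengths(posS)[si]
  lenR <- lengths(posR)[ri]
  npair <- sum(as.numeric(lenS) * lenR)
  if (npair > max_pairs) {
    stop("structural anomaly: repeat-degenerate sequence (seed pair ",
         "explosion)", call. = FALSE)
  }
  pa_l <- vector("list", length(common))
  px_l <- vector("list", length(common))
  for (i in seq_along(common)) {
    a <- posS[[si[i]]]; x <- posR[[ri[i]]]
    pa_l[[i]] <- rep(a, times = length(x))
    px_l[[i]] <- rep(x, each = length(a))
  }
  pa <- unlist(pa_l, use.names = FALSE)
  px <- unlist(px_l, use.names = FALSE)
  # matches extend along constant diagonal a - x
  d <- pa - px
  o <- order(d, pa)
  pa <- pa[o]; px <- px[o]; d <- d[o]
  newrun <- c(TRUE, !(d[-1] == d[-length(d)] & diff(pa) == 1L))
  runid <- cumsum(newrun)
  a0 <- tapply(pa, runid, min)
  alen <- tapply(pa, runid, length) + k - 1L
  x0 <- tapply(px, runid, min)
  # copy B of the inverted pair in s2 coordinates
  b0 <- 2L * n - x0 - alen + 2L
  len <- pmin(as.integer(alen), n)
  A <- (as.integer(a0) - 1L) %% n
  B <- (as.integer(b0) - 1L) %% n
  key <- paste(pmin(A, B), pmax(A, B), len)
  keep <- !duplicated(key)
  res <- data.frame(start1 = pmin(A, B)[keep], start2 = pmax(A, B)[keep],
                    len = len[keep])
  res[res$len >= min_len, , drop = FALSE]
}

# TRUE if the two 0-based circular intervals [s1, s1+len), [s2, s2+len)
# are disjoint on a circle of size n
circ_disjoint <- function(s1, s2, len, n) {
  if (len * 2 > n) return(FALSE)
  pos1 <- (s1 + seq_len(len) - 1L) %% n
  # interval test without materializing pos2: distance from s2 along circle
  off <- (pos1 - s2) %% n
  all(off >= len)
}

#' Detect the quadripartite architecture of a circular plastome
#'
#' Finds the longest pair of disjoint inverted repeats (exact match by
#' default) on the circular sequence and derives the LSC/IRb/SSC/IRa
#' partition.  Coordinates are reported on the canonical rotation: position
#' 0 is the first LSC base, regions in the order LSC, IRb, SSC, IRa.
#'
#' @param seq a [plastome()] or nucleotide string.
#' @param min_ir_len minimum inverted-repeat length in bp (default 1000;
#'   plastome-scale work should keep this >= 100, the floor accepted here is
#'   8 so that miniature test genomes remain analyzable).
#' @param max_mismatch_rate allowed divergence between the two IR copies
#'   when merging collinear exact matches (default 0 = exact; at most 0.001).
#' @return object of class `quad_partition`: 0-based half-open intervals
#'   `lsc`, `irb`, `ssc`, `ira` on the canonical rotation, per-region
#'   `lengths` and `gc`, the canonical-rotation `sequence`, the rotation
#'   `offset` applied, and `ir_mismatches` between the two IR copies.
#' @export
detect_quadripartite <- function(seq, min_ir_len = 1000L,
                                 max_mismatch_rate = 0) {
  p <- as_plastome(seq)
  if (!p$circular) stop("plastome must be circular", call. = FALSE)
  if (min_ir_len < 8) stop("min_ir_len must be >= 8", call. = FALSE)
  if (max_mismatch_rate < 0 || max_mismatch_rate > 0.001) {
    stop("max_mismatch_rate must be in [0, 0.001]", call. = FALSE)
  }
  s <- p$seq
  n <- nchar(s)
  reps <- find_inverted_repeats(s, min_ir_len)
  if (is.null(reps) || nrow(reps) == 0L) {
    stop("no quadripartite structure: no inverted repeat >= ", min_ir_len,
         " bp", call. = FALSE)
  }
  if (max_mismatch_rate > 0) {
    reps <- merge_tolerant_repeats(s, reps, max_mismatch_rate, min_ir_len)
  }
  reps <- reps[order(-reps$len, reps$start1, reps$start2), , drop = FALSE]
  best <- reps[1L, ]
  ties <- reps[reps$len == best$len, , drop = FALSE]
  best <- ties[1L, ]
  if (!circ_disjoint(best$start1, best$start2, best$len, n)) {
    stop("structural anomaly: best inverted repeat pair overlaps itself",
         call. = FALSE)
  }
  build_partition(p, best$start1, best$start2, best$len)
}

# Merge exact repeat matches separated by a small number of mismatching
# positions (same pair geometry), honoring an overall mismatch-rate cap.
merge_tolerant_repeats <- function(s, reps, rate, min_len) {
  n <- nchar(s)
  # anti-diagonal invariant of an inverted pair: start1 + start2 + len
  reps$anti <- (reps$start1 + reps$start2 + reps$len) %% n
  out <- reps
  for (a in unique(reps$anti)) {
    grp <- reps[reps$anti == a, , drop = FALSE]
    if (nrow(grp) < 2L) next
    grp <- grp[order(grp$start1), ]
    i <- 1L
    while (i < nrow(grp)) {
      gap <- grp$start1[i + 1L] - (grp$start1[i] + grp$len[i])
      span <- grp$start1[i + 1L] + grp$len[i + 1L] - grp$start1[i]
      if (gap >= 0 && gap <= floor(rate * span)) {
        grp$len[i] <- span
        grp$start2[i] <- grp$start2[i + 1L]
        grp <- grp[-(i + 1L), , drop = FALSE]
      } else i <- i + 1L
    }
    out <- rbind(out[out$anti != a, ], grp)
  }
  out$anti <- NULL
  out
}

build_partition <- function(p, s1, s2, len) {
  s <- p$seq
  n <- nchar(s)
  # single-copy gaps between the two repeat copies, walking the circle
  gap_a_start <- (s1 + len) %% n          # after copy at s1
  gap_a_len <- (s2 - gap_a_start) %% n
  gap_b_start <- (s2 + len) %% n          # after copy at s2
  gap_b_len <- (s1 - gap_b_start) %% n
  if (gap_a_len == 0L || gap_b_len == 0L) {
    stop("structural anomaly: repeat copies are adjacent (no single-copy ",
         "region)", call. = FALSE)
  }
  if (gap_a_len == gap_b_len) {
    stop("structural anomaly: single-copy regions have equal length; ",
         "LSC/SSC assignment undefined", call. = FALSE)
  }
  if (gap_a_len > gap_b_len) {
    lsc_start <- gap_a_start; lsc_len <- gap_a_len
    irb_start <- s2; ssc_start <- gap_b_start; ssc_len <- gap_b_len
    ira_start <- s1
  } else {
    lsc_start <- gap_b_start; lsc_len <- gap_b_len
    irb_start <- s1; ssc_start <- gap_a_start; ssc_len <- gap_a_len
    ira_start <- s2
  }
  canonical <- circ_substr(s, lsc_start, n)
  lengths <- c(lsc = lsc_len, irb = len, ssc = ssc_len, ira = len)
  if (sum(lengths) != n) {
    stop("structural anomaly: regions do not tile the genome", call. = FALSE)
  }
  bounds <- cumsum(c(0L, lengths))
  iv <- function(i) c(start = unname(bounds[i]), end = unname(bounds[i + 1L]))
  ch <- seq_chars(canonical)
  reg_gc <- vapply(1:4, function(i)
    gc_fraction(ch[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))
  irb_seq <- substr(canonical, bounds[2] + 1L, bounds[3])
  ira_seq <- substr(canonical, bounds[4] + 1L, bounds[5])
  mm <- sum(seq_chars(revcomp(irb_seq)) != seq_chars(ira_seq))
  structure(list(
    sample_id = p$sample_id,
    lsc = iv(1), irb = iv(2), ssc = iv(3), ira = iv(4),
    lengths = lengths,
    gc = c(total = gc_fraction(ch), lsc = reg_gc[1], irb = reg_gc[2],
           ssc = reg_gc[3], ira = reg_gc[4]),
    sequence = canonical,
    offset = lsc_start,
    ir_mismatches = mm
  ), class = "quad_partition")
}

#' @export
print.quad_partition <- function(x, ...) {
  cat(sprintf("<quad_partition> %s: total %d bp\n", x$sample_id,
              sum(x$lengths)))
  cat(sprintf("  LSC %d bp | IRb %d bp | SSC %d bp | IRa %d bp\n",
              x$lengths["lsc"], x$lengths["irb"], x$lengths["ssc"],
              x$lengths["ira"]))
  cat(sprintf("  GC total %.4f; IR copy mismatches: %d\n",
              x$gc["total"], x$ir_mismatches))
  invisible(x)
}

# region label (LSC/IR/SSC) of a 0-based canonical position
region_of_position <- function(part, pos0) {
  b <- cumsum(c(0L, part$lengths))
  lab <- c("LSC", "IR", "SSC", "IR")
  idx <- findInterval(pos0, b, rightmost.closed = FALSE, left.open = FALSE)
  idx[pos0 >= b[5] | pos0 < 0] <- NA_integer_
  lab[idx]
}

#' Per-region length and GC metrics
#'
#' @param seq plastome on the canonical rotation of `part` (string or
#'   [plastome()]).
#' @param part a [detect_quadripartite()] partition.
#' @return data.frame with one row per region (plus `total`): `region`,
#'   `length`, `gc`.  Ambiguity codes count toward length but are excluded
#'   from the GC numerator and denominator.
#' @export
region_metrics <- function(seq, part) {
  p <- as_plastome(seq)
  stopifnot(inherits(part, "quad_partition"))
  n <- nchar(p$seq)
  if (sum(part$lengths) != n) {
    stop("partition does not match sequence length", call. = FALSE)
  }
  ch <- seq_chars(p$seq)
  b <- cumsum(c(0L, part$lengths))
  regions <- c("lsc", "irb", "ssc", "ira")
  rows <- lapply(1:4, function(i) {
    sub <- ch[(b[i] + 1L):b[i + 1L]]
    g <- gc_fraction(sub)
    if (is.na(g)) {
      stop("undefined GC: region '", regions[i],
           "' has no unambiguous base", call. = FALSE)
    }
    data.frame(region = regions[i], length = length(sub), gc = g)
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(region = "total", length = n, gc = gc_fraction(ch)))
}

#' Canonicalize rotation, strand and single-copy orientation
#'
#' Among the quadripartite-preserving isomers of `seq` (flip of the LSC, of
#' the SSC, or both -- a flip of both is the whole-molecule strand flip),
#' returns the one whose LSC and SSC maximize positional identity with the
#' reference's corresponding regions, on the canonical rotation.  Ties are
#' broken in favor of fewer flips (no flip < SSC flip < LSC flip < both).
#'
#' @param seq plastome to canonicalize.
#' @param part partition of `seq` (computed if `NULL`).
#' @param reference reference plastome, or its `quad_partition`.
#' @param min_ir_len passed to [detect_quadripartite()] when partitions must
#'   be computed.
#' @return a [plastome()] holding the canonical-rotation sequence of the
#'   best isomer; attribute `flips` records the choice.
#' @export
canonicalize_orientation <- function(seq, part = NULL, reference,
                                     min_ir_len = 1000L) {
  p <- as_plastome(seq)
  if (is.null(part)) part <- detect_quadripartite(p, min_ir_len = min_ir_len)
  if (sum(part$lengths) != nchar(p$seq)) {
    stop("partition invalid for sequence", call. = FALSE)
  }
  ref_part <- if (inherits(reference, "quad_partition")) reference
              else detect_quadripartite(as_plastome(reference),
                                        min_ir_len = min_ir_len)
  b <- cumsum(c(0L, part$lengths))
  seg <- function(i) substr(part$sequence, b[i] + 1L, b[i + 1L])
  L <- seg(1); B <- seg(2); C <- seg(3); A <- seg(4)
  rb <- cumsum(c(0L, ref_part$lengths))
  ref_L <- substr(ref_part$sequence, rb[1] + 1L, rb[2])
  ref_C <- substr(ref_part$sequence, rb[3] + 1L, rb[4])
  ident <- function(a, b) {
    m <- min(nchar(a), nchar(b))
    sum(seq_chars(substr(a, 1, m)) == seq_chars(substr(b, 1, m)))
  }
  combos <- list(c(FALSE, FALSE), c(FALSE, TRUE), c(TRUE, FALSE),
                 c(TRUE, TRUE))
  best <- NULL; best_score <- -1L; best_flip <- NULL
  for (fl in combos) {
    Lx <- if (fl[1]) revcomp(L) else L
    Cx <- if (fl[2]) revcomp(C) else C
    score <- ident(Lx, ref_L) + ident(Cx, ref_C)
    if (score > best_score) {
      best_score <- score
      best <- paste0(Lx, B, Cx, A)
      best_flip <- c(lsc = fl[1], ssc = fl[2])
    }
  }
  out <- plastome(best, sample_id = p$sample_id)
  attr(out, "flips") <- best_flip
  out
}

#' Structure metrics table for a set of plastomes
#'
#' Runs [detect_quadripartite()] on each sequence and assembles the
#' per-accession table of region lengths and GC contents.
#'
#' @param seqs named character vector of sequences (e.g. [read_fasta()]).
#' @param min_ir_len minimum IR length.
#' @return data.frame with columns `sample_id`, `total_len`, `lsc_len`,
#'   `irb_len`, `ssc_len`, `ira_len`, `total_gc`, `lsc_gc`, `ssc_gc`,
#'   `ir_gc`, `ir_asymmetric`.
#' @export
structure_table <- function(seqs, min_ir_len = 1000L) {
  rows <- lapply(names(seqs), function(id) {
    part <- detect_quadripartite(plastome(seqs[[id]], id),
                                 min_ir_len = min_ir_len)
    data.frame(
      sample_id = id,
      total_len = sum(part$lengths),
      lsc_len = unname(part$lengths["lsc"]),
      irb_len = unname(part$lengths["irb"]),
      ssc_len = unname(part$lengths["ssc"]),
      ira_len = unname(part$lengths["ira"]),
      total_gc = unname(part$gc["total"]),
      lsc_gc = unname(part$gc["lsc"]),
      ssc_gc = unname(part$gc["ssc"]),
      ir_gc = unname((part$gc["irb"] + part$gc["ira"]) / 2),
      ir_asymmetric = part$ir_mismatches > 0
    )
  })
  do.call(rbind, rows)
}
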