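# Hypervariable-window and clade-diagnostic screening: candidate barcode
# loci are windows of elevated nucleotide diversity and alignment columns
# whose state exactly separates one (or a set of) genetic cluster(s).

#' Sliding-window nucleotide diversity
#'
#' Windows tile the reference coordinate space at the given step; within
#' each window Pi is computed under complete deletion restricted to the
#' window's columns, and variant events starting in the window are counted.
#'
#' @param aln a [plast_alignment()].
#' @param window window length in bp (reference coordinates); default 600.
#' @param step step in bp; default 200.  Requires `window >= step >= 1`.
#' @param events optional pre-computed [call_variant_events()] table.
#' @return data.frame: `window_start`, `window_end` (0-based half-open),
#'   `n_retained`, `pi`, `variant_count`, `rank` (1 = most diverse).
#' @export
sliding_window_diversity <- function(aln, window = 600L, step = 200L,
                                     events = NULL) {
  stopifnot(window >= step, step >= 1L)
  m <- unclass(aln)
  refpos <- attr(aln, "col_to_ref_pos")
  ref_len <- max(refpos) + 1L
  if (window > ref_len) {
    warning("window longer than genome; using a single whole-genome window",
            call. = FALSE)
    window <- ref_len
    starts <- 0L
  } else {
    starts <- seq.int(0L, ref_len - 1L, by = step)
  }
  if (is.null(events)) events <- call_variant_events(aln)
  n <- nrow(m)
  npairs <- n * (n - 1) / 2
  rows <- lapply(starts, function(s) {
    e <- min(s + window, ref_len)
    cols <- which(refpos >= s & refpos < e)
    sub <- m[, cols, drop = FALSE]
    keep <- retained_columns(sub)
    pi <- if (length(keep) == 0L) NA_real_ else {
      sub2 <- sub[, keep, drop = FALSE]
      tot <- 0
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) tot <- tot + sum(sub2[i, ] != sub2[j, ])
      }
      (tot / length(keep)) / npairs
    }
    vc <- sum(events$ref_start >= s & events$ref_start < e)
    data.frame(window_start = s, window_end = e,
               n_retained = length(keep), pi = pi, variant_count = vc)
  })
  out <- do.call(rbind, rows)
  out$rank <- rank(-out$pi, ties.method = "min", na.last = "keep")
  out
}

#' Clade-diagnostic sites
#'
#' A variant column is diagnostic for a set of clusters S when one of its
#' states is carried by every member of every cluster in S and by no other
#' sample.  Singleton S (one clade) is the preferred report; larger sets
#' are reported when no single clade is separable at that column.  Columns
#' involving gaps are reported as `InDel` sites, others as `SNV`.
#'
#' @param aln a [plast_alignment()].
#' @param clusters data.frame `sample_id`, `cluster`; must cover all rows.
#' @param model optional [gene_model()] used to resolve `locus_label`
#'   (gene name, or `"<left>-<right>"` for intergenic positions).
#' @return data.frame: `aln_column` (1-based), `ref_position` (0-based),
#'   `site_kind`, `target_clades` (comma-joined), `allele`, `locus_label`.
#' @export
clade_diagnostic_sites <- function(aln, clusters, model = NULL) {
  m <- unclass(aln)
  stopifnot(all(rownames(m) %in% clusters$sample_id))
  cl <- stats::setNames(as.character(clusters$cluster), clusters$sample_id)
  cl <- cl[rownames(m)]
  states <- scan_columns(aln)
  refpos <- attr(aln, "col_to_ref_pos")
  idx <- if (!is.null(model)) genic_context_index(model) else NULL
  cols <- which(states != "invariant")
  rows <- list()
  for (cc in cols) {
    col <- m[, cc]
    for (s in unique(col)) {
      if (s %in% AMBIG_CHARS) next
      carriers <- cl[col == s]
      carried_clades <- unique(carriers)
      # all members of every carried clade must carry s, and nobody else
      full <- all(vapply(carried_clades, function(g)
        all(col[cl == g] == s), logical(1)))
      if (!full) next
      rows[[length(rows) + 1L]] <- data.frame(
        aln_column = cc,
        ref_position = refpos[cc],
        site_kind = if (states[cc] == "gap") "InDel" else "SNV",
        n_clades = length(carried_clades),
        target_clades = paste(sort(carried_clades), collapse = ","),
        allele = s,
        locus_label = if (is.null(idx)) NA_character_
                      else locus_label(refpos[cc], model, idx),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(aln_column = integer(0), ref_position = integer(0),
                      site_kind = character(0), n_clades = integer(0),
                      target_clades = character(0), allele = character(0),
                      locus_label = character(0)))
  }
  out <- do.call(rbind, rows)
  # prefer singleton clade sets at a column: drop wider sets when a
  # singleton exists for the same column
  keep <- rep(TRUE, nrow(out))
  for (cc in unique(out$aln_column)) {
    at <- which(out$aln_column == cc)
    if (any(out$n_clades[at] == 1L)) {
      keep[at[out$n_clades[at] > 1L]] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$aln_column, out$target_clades), , drop = FALSE]
}

# gene or IGS label of a 0-based reference position
locus_label <- function(pos0, model, idx = NULL) {
  if (is.null(idx)) idx <- genic_context_index(model)
  g <- idx$gene[pos0 + 1L]
  if (!is.na(g)) return(g)
  f <- model$features
  starts <- vapply(f$exons, function(e) min(e[, 1]), integer(1))
  ends <- vapply(f$exons, function(e) max(e[, 2]), integer(1))
  left <- which(ends <= pos0)
  right <- which(starts > pos0)
  left_name <- if (length(left) > 0) f$name[left[which.max(ends[left])]]
               else f$name[which.max(ends)]        # wrap on the circle
  right_name <- if (length(right) > 0) f$name[right[which.min(starts[right])]]
                else f$name[which.min(starts)]
  paste0(left_name, "-", right_name)
}
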