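# Alignment-based variant event calling with the four-way typology:
# SNV, InDel, block substitution (BlockSub), mixed.  A variant event is a
# maximal run of contiguous non-invariant alignment columns; the run's
# column states determine its category:
#   one substitution column            -> SNV
#   >= 2 columns, all substitution     -> BlockSub
#   gap columns only                   -> InDel
#   substitution and gap columns mixed -> Mixed

AMBIG_CHARS <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "U")

#' Construct an alignment matrix
#'
#' @param x character matrix (rows = samples, single characters), a named
#'   character vector of equal-length aligned sequences, or an
#'   `XStringSet`.
#' @param ref_index row used as coordinate reference (default 1).
#' @return object of class `plast_alignment`: the character matrix plus
#'   attributes `ref_index` and `col_to_ref_pos` (0-based reference
#'   position per alignment column; columns that are gaps in the reference
#'   map to the preceding reference position).
#' @export
plast_alignment <- function(x, ref_index = 1L) {
  if (inherits(x, "XStringSet")) x <- as.character(x)
  if (is.character(x) && !is.matrix(x)) {
    if (length(unique(nchar(x))) != 1L) {
      stop("aligned sequences must have equal length", call. = FALSE)
    }
    ids <- if (is.null(names(x))) paste0("s", seq_along(x)) else names(x)
    x <- do.call(rbind, lapply(toupper(x), seq_chars))
    rownames(x) <- ids
  }
  stopifnot(is.matrix(x))
  if (nrow(x) < 2L) stop("alignment needs >= 2 rows", call. = FALSE)
  x[] <- toupper(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  ref <- x[ref_index, ]
  nongap <- ref != "-"
  refpos <- pmax(cumsum(nongap) - 1L, 0L)
  structure(x, class = c("plast_alignment", "matrix"),
            ref_index = as.integer(ref_index),
            col_to_ref_pos = as.integer(refpos))
}

#' Read an alignment from FASTA
#'
#' @param path alignment FASTA.
#' @param ref_index coordinate-reference row.
#' @return a [plast_alignment()].
#' @export
read_alignment <- function(path, ref_index = 1L) {
  plast_alignment(read_fasta(path), ref_index = ref_index)
}

#' Classify alignment columns
#'
#' A column is `gap` if any row holds `-`; `substitution` if it is gap-free
#' with at least two distinct unambiguous states (`A`, `C`, `G`, `T`);
#' otherwise `invariant`.  Columns whose only variation involves `N` or
#' ambiguity codes are invariant.
#'
#' @param aln a [plast_alignment()].
#' @return character vector (one state per column).
#' @export
scan_columns <- function(aln) {
  stopifnot(inherits(aln, "plast_alignment"))
  m <- unclass(aln)
  has_gap <- colSums(m == "-") > 0L
  nstates <- (colSums(m == "A") > 0L) + (colSums(m == "C") > 0L) +
             (colSums(m == "G") > 0L) + (colSums(m == "T") > 0L)
  out <- rep("invariant", ncol(m))
  out[!has_gap & nstates >= 2L] <- "substitution"
  out[has_gap] <- "gap"
  out
}

#' Call merged variant events from an alignment
#'
#' Maximal runs of contiguous non-invariant columns become one event each,
#' classified by the run's column composition (see module header).
#'
#' @param aln a [plast_alignment()].
#' @return data.frame of events in alignment order: `aln_start`, `aln_end`
#'   (0-based half-open columns), `ref_start`, `ref_end` (0-based reference
#'   coordinates of the event span), `category`, `n_alleles`, `alleles`
#'   (comma-separated row substrings over the span).
#' @export
call_variant_events <- function(aln) {
  states <- scan_columns(aln)
  m <- unclass(aln)
  refpos <- attr(aln, "col_to_ref_pos")
  r <- rle(states != "invariant")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  rows <- lapply(keep, function(i) {
    cols <- starts[i]:ends[i]
    st <- states[cols]
    category <- if (all(st == "substitution")) {
      if (length(cols) == 1L) "SNV" else "BlockSub"
    } else if (all(st == "gap")) "InDel" else "Mixed"
    alle <- unique(apply(m[, cols, drop = FALSE], 1L, paste, collapse = ""))
    data.frame(aln_start = cols[1] - 1L, aln_end = cols[length(cols)],
               ref_start = refpos[cols[1]],
               ref_end = refpos[cols[length(cols)]] + 1L,
               category = category,
               n_alleles = length(alle),
               alleles = paste(alle, collapse = ","),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(aln_start = integer(0), aln_end = integer(0),
                      ref_start = integer(0), ref_end = integer(0),
                      category = character(0), n_alleles = integer(0),
                      alleles = character(0)))
  }
  do.call(rbind, rows)
}

#' Annotate events with region, genic context, and gene
#'
#' Region (LSC / SSC / IR) comes from the reference position of the event's
#' first column against the quadripartite partition; context (CDS / intron /
#' IGS) and gene from the genic-context index.  Events spanning a region or
#' context boundary keep their first-column label and are flagged.
#'
#' @param events output of [call_variant_events()].
#' @param part a [detect_quadripartite()] partition, or `NULL`.
#' @param model a [gene_model()], or `NULL`.
#' @return events with added columns `region`, `context`, `gene`,
#'   `boundary_flag`.
#' @export
annotate_events <- function(events, part = NULL, model = NULL) {
  ev <- events
  n <- nrow(ev)
  ev$region <- rep(NA_character_, n)
  ev$context <- rep(NA_character_, n)
  ev$gene <- rep(NA_character_, n)
  ev$boundary_flag <- rep(FALSE, n)
  if (n == 0L) return(ev)
  last0 <- pmax(ev$ref_end - 1L, ev$ref_start)
  if (!is.null(part)) {
    ev$region <- region_of_position(part, ev$ref_start)
    reg_last <- region_of_position(part, last0)
    ev$boundary_flag <- ev$boundary_flag | (ev$region != reg_last)
  }
  if (!is.null(model)) {
    idx <- genic_context_index(model)
    ev$context <- idx$context[ev$ref_start + 1L]
    ev$gene <- idx$gene[ev$ref_start + 1L]
    ctx_last <- idx$context[pmin(last0, model$genome_length - 1L) + 1L]
    ev$boundary_flag <- ev$boundary_flag | (ev$context != ctx_last)
  }
  ev
}

#' Summarize annotated variant events
#'
#' @param events (annotated) event data.frame.
#' @return object of class `variant_summary`: `total`; `by_category`,
#'   `by_region`, `by_context` data.frames with counts and percentages of
#'   the grand total (two decimals); `per_gene` counts by category sorted
#'   by descending total.
#' @export
summarize_variants <- function(events) {
  total <- nrow(events)
  count_table <- function(x, levels) {
    cnt <- table(factor(x, levels = levels))
    data.frame(level = levels, count = as.integer(cnt),
               pct = if (total > 0) round(100 * as.integer(cnt) / total, 2)
                     else rep(0, length(levels)),
               stringsAsFactors = FALSE)
  }
  by_category <- count_table(events$category,
                             c("SNV", "InDel", "BlockSub", "Mixed"))
  regions <- c("LSC", "SSC", "IR")
  contexts <- c("CDS", "intron", "IGS")
  has_region <- total > 0 && !all(is.na(events$region))
  has_context <- total > 0 && !all(is.na(events$context))
  by_region <- if (has_region) count_table(events$region, regions)
               else count_table(character(0), regions)
  by_context <- if (has_context) count_table(events$context, contexts)
                else count_table(character(0), contexts)
  per_gene <- data.frame(gene = character(0))
  if (total > 0 && "gene" %in% names(events) && any(!is.na(events$gene))) {
    sub <- events[!is.na(events$gene), , drop = FALSE]
    tab <- as.data.frame.matrix(table(sub$gene,
      factor(sub$category, levels = c("SNV", "InDel", "BlockSub", "Mixed"))))
    per_gene <- data.frame(gene = rownames(tab), tab,
                           total = rowSums(tab), row.names = NULL,
                           stringsAsFactors = FALSE)
    per_gene <- per_gene[order(-per_gene$total, per_gene$gene), ,
                         drop = FALSE]
    rownames(per_gene) <- NULL
  }
  structure(list(total = total, by_category = by_category,
                 by_region = by_region, by_context = by_context,
                 per_gene = per_gene),
            class = "variant_summary")
}

#' @export
print.variant_summary <- function(x, ...) {
  cat(sprintf("<variant_summary> %d event(s)\n", x$total))
  cat("by category:\n"); print(x$by_category)
  if (sum(x$by_region$count) > 0) { cat("by region:\n"); print(x$by_region) }
  if (sum(x$by_context$count) > 0) {
    cat("by context:\n"); print(x$by_context)
  }
  invisible(x)
}

#' Extract the SNV character matrix
#'
#' Restricts the alignment to gap-free variable (substitution) columns; the
#' input of PCA, Fst and SNV-based haplotyping.
#'
#' @param aln a [plast_alignment()].
#' @return character matrix samples x SNV columns; column names carry the
#'   0-based reference positions.
#' @export
snv_matrix <- function(aln) {
  states <- scan_columns(aln)
  cols <- which(states == "substitution")
  if (length(cols) == 0L) {
    warning("no SNV columns in alignment", call. = FALSE)
  }
  m <- unclass(aln)[, cols, drop = FALSE]
  colnames(m) <- attr(aln, "col_to_ref_pos")[cols]
  m
}

#' Collapse IR-mirrored variant events
#'
#' Both IR copies are distinct alignment loci, so a mutation present in both
#' copies is called twice.  This merges an IRa event with its mirrored IRb
#' partner (same category and mirrored span) and keeps the IRb copy,
#' flagged with `ir_mirrored = TRUE`.
#'
#' @param events annotated events (need `region`).
#' @param part quadripartite partition (canonical coordinates).
#' @return filtered events with added logical column `ir_mirrored`.
#' @export
collapse_ir_events <- function(events, part) {
  ev <- events
  ev$ir_mirrored <- FALSE
  if (nrow(ev) == 0L) return(ev)
  irb <- part$irb; ira <- part$ira
  in_irb <- ev$ref_start >= irb["start"] & ev$ref_start < irb["end"]
  in_ira <- ev$ref_start >= ira["start"] & ev$ref_start < ira["end"]
  # the IR copies read antiparallel: canonical position p in IRa mirrors
  # to irb_start + (ira_end - 1 - p) in IRb
  drop <- rep(FALSE, nrow(ev))
  for (i in which(in_ira)) {
    span <- ev$ref_end[i] - ev$ref_start[i]
    m_start <- irb["start"] + (ira["end"] - 1L - (ev$ref_end[i] - 1L))
    j <- which(in_irb & ev$category == ev$category[i] &
               ev$ref_start == m_start &
               (ev$ref_end - ev$ref_start) == span)
    if (length(j) >= 1L) {
      drop[i] <- TRUE
      ev$ir_mirrored[j[1]] <- TRUE
    }
  }
  ev[!drop, , drop = FALSE]
}
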