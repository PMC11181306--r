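# Gene-annotation handling: GFF3 / GenBank loading, unique-gene counting
# with IR duplicates collapsed, and the genic-context index (CDS / intron /
# IGS) used to partition variants.

GENE_CATEGORIES <- c("PCG", "tRNA", "rRNA")

#' Build a gene model from explicit features
#'
#' @param name gene symbols (character).
#' @param category one of `"PCG"`, `"tRNA"`, `"rRNA"` per gene.
#' @param strand `"+"` or `"-"` per gene.
#' @param exons list of integer matrices, one per gene, columns
#'   `start`, `end` (0-based half-open, canonical rotation).
#' @param trans_spliced logical per gene.
#' @param genome_length genome length in bp.
#' @param partition optional [detect_quadripartite()] partition.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(name, category, strand, exons, trans_spliced,
                       genome_length, partition = NULL) {
  n <- length(name)
  stopifnot(length(category) == n, length(strand) == n,
            length(exons) == n, length(trans_spliced) == n)
  if (n > 0 && !all(category %in% GENE_CATEGORIES)) {
    stop("category must be one of ", paste(GENE_CATEGORIES, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(n)) {
    ex <- exons[[i]]
    stopifnot(is.matrix(ex), ncol(ex) == 2L, nrow(ex) >= 1L)
    if (any(ex[, 1] < 0L) || any(ex[, 2] > genome_length) ||
        any(ex[, 2] <= ex[, 1])) {
      stop("gene '", name[i], "': exon coordinates out of bounds ",
           "[0, ", genome_length, ")", call. = FALSE)
    }
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex[-1L, 1] < ex[-nrow(ex), 2])) {
      stop("gene '", name[i], "': overlapping exons", call. = FALSE)
    }
    colnames(ex) <- c("start", "end")
    exons[[i]] <- ex
  }
  feats <- data.frame(name = as.character(name),
                      category = as.character(category),
                      strand = as.character(strand),
                      trans_spliced = as.logical(trans_spliced),
                      n_exons = vapply(exons, nrow, integer(1)),
                      stringsAsFactors = FALSE)
  feats$exons <- exons
  structure(list(features = feats, genome_length = as.integer(genome_length),
                 partition = partition),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %d feature(s) on %s bp\n", nrow(x$features),
              format(x$genome_length, big.mark = ",")))
  if (nrow(x$features) > 0) {
    print(table(x$features$category))
  }
  invisible(x)
}

#' Load a gene annotation from GFF3 or GenBank flat format
#'
#' GFF3 is parsed with \pkg{rtracklayer}; `gene`, `CDS`, `tRNA` and `rRNA`
#' records are consumed (multi-segment genes via shared gene name), other
#' feature types are skipped with a warning.  A minimal GenBank feature-table
#' reader handles `CDS` / `tRNA` / `rRNA` keys with `join()` /
#' `complement()` locations and `/gene` qualifiers.
#'
#' @param path annotation file.
#' @param genome_length genome length in bp; segment coordinates beyond it
#'   are an error.
#' @param format `"auto"` (by extension/sniffing), `"gff3"`, or
#'   `"genbank"`.
#' @param partition optional partition attached to the model.
#' @return a [gene_model()].
#' @export
load_annotation <- function(path, genome_length,
                            format = c("auto", "gff3", "genbank"),
                            partition = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gb", "gbk", "gbf", "genbank")) "genbank"
              else if (ext %in% c("gff", "gff3")) "gff3"
              else {
        first <- readLines(path, n = 1L)
        if (grepl("^LOCUS", first)) "genbank" else "gff3"
      }
  }
  recs <- if (format == "gff3") parse_gff3_records(path)
          else parse_genbank_records(path)
  build_model_from_records(recs, genome_length, partition)
}

# records: data.frame(name, type, strand, start0, end0, trans_spliced)
# with one row per location segment
parse_gff3_records <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  type <- as.character(df$type)
  keep_types <- c("CDS", "tRNA", "rRNA", "gene", "exon")
  unknown <- setdiff(unique(type), keep_types)
  if (length(unknown) > 0L) {
    warning("skipping unknown feature types: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  df <- df[type %in% c("CDS", "tRNA", "rRNA"), , drop = FALSE]
  getattr <- function(col) if (col %in% names(df)) as.character(df[[col]])
                           else rep(NA_character_, nrow(df))
  name <- getattr("gene")
  alt <- getattr("Name")
  name[is.na(name)] <- alt[is.na(name)]
  par <- getattr("Parent")
  name[is.na(name)] <- sub("^gene[-:]", "", par[is.na(name)])
  if (anyNA(name)) stop("GFF3 records without gene/Name/Parent attribute",
                        call. = FALSE)
  ts <- getattr("trans_spliced")
  exc <- getattr("exception")
  data.frame(name = name,
             type = as.character(df$type),
             strand = as.character(df$strand),
             start0 = df$start - 1L,
             end0 = df$end,
             trans_spliced = (!is.na(ts) & ts == "true") |
                             (!is.na(exc) & exc == "trans-splicing"),
             stringsAsFactors = FALSE)
}

# minimal GenBank flat-file feature table parser
parse_genbank_records <- function(path) {
  lines <- readLines(path)
  fstart <- grep("^FEATURES", lines)
  if (length(fstart) == 0L) stop("not a GenBank flat file: no FEATURES ",
                                 "section", call. = FALSE)
  fend <- grep("^(ORIGIN|CONTIG|//)", lines)
  fend <- fend[fend > fstart[1]][1]
  if (is.na(fend)) fend <- length(lines) + 1L
  block <- lines[(fstart[1] + 1L):(fend - 1L)]
  is_key <- grepl("^ {5}\\S", block)
  idx <- cumsum(is_key)
  feats <- split(block, idx)
  rows <- list()
  for (f in feats) {
    key <- sub("^ {5}(\\S+).*$", "\\1", f[1])
    if (!key %in% c("CDS", "tRNA", "rRNA")) next
    loc <- sub("^ {5}\\S+\\s+", "", f[1])
    i <- 2L
    while (i <= length(f) && !grepl("^\\s+/", f[i])) {
      loc <- paste0(loc, gsub("\\s", "", f[i])); i <- i + 1L
    }
    quals <- f[grepl("^\\s+/", f)]
    gq <- grep("/gene=", quals, value = TRUE)
    name <- if (length(gq) > 0) sub('.*?/gene="?([^"]+)"?.*', "\\1", gq[1])
            else NA_character_
    if (is.na(name)) next
    parsed <- parse_gb_location(loc)
    rows[[length(rows) + 1L]] <- data.frame(
      name = name, type = key, strand = parsed$strand,
      start0 = parsed$segs[, 1], end0 = parsed$segs[, 2],
      trans_spliced = grepl("trans[-_]splicing", paste(quals, collapse = " ")),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(name = character(0), type = character(0),
                      strand = character(0), start0 = integer(0),
                      end0 = integer(0), trans_spliced = logical(0)))
  }
  do.call(rbind, rows)
}

# GenBank location string -> list(segs = matrix start0/end0, strand)
parse_gb_location <- function(loc) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  inner <- gsub("join\\(|complement\\(|order\\(|\\)|<|>", "", loc)
  parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
  segs <- t(vapply(parts, function(p) {
    xy <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    if (length(xy) == 1L) xy <- c(xy, xy)
    c(xy[1] - 1L, xy[2])
  }, integer(2)))
  list(segs = segs, strand = strand)
}

build_model_from_records <- function(recs, genome_length, partition) {
  if (nrow(recs) > 0 && any(recs$end0 > genome_length | recs$start0 < 0)) {
    bad <- recs$name[recs$end0 > genome_length | recs$start0 < 0][1]
    stop("feature '", bad, "' extends beyond genome length ", genome_length,
         call. = FALSE)
  }
  cat_of <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA")
  # one gene copy = one (name, type, contiguous coordinate cluster); IR
  # duplicates of the same gene arrive as widely separated segment groups
  name <- character(0); category <- character(0); strand <- character(0)
  exlist <- list(); ts <- logical(0)
  if (nrow(recs) > 0) {
    recs$grp <- paste(recs$name, recs$type)
    for (g in unique(recs$grp)) {
      sub <- recs[recs$grp == g, , drop = FALSE]
      sub <- sub[order(sub$start0), , drop = FALSE]
      # split segment list into copies: gap > 25% of genome means a
      # separate (IR-duplicated) copy, unless the gene is trans-spliced
      splits <- cumsum(c(1L, as.integer(
        diff(sub$start0) > 0.25 * genome_length & !sub$trans_spliced[1])))
      for (cp in unique(splits)) {
        seg <- sub[splits == cp, , drop = FALSE]
        name <- c(name, seg$name[1])
        category <- c(category, unname(cat_of[seg$type[1]]))
        strand <- c(strand, seg$strand[1])
        ts <- c(ts, seg$trans_spliced[1])
        exlist[[length(exlist) + 1L]] <-
          cbind(start = seg$start0, end = seg$end0)
      }
    }
  }
  gene_model(name, category, strand, exlist, ts, genome_length, partition)
}

# span-based majority region of a feature's exons; partition regions are
# LSC / IR / SSC (the two IR copies pooled)
feature_region <- function(model, rows) {
  part <- model$partition
  vapply(rows, function(i) {
    ex <- model$features$exons[[i]]
    pos <- unlist(lapply(seq_len(nrow(ex)),
                         function(j) ex[j, 1]:(ex[j, 2] - 1L)))
    reg <- region_of_position(part, pos)
    names(which.max(table(reg)))
  }, character(1))
}

#' Count unique genes with IR duplicates counted once
#'
#' Gene copies sharing a (case-insensitive) name are counted as one unique
#' gene.  When a partition is attached, each unique gene is placed in LSC,
#' SSC or IR by majority overlap of all its exon positions.
#'
#' @param model a [gene_model()].
#' @return list with `total`, per-category counts, `per_region` counts and
#'   the per-gene `table` (name, category, n_copies, region).
#' @export
count_unique_genes <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  f <- model$features
  if (nrow(f) == 0L) {
    return(list(total = 0L, PCG = 0L, tRNA = 0L, rRNA = 0L,
                per_region = c(LSC = 0L, SSC = 0L, IR = 0L),
                table = data.frame()))
  }
  key <- tolower(f$name)
  uniq <- !duplicated(key)
  tab <- data.frame(name = f$name[uniq], category = f$category[uniq],
                    n_copies = as.integer(table(key)[key[uniq]]),
                    stringsAsFactors = FALSE)
  if (!is.null(model$partition)) {
    tab$region <- vapply(f$name[uniq], function(nm) {
      rows <- which(key == tolower(nm))
      regs <- feature_region(model, rows)
      names(which.max(table(regs)))
    }, character(1))
  } else {
    tab$region <- NA_character_
  }
  cats <- table(factor(tab$category, levels = GENE_CATEGORIES))
  per_region <- table(factor(tab$region, levels = c("LSC", "SSC", "IR")))
  list(total = nrow(tab),
       PCG = unname(cats["PCG"]), tRNA = unname(cats["tRNA"]),
       rRNA = unname(cats["rRNA"]),
       per_region = c(per_region),
       table = tab)
}

#' Genic-context index over the genome
#'
#' Assigns every genome position to exactly one of `CDS` (exonic, including
#' tRNA/rRNA exons by default), `intron`, or `IGS`, with priority
#' CDS > intron > IGS at overlaps.  For trans-spliced genes only the exons
#' themselves are marked; the (genome-wide) gaps between their segments are
#' not introns.
#'
#' @param model a [gene_model()].
#' @param rna_exon_separate report tRNA/rRNA exons as their own `"RNA"`
#'   bucket instead of folding them into `CDS`.
#' @return list with `context` (character vector, one element per genome
#'   position) and `gene` (gene symbol per position, `NA` in IGS).
#' @export
genic_context_index <- function(model, rna_exon_separate = FALSE) {
  stopifnot(inherits(model, "gene_model"))
  n <- model$genome_length
  context <- rep("IGS", n)
  gene <- rep(NA_character_, n)
  f <- model$features
  # pass 1: introns (lower priority, written first)
  for (i in seq_len(nrow(f))) {
    if (f$trans_spliced[i]) next
    ex <- f$exons[[i]]
    if (nrow(ex) < 2L) next
    for (j in seq_len(nrow(ex) - 1L)) {
      ivl <- (ex[j, 2] + 1L):ex[j + 1L, 1]
      context[ivl] <- "intron"
      gene[ivl] <- f$name[i]
    }
  }
  # pass 2: exons override introns of overlapping genes
  for (i in seq_len(nrow(f))) {
    ex <- f$exons[[i]]
    lab <- if (rna_exon_separate && f$category[i] != "PCG") "RNA" else "CDS"
    for (j in seq_len(nrow(ex))) {
      ivl <- (ex[j, 1] + 1L):ex[j, 2]
      context[ivl] <- lab
      gene[ivl] <- f$name[i]
    }
  }
  list(context = context, gene = gene)
}

#' Genes containing introns
#'
#' @param model a [gene_model()].
#' @return data.frame (name, category, intron_count, trans_spliced) for
#'   genes with at least one intron; intron count of a gene is
#'   `n_exons - 1` of its most exon-rich copy (trans-spliced genes counted
#'   across their segments).
#' @export
list_intron_genes <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  f <- model$features
  if (nrow(f) == 0L) {
    return(data.frame(name = character(0), category = character(0),
                      intron_count = integer(0), trans_spliced = logical(0)))
  }
  key <- tolower(f$name)
  rows <- lapply(unique(key), function(k) {
    sub <- f[key == k, , drop = FALSE]
    if (sub$trans_spliced[1]) {
      # count across all trans-spliced segments (copies hold the segments)
      nex <- sum(sub$n_exons)
    } else {
      nex <- max(sub$n_exons)
    }
    data.frame(name = sub$name[1], category = sub$category[1],
               intron_count = nex - 1L, trans_spliced = sub$trans_spliced[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$intron_count >= 1L, , drop = FALSE]
  rownames(out) <- NULL
  out[order(-out$intron_count, out$name), , drop = FALSE]
}
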