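# Seeded plastome-population simulator.  Emits a quadripartite ancestor
# (LSC + IRb + SSC + IRa with mirrored IRs), a non-overlapping gene model,
# a balanced cluster genealogy, and an alignment with planted variant
# events of all four categories, plus machine-readable truth for every
# downstream stage.  Deletion-only indels keep alignment columns identical
# to ancestor coordinates, so truth bookkeeping is exact; the first
# alignment row is the ancestor and serves as the coordinate reference.

#' Simulation configuration
#'
#' Defaults state a desk-scale analogue of a real pan-plastome panel:
#' a ~158 kb quadripartite genome, 112 unique genes (78 PCG / 30 tRNA /
#' 4 rRNA; 83 LSC, 13 SSC, 16 IR-duplicated), six genetic clusters of
#' uneven size and uneven within-cluster diversity, and planted events in
#' roughly the observed category (2/3 SNV, ~30% InDel) and region
#' (LSC-heavy) proportions.
#'
#' @param seed integer RNG seed; one stream drives all sampling.
#' @param n_clusters number of genetic clusters.
#' @param samples_per_cluster integer vector (length `n_clusters`).
#' @param region_lengths named vector `c(lsc=, ir=, ssc=)` in bp;
#'   `lsc > ssc` required.
#' @param genes list: `per_region_categories` (named list LSC/SSC/IR of
#'   `c(PCG=, tRNA=, rRNA=)` counts; IR genes are duplicated into both
#'   copies but count once), `intron_genes`, `two_intron_genes`.
#' @param events_per_branch named counts `c(SNV=, InDel=, BlockSub=,
#'   Mixed=)` planted on every branch of the cluster tree.
#' @param indel_len,blocksub_len bounded geometric length laws
#'   `list(p=, max=)`; InDel lengths start at 1, BlockSub at 2.
#' @param min_event_spacing minimum invariant columns between planted
#'   events (>= 3 guarantees exact recoverability).
#' @param within_cluster_extra_snvs per-cluster count of private SNVs per
#'   sample (scalar or length `n_clusters`); drives uneven Hd/Pi.
#' @param region_weights,context_weights sampling weights for event
#'   placement across LSC/SSC/IR and IGS/CDS/intron.
#' @param boundary_margin planted events keep this many columns clear of
#'   region boundaries.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_clusters = 6L,
                       samples_per_cluster = c(6L, 12L, 10L, 4L, 4L, 12L),
                       region_lengths = c(lsc = 86200L, ir = 26400L,
                                          ssc = 19000L),
                       genes = list(
                         per_region_categories = list(
                           LSC = c(PCG = 61L, tRNA = 22L, rRNA = 0L),
                           SSC = c(PCG = 12L, tRNA = 1L, rRNA = 0L),
                           IR = c(PCG = 5L, tRNA = 7L, rRNA = 4L)),
                         intron_genes = 18L,
                         two_intron_genes = 3L,
                         len_range = list(PCG = c(200L, 1600L),
                                          tRNA = c(70L, 90L),
                                          rRNA = c(1500L, 2900L))),
                       events_per_branch = c(SNV = 46L, InDel = 20L,
                                             BlockSub = 2L, Mixed = 1L),
                       indel_len = list(p = 0.5, max = 12L),
                       blocksub_len = list(p = 0.5, max = 8L),
                       min_event_spacing = 5L,
                       within_cluster_extra_snvs = c(0L, 2L, 1L, 0L, 0L, 1L),
                       region_weights = c(LSC = 0.695, SSC = 0.236,
                                          IR = 0.069),
                       context_weights = c(IGS = 0.559, CDS = 0.323,
                                           intron = 0.118),
                       boundary_margin = 2L) {
  if (length(within_cluster_extra_snvs) == 1L) {
    within_cluster_extra_snvs <- rep(within_cluster_extra_snvs, n_clusters)
  }
  cfg <- list(seed = as.integer(seed), n_clusters = as.integer(n_clusters),
              samples_per_cluster = as.integer(samples_per_cluster),
              region_lengths = region_lengths, genes = genes,
              events_per_branch = events_per_branch,
              indel_len = indel_len, blocksub_len = blocksub_len,
              min_event_spacing = as.integer(min_event_spacing),
              within_cluster_extra_snvs =
                as.integer(within_cluster_extra_snvs),
              region_weights = region_weights,
              context_weights = context_weights,
              boundary_margin = as.integer(boundary_margin))
  stopifnot(length(cfg$samples_per_cluster) == cfg$n_clusters,
            length(cfg$within_cluster_extra_snvs) == cfg$n_clusters,
            cfg$min_event_spacing >= 3L,
            cfg$region_lengths["lsc"] > cfg$region_lengths["ssc"],
            all(cfg$events_per_branch >= 0L))
  structure(cfg, class = "sim_config")
}

# branches of a balanced rooted binary tree over cluster indices; each
# branch carries the clusters below it
cluster_tree_branches <- function(k) {
  branches <- list()
  descend <- function(set) {
    if (length(set) == 1L) return(invisible(NULL))
    half <- ceiling(length(set) / 2)
    left <- set[seq_len(half)]
    right <- set[-seq_len(half)]
    for (side in list(left, right)) {
      branches[[length(branches) + 1L]] <<- side
      descend(side)
    }
  }
  root <- seq_len(k)
  descend(root)
  branches
}

cluster_tree_newick <- function(k) {
  build <- function(set) {
    if (length(set) == 1L) return(paste0("c", set))
    half <- ceiling(length(set) / 2)
    paste0("(", build(set[seq_len(half)]), ":1,",
           build(set[-seq_len(half)]), ":1)")
  }
  paste0(build(seq_len(k)), ";")
}

rgeom_bounded <- function(p, max, base) {
  min(base + stats::rgeom(1L, p), max)
}

# place `lens` gene lengths in a region [r0, r0+R) (0-based), separated by
# random gaps of at least min_gap; returns 0-based start per gene
place_in_region <- function(r0, R, lens, min_gap = 30L) {
  k <- length(lens)
  if (k == 0L) return(integer(0))
  slack <- R - sum(lens) - (k + 1L) * min_gap
  if (slack < 0L) {
    stop("config infeasible: genes do not fit in region (need ",
         sum(lens) + (k + 1L) * min_gap, " bp, have ", R, ")", call. = FALSE)
  }
  cuts <- sort(sample.int(slack + 1L, k + 1L, replace = TRUE) - 1L)
  extra <- diff(c(0L, cuts))
  gaps <- min_gap + extra[seq_len(k + 1L)]
  starts <- r0 + cumsum(gaps[seq_len(k)]) + cumsum(c(0L, lens[-k]))
  as.integer(starts)
}

# carve 1 or 2 introns into a span [s, e); returns exon matrix
carve_exons <- function(s, e, n_introns, min_exon = 30L, min_intron = 40L) {
  len <- e - s
  need <- (n_introns + 1L) * min_exon + n_introns * min_intron
  if (n_introns == 0L || len < need) {
    return(cbind(start = s, end = e))
  }
  slack <- len - need
  parts <- 2L * n_introns + 1L
  extra <- diff(c(0L, sort(sample.int(slack + 1L, parts, replace = TRUE) -
                             1L)))[seq_len(parts)]
  sizes <- ifelse(seq_len(parts) %% 2L == 1L, min_exon, min_intron) + extra
  sizes[parts] <- sizes[parts] + (len - sum(sizes))
  bounds <- s + cumsum(c(0L, sizes))
  ex <- cbind(start = bounds[seq(1, parts, by = 2)],
              end = bounds[seq(2, parts + 1, by = 2)])
  ex
}

build_sim_genes <- function(cfg) {
  rl <- cfg$region_lengths
  lsc <- as.integer(rl["lsc"]); ir <- as.integer(rl["ir"])
  ssc <- as.integer(rl["ssc"])
  irb0 <- lsc; ssc0 <- lsc + ir; ira0 <- lsc + ir + ssc
  n <- lsc + 2L * ir + ssc
  prc <- cfg$genes$per_region_categories
  lr <- cfg$genes$len_range
  if (is.null(lr)) lr <- list(PCG = c(200L, 1600L), tRNA = c(70L, 90L),
                              rRNA = c(1500L, 2900L))
  gene_len <- function(cat) sample(lr[[cat]][1]:lr[[cat]][2], 1L)
  name <- character(0); category <- character(0); strand <- character(0)
  exlist <- list(); counters <- c(PCG = 0L, tRNA = 0L, rRNA = 0L)
  prefix <- c(PCG = "pcg", tRNA = "trn", rRNA = "rrn")
  region_starts <- c(LSC = 0L, SSC = ssc0, IR = irb0)
  region_sizes <- c(LSC = lsc, SSC = ssc, IR = ir)
  placed <- list()
  for (reg in c("LSC", "SSC", "IR")) {
    cats <- rep(names(prc[[reg]]), times = prc[[reg]])
    if (length(cats) == 0L) next
    cats <- sample(cats)
    lens <- vapply(cats, gene_len, integer(1))
    starts <- place_in_region(region_starts[reg], region_sizes[reg], lens)
    for (i in seq_along(cats)) {
      counters[cats[i]] <- counters[cats[i]] + 1L
      placed[[length(placed) + 1L]] <- list(
        name = sprintf("%s%03d", prefix[cats[i]], counters[cats[i]]),
        category = cats[i], start = starts[i], end = starts[i] + lens[i],
        region = reg)
    }
  }
  # intron allocation: prefer long genes
  spans <- vapply(placed, function(g) g$end - g$start, integer(1))
  eligible <- which(spans >= 300L)
  n_int <- min(cfg$genes$intron_genes, length(eligible))
  intron_idx <- sample(eligible, n_int)
  two_idx <- if (n_int > 0L)
    utils::head(intron_idx[spans[intron_idx] >= 600L],
                cfg$genes$two_intron_genes) else integer(0)
  for (i in seq_along(placed)) {
    g <- placed[[i]]
    n_in <- if (i %in% two_idx) 2L else if (i %in% intron_idx) 1L else 0L
    ex <- carve_exons(g$start, g$end, n_in)
    strand_i <- sample(c("+", "-"), 1L)
    name <- c(name, g$name); category <- c(category, g$category)
    strand <- c(strand, strand_i)
    exlist[[length(exlist) + 1L]] <- ex
    if (g$region == "IR") {  # mirrored copy in IRa
      m_ex <- cbind(start = ira0 + (irb0 + ir) - ex[, 2],
                    end = ira0 + (irb0 + ir) - ex[, 1])
      m_ex <- m_ex[order(m_ex[, 1]), , drop = FALSE]
      name <- c(name, g$name); category <- c(category, g$category)
      strand <- c(strand, if (strand_i == "+") "-" else "+")
      exlist[[length(exlist) + 1L]] <- m_ex
    }
  }
  gene_model(name, category, strand, exlist,
             rep(FALSE, length(name)), genome_length = n)
}

#' Simulate a plastome population with planted truth
#'
#' See [sim_config()] for the stated world.  The same seed yields
#' byte-identical outputs.
#'
#' @param cfg a [sim_config()].
#' @return object of class `plastome_sim`: `ancestor` (string), `model`
#'   ([gene_model()]), `alignment` ([plast_alignment()], first row
#'   `ancestor`), `sequences` (gap-free strings per sample), `clusters`
#'   (data.frame sample_id, cluster), and `truth` (planted `events`
#'   data.frame, `expected_summary`, `tree` newick, region bounds,
#'   `config`).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  rl <- cfg$region_lengths
  lsc <- as.integer(rl["lsc"]); ir <- as.integer(rl["ir"])
  ssc <- as.integer(rl["ssc"])
  n <- lsc + 2L * ir + ssc
  spacing <- cfg$min_event_spacing
  # feasibility: generous per-event footprint bound
  n_branches <- 2L * cfg$n_clusters - 2L
  max_span <- max(cfg$indel_len$max, cfg$blocksub_len$max + 0L,
                  1L + cfg$indel_len$max)
  n_events <- n_branches * sum(cfg$events_per_branch) +
    sum(cfg$within_cluster_extra_snvs * cfg$samples_per_cluster)
  if (n_events * (max_span + 2L * spacing) > 0.6 * n) {
    stop("config infeasible: planted events x spacing exceed genome",
         call. = FALSE)
  }
  # ancestor with mirrored IRs and extension-blocking boundary bases
  lsc_seq <- sample(c("A", "C", "G", "T"), lsc, replace = TRUE)
  irb_seq <- sample(c("A", "C", "G", "T"), ir, replace = TRUE)
  ssc_seq <- sample(c("A", "C", "G", "T"), ssc, replace = TRUE)
  lsc_seq[c(1L, lsc)] <- "A"
  ssc_seq[c(1L, ssc)] <- "A"
  ira_seq <- rev(comp_chars(irb_seq))
  anc <- c(lsc_seq, irb_seq, ssc_seq, ira_seq)
  region <- rep(c("LSC", "IR", "SSC", "IR"), times = c(lsc, ir, ssc, ir))
  model <- build_sim_genes(cfg)
  idx <- genic_context_index(model)
  # sample labels
  clusters <- data.frame(
    sample_id = unlist(lapply(seq_len(cfg$n_clusters), function(i)
      sprintf("c%d_%02d", i, seq_len(cfg$samples_per_cluster[i])))),
    cluster = rep(paste0("c", seq_len(cfg$n_clusters)),
                  times = cfg$samples_per_cluster),
    stringsAsFactors = FALSE)
  cluster_members <- split(clusters$sample_id, clusters$cluster)
  # blocked positions: region boundaries +/- margin, then growing with
  # each planted event
  blocked <- rep(FALSE, n)
  bounds <- cumsum(c(0L, lsc, ir, ssc, ir))
  for (b in bounds) {
    lo <- max(1L, b - cfg$boundary_margin + 1L)
    hi <- min(n, b + cfg$boundary_margin)
    if (lo <= hi) blocked[lo:hi] <- TRUE
  }
  # precomputed (region, context) strata so each draw touches only a pool
  strata <- lapply(names(cfg$region_weights), function(reg) {
    out <- lapply(names(cfg$context_weights), function(ctx)
      which(region == reg & idx$context == ctx))
    names(out) <- names(cfg$context_weights)
    out
  })
  names(strata) <- names(cfg$region_weights)
  region_pool <- lapply(names(cfg$region_weights),
                        function(reg) which(region == reg))
  names(region_pool) <- names(cfg$region_weights)
  draw_position <- function(span) {
    for (try in 1:400) {
      reg <- sample(names(cfg$region_weights), 1L,
                    prob = cfg$region_weights)
      ctx <- sample(names(cfg$context_weights), 1L,
                    prob = cfg$context_weights)
      pool <- strata[[reg]][[ctx]]
      if (try > 200L) pool <- region_pool[[reg]]
      pool <- pool[!blocked[pool]]
      if (length(pool) == 0L) next
      pos <- pool[sample.int(length(pool), 1L)]
      if (pos + span - 1L > n) next
      win <- pos:(pos + span - 1L)
      if (any(blocked[win]) || any(region[win] != reg)) next
      return(pos)
    }
    stop("config infeasible: could not place event after 400 tries",
         call. = FALSE)
  }
  events <- list()
  plant <- function(category, carriers) {
    span <- switch(category,
                   SNV = 1L,
                   InDel = rgeom_bounded(cfg$indel_len$p,
                                         cfg$indel_len$max, 1L),
                   BlockSub = rgeom_bounded(cfg$blocksub_len$p,
                                            cfg$blocksub_len$max, 2L),
                   Mixed = 1L + rgeom_bounded(cfg$indel_len$p,
                                              cfg$indel_len$max, 1L))
    pos <- draw_position(span)
    lo <- max(1L, pos - spacing); hi <- min(n, pos + span - 1L + spacing)
    blocked[lo:hi] <<- TRUE
    win <- pos:(pos + span - 1L)
    alt <- switch(category,
                  SNV = ,
                  BlockSub = vapply(anc[win], function(b)
                    sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                    character(1)),
                  InDel = rep("-", span),
                  Mixed = c(sample(setdiff(c("A", "C", "G", "T"),
                                           anc[win[1]]), 1L),
                            rep("-", span - 1L)))
    events[[length(events) + 1L]] <<- list(
      category = category, start0 = pos - 1L, span = span,
      alt = alt, carriers = carriers)
  }
  branches <- cluster_tree_branches(cfg$n_clusters)
  for (br in branches) {
    carriers <- unlist(cluster_members[paste0("c", br)], use.names = FALSE)
    for (cat in names(cfg$events_per_branch)) {
      for (rep_i in seq_len(cfg$events_per_branch[[cat]])) {
        plant(cat, carriers)
      }
    }
  }
  for (i in seq_len(cfg$n_clusters)) {
    cnt <- cfg$within_cluster_extra_snvs[i]
    if (cnt == 0L) next
    for (sid in cluster_members[[paste0("c", i)]]) {
      for (rep_i in seq_len(cnt)) plant("SNV", sid)
    }
  }
  # build alignment: ancestor row first, then samples
  aln <- matrix(rep(anc, nrow(clusters) + 1L),
                nrow = nrow(clusters) + 1L, byrow = TRUE)
  rownames(aln) <- c("ancestor", clusters$sample_id)
  for (ev in events) {
    rows <- match(ev$carriers, rownames(aln))
    cols <- ev$start0 + seq_len(ev$span)
    aln[rows, cols] <- matrix(rep(ev$alt, each = length(rows)),
                              nrow = length(rows))
  }
  alignment <- plast_alignment(aln, ref_index = 1L)
  # truth tables
  ev_df <- do.call(rbind, lapply(seq_along(events), function(i) {
    ev <- events[[i]]
    data.frame(event_id = i, category = ev$category,
               aln_start = ev$start0, aln_end = ev$start0 + ev$span,
               region = region[ev$start0 + 1L],
               context = idx$context[ev$start0 + 1L],
               gene = ifelse(is.na(idx$gene[ev$start0 + 1L]),
                             NA_character_, idx$gene[ev$start0 + 1L]),
               n_carriers = length(ev$carriers),
               carriers = paste(ev$carriers, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(ev_df)) {
    ev_df <- data.frame(event_id = integer(0), category = character(0),
                        aln_start = integer(0), aln_end = integer(0),
                        region = character(0), context = character(0),
                        gene = character(0), n_carriers = integer(0),
                        carriers = character(0))
  }
  ev_df <- ev_df[order(ev_df$aln_start), , drop = FALSE]
  rownames(ev_df) <- NULL
  expected_summary <- list(
    total = nrow(ev_df),
    by_category = table(factor(ev_df$category,
                               c("SNV", "InDel", "BlockSub", "Mixed"))),
    by_region = table(factor(ev_df$region, c("LSC", "SSC", "IR"))),
    by_context = table(factor(ev_df$context, c("CDS", "intron", "IGS"))))
  seqs <- apply(unclass(alignment), 1L, function(r)
    paste(r[r != "-"], collapse = ""))
  structure(list(
    ancestor = chars_to_seq(anc),
    model = model,
    alignment = alignment,
    sequences = seqs,
    clusters = clusters,
    truth = list(events = ev_df, expected_summary = expected_summary,
                 tree = cluster_tree_newick(cfg$n_clusters),
                 region_lengths = c(lsc = lsc, irb = ir, ssc = ssc,
                                    ira = ir),
                 config = cfg)
  ), class = "plastome_sim")
}

#' @export
print.plastome_sim <- function(x, ...) {
  cat(sprintf("<plastome_sim> %d sample(s) in %d cluster(s), %s bp genome, %d planted event(s)\n",
              nrow(x$clusters), length(unique(x$clusters$cluster)),
              format(nchar(x$ancestor), big.mark = ","),
              nrow(x$truth$events)))
  invisible(x)
}

#' Write simulation outputs to a directory
#'
#' @param sim a [simulate_population()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.  Writes `ancestor.fasta`, `sequences.fasta`,
#'   `alignment.fasta`, `genes.gff3`, `clusters.tsv`, `truth_events.tsv`,
#'   `truth.json`, `tree.nwk`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(c(ancestor = sim$ancestor), file.path(dir, "ancestor.fasta"))
  write_fasta(sim$sequences[setdiff(names(sim$sequences), "ancestor")],
              file.path(dir, "sequences.fasta"))
  aln <- apply(unclass(sim$alignment), 1L, paste, collapse = "")
  write_fasta(aln, file.path(dir, "alignment.fasta"))
  write_gff3(sim$model, file.path(dir, "genes.gff3"))
  write_tsv(sim$clusters, file.path(dir, "clusters.tsv"))
  write_tsv(sim$truth$events, file.path(dir, "truth_events.tsv"))
  writeLines(sim$truth$tree, file.path(dir, "tree.nwk"))
  truth <- sim$truth
  truth$events <- NULL
  truth$expected_summary <- lapply(truth$expected_summary, function(x)
    if (inherits(x, "table")) as.list(x) else x)
  truth$config <- unclass(truth$config)
  write_json_report(truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' Write a gene model as GFF3
#'
#' @param model a [gene_model()].
#' @param path output file.
#' @param seqid sequence identifier for column 1.
#' @export
write_gff3 <- function(model, path, seqid = "plastome") {
  f <- model$features
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", seqid,
                     model$genome_length))
  type_of <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA")
  for (i in seq_len(nrow(f))) {
    ex <- f$exons[[i]]
    attrs <- sprintf("ID=%s.%d;gene=%s", f$name[i], i, f$name[i])
    if (f$trans_spliced[i]) attrs <- paste0(attrs, ";trans_spliced=true")
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, paste(seqid, "panplastome",
                              type_of[f$category[i]],
                              ex[j, 1] + 1L, ex[j, 2], ".", f$strand[i],
                              ".", attrs, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Compare pipeline output against planted truth
#'
#' @param truth `truth` element of a [simulate_population()] result.
#' @param observed_events annotated [call_variant_events()] table from the
#'   same alignment.
#' @param observed_clusters optional named vector of inferred cluster
#'   labels (names = sample ids) to score against the true labels.
#' @return list: `events_match` (logical), `n_planted`, `n_called`,
#'   `mismatches` (data.frame of disagreeing loci), and
#'   `cluster_agreement` (adjusted Rand index, `NA` if labels absent).
#' @export
truth_check <- function(truth, observed_events, observed_clusters = NULL) {
  planted <- truth$events[order(truth$events$aln_start), , drop = FALSE]
  called <- observed_events[order(observed_events$aln_start), , drop = FALSE]
  key_p <- sprintf("%d:%d:%s", planted$aln_start, planted$aln_end,
                   planted$category)
  key_c <- sprintf("%d:%d:%s", called$aln_start, called$aln_end,
                   called$category)
  only_p <- setdiff(key_p, key_c)
  only_c <- setdiff(key_c, key_p)
  mism <- rbind(
    if (length(only_p) > 0)
      data.frame(key = only_p, side = "planted_only") else NULL,
    if (length(only_c) > 0)
      data.frame(key = only_c, side = "called_only") else NULL)
  if (is.null(mism)) mism <- data.frame(key = character(0),
                                        side = character(0))
  ari <- NA_real_
  if (!is.null(observed_clusters)) {
    cl <- truth_cluster_labels(truth)
    common <- intersect(names(observed_clusters), names(cl))
    ari <- adjusted_rand_index(cl[common], observed_clusters[common])
  }
  list(events_match = nrow(mism) == 0L && nrow(planted) == nrow(called),
       n_planted = nrow(planted), n_called = nrow(called),
       mismatches = mism, cluster_agreement = ari)
}

truth_cluster_labels <- function(truth) {
  cfg <- truth$config
  ids <- unlist(lapply(seq_len(cfg$n_clusters), function(i)
    sprintf("c%d_%02d", i, seq_len(cfg$samples_per_cluster[i]))))
  stats::setNames(rep(paste0("c", seq_len(cfg$n_clusters)),
                      times = cfg$samples_per_cluster), ids)
}

#' Cut a tree into k groups
#'
#' Average-linkage clustering of the tree's cophenetic distances, cut at
#' `k`; the stand-in for tree-derived cluster labels.
#'
#' @param tree a `phylo`.
#' @param k number of groups.
#' @return named character vector of group labels per tip.
#' @export
tree_cut_clusters <- function(tree, k) {
  d <- ape::cophenetic.phylo(tree)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  grp <- stats::cutree(hc, k = k)
  stats::setNames(paste0("g", grp), names(grp))
}
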