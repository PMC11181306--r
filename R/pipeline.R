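# End-to-end orchestration: structure -> annotation -> variants -> popgen
# -> network -> markers, on simulated or user-supplied inputs, with one
# consolidated machine-readable report.

#' Pipeline configuration
#'
#' Exactly one of `simulation` or `inputs` must be given.
#'
#' @param simulation a [sim_config()], or `NULL`.
#' @param inputs list of paths (`alignment` required; optional `fasta`,
#'   `annotation`, `clusters`), or `NULL`.
#' @param out_dir output directory for per-stage artifacts (`NULL` = no
#'   files, report only).
#' @param min_ir_len structure-stage IR seed length.
#' @param collapse_ir merge IR-mirrored variant events.
#' @param model distance model for popgen (`"tn93"` or `"p"`).
#' @param snv_only compute Pi on SNV columns only.
#' @param epsilon median-joining relaxation.
#' @param window,step marker-scan window scheme in bp.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, inputs = NULL,
                            out_dir = NULL, min_ir_len = 1000L,
                            collapse_ir = FALSE,
                            model = c("tn93", "p"), snv_only = FALSE,
                            epsilon = 0L, window = 600L, step = 200L) {
  model <- match.arg(model)
  if (is.null(simulation) == is.null(inputs)) {
    stop("specify exactly one of 'simulation' or 'inputs'", call. = FALSE)
  }
  structure(list(simulation = simulation, inputs = inputs,
                 out_dir = out_dir, min_ir_len = as.integer(min_ir_len),
                 collapse_ir = collapse_ir, model = model,
                 snv_only = snv_only, epsilon = as.integer(epsilon),
                 window = as.integer(window), step = as.integer(step)),
            class = "pipeline_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  x <- unclass(cfg)
  x$out_dir <- NULL  # where artifacts land is not part of the analysis
  saveRDS(rapply(x, identity, how = "replace"), tmp, compress = FALSE)
  unname(tools::md5sum(tmp))
}

log_stage <- function(...) message("[panplastome] ", sprintf(...))

#' Run the full pan-plastome pipeline
#'
#' Executes all applicable stages in dependency order.  Stages whose
#' inputs are unavailable (e.g. Fst without a cluster table) are skipped
#' with a logged reason.  The report body is a pure function of
#' (inputs, config): reruns are byte-identical.
#'
#' @param cfg a [pipeline_config()].
#' @return report list (also written as `report.json` under `out_dir`
#'   when set); carries `config_hash` and `seed`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  report <- list(config_hash = config_hash(cfg),
                 seed = if (!is.null(cfg$simulation))
                   cfg$simulation$seed else NA,
                 skipped = list())
  skip <- function(stage, why) {
    log_stage("skipping %s: %s", stage, why)
    report$skipped[[stage]] <<- why
  }
  sim <- NULL; aln <- NULL; model <- NULL; part <- NULL; clusters <- NULL
  structure_seqs <- NULL
  if (!is.null(cfg$simulation)) {
    log_stage("simulating population (seed %d)", cfg$simulation$seed)
    sim <- simulate_population(cfg$simulation)
    aln <- sim$alignment
    model <- sim$model
    clusters <- sim$clusters
    structure_seqs <- c(ancestor = sim$ancestor)
    report$truth <- list(n_events = nrow(sim$truth$events),
                         tree = sim$truth$tree)
  } else {
    ins <- cfg$inputs
    if (is.null(ins$alignment)) stop("inputs$alignment is required",
                                     call. = FALSE)
    aln <- read_alignment(ins$alignment)
    if (!is.null(ins$fasta)) structure_seqs <- read_fasta(ins$fasta)
    if (!is.null(ins$clusters)) {
      clusters <- read_tsv(ins$clusters)
      names(clusters)[1:2] <- c("sample_id", "cluster")
    }
  }
  # ---- structure ----
  if (!is.null(structure_seqs)) {
    log_stage("structure: %d sequence(s)", length(structure_seqs))
    st <- structure_table(structure_seqs, min_ir_len = cfg$min_ir_len)
    part <- detect_quadripartite(
      plastome(structure_seqs[[1]], names(structure_seqs)[1]),
      min_ir_len = cfg$min_ir_len)
    report$structure <- st
  } else skip("structure", "no genome FASTA supplied")
  # ---- annotation ----
  if (!is.null(cfg$inputs$annotation)) {
    ref_len <- max(attr(aln, "col_to_ref_pos")) + 1L
    model <- load_annotation(cfg$inputs$annotation, ref_len,
                             partition = part)
  }
  if (!is.null(model)) {
    if (is.null(model$partition) && !is.null(part)) model$partition <- part
    cnt <- count_unique_genes(model)
    report$annotation <- list(total = cnt$total, PCG = cnt$PCG,
                              tRNA = cnt$tRNA, rRNA = cnt$rRNA,
                              per_region = as.list(cnt$per_region),
                              intron_genes = list_intron_genes(model))
  } else skip("annotation", "no annotation supplied")
  # ---- variants ----
  log_stage("variants: scanning %d columns", ncol(aln))
  events <- call_variant_events(aln)
  events <- annotate_events(events, part, model)
  if (cfg$collapse_ir && !is.null(part)) {
    events <- collapse_ir_events(events, part)
  }
  vsum <- summarize_variants(events)
  report$variants <- list(total = vsum$total,
                          by_category = vsum$by_category,
                          by_region = vsum$by_region,
                          by_context = vsum$by_context,
                          per_gene = utils::head(vsum$per_gene, 25L))
  # ---- popgen ----
  sample_rows <- setdiff(rownames(aln), "ancestor")
  sub <- plast_alignment(unclass(aln)[sample_rows, , drop = FALSE])
  hs <- collapse_haplotypes(sub)
  report$popgen <- list(n_haplotypes = nrow(hs$haplotypes),
                        Hd = haplotype_diversity(hs),
                        Pi = nucleotide_diversity(sub,
                                                  snv_only = cfg$snv_only))
  if (!is.null(clusters)) {
    report$popgen$by_cluster <- diversity_by_cluster(sub, clusters,
                                                     snv_only = cfg$snv_only)
    report$popgen$fst <- fst_matrix(sub, clusters, model = cfg$model)
  } else skip("fst", "no cluster table supplied")
  snv <- suppressWarnings(snv_matrix(sub))
  if (ncol(snv) > 0L && nrow(snv) >= 3L) {
    pca <- pca_coordinates(snv)
    report$popgen$pca_explained <- pca$explained
    hd <- dist_matrix(hs_seqmat(hs), model = "p")
    if (nrow(hd$matrix) >= 3L) {
      tr <- nj_tree(hd)
      report$popgen$nj_newick <- ape::write.tree(tr)
    } else skip("nj", "fewer than 3 haplotypes")
  } else skip("pca", "no SNV columns or fewer than 3 samples")
  # ---- network ----
  net <- if (nrow(hs$haplotypes) > 1L) {
    nw <- median_joining_network(hs, epsilon = cfg$epsilon)
    if (!is.null(clusters)) {
      nw <- annotate_composition(
        nw, data.frame(sample_id = clusters$sample_id,
                       group = clusters$cluster))
    }
    tabs <- network_tables(nw)
    report$network <- list(n_nodes = nrow(tabs$nodes),
                           n_medians = sum(tabs$nodes$is_median),
                           edges = tabs$edges)
    nw
  } else {
    skip("network", "single haplotype")
    NULL
  }
  # ---- markers ----
  # events recomputed on the sample-only alignment so window ranges and
  # event coordinates share one reference frame
  win <- sliding_window_diversity(sub, window = cfg$window, step = cfg$step)
  report$markers <- list(
    top_windows = utils::head(win[order(win$rank), ], 10L))
  if (!is.null(clusters)) {
    diag_sites <- clade_diagnostic_sites(sub, clusters, model = model)
    report$markers$n_diagnostic_sites <- nrow(diag_sites)
    report$markers$diagnostic_sites <- utils::head(diag_sites, 50L)
  } else skip("diagnostic_sites", "no cluster table supplied")
  # ---- artifacts ----
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(sim)) write_simulation(sim, file.path(cfg$out_dir, "sim"))
    if (!is.null(report$structure)) {
      write_tsv(report$structure, file.path(cfg$out_dir, "structure.tsv"))
    }
    write_tsv(events, file.path(cfg$out_dir, "events.tsv"))
    if (!is.null(net)) {
      tabs <- network_tables(net)
      write_tsv(tabs$nodes, file.path(cfg$out_dir, "network_nodes.tsv"))
      write_tsv(tabs$edges, file.path(cfg$out_dir, "network_edges.tsv"))
    }
    write_tsv(win, file.path(cfg$out_dir, "windows.tsv"))
    write_json_report(report, file.path(cfg$out_dir, "report.json"))
  }
  report
}
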