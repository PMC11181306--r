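# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code; no binary fixtures.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# toy quadripartite genome LSC + IRb + SSC + revcomp(IRb); flanking bases
# fixed to "A" so chance single-base extension of the IR match is blocked
# (extension would need the complement, "T")
make_toy_genome <- function(lsc = 500, ir = 120, ssc = 90, seed = 42) {
  set.seed(seed)
  L <- paste0("A", random_dna(lsc - 2), "A")
  R <- random_dna(ir)
  S <- paste0("A", random_dna(ssc - 2), "A")
  g <- paste0(L, R, S, panplastome:::revcomp(R))
  list(seq = g, lsc = L, irb = R, ssc = S,
       lengths = c(lsc = lsc, irb = ir, ssc = ssc, ira = ir))
}

rotate_seq <- function(s, k) {
  n <- nchar(s)
  k <- k %% n
  if (k == 0) return(s)
  paste0(substr(s, k + 1, n), substr(s, 1, k))
}

# shared small simulation world for fast tests
small_sim_config <- function(seed = 1,
                             events_per_branch = c(SNV = 4L, InDel = 2L,
                                                   BlockSub = 1L,
                                                   Mixed = 1L),
                             within = c(1L, 2L, 0L, 0L), ...) {
  sim_config(seed = seed, n_clusters = 4L,
             samples_per_cluster = c(3L, 4L, 3L, 2L),
             region_lengths = c(lsc = 3000L, ir = 700L, ssc = 1200L),
             genes = list(per_region_categories = list(
                            LSC = c(PCG = 3L, tRNA = 2L, rRNA = 0L),
                            SSC = c(PCG = 1L, tRNA = 1L, rRNA = 0L),
                            IR = c(PCG = 1L, tRNA = 0L, rRNA = 1L)),
                          intron_genes = 2L, two_intron_genes = 1L,
                          len_range = list(PCG = c(150L, 300L),
                                           tRNA = c(70L, 90L),
                                           rRNA = c(150L, 250L))),
             events_per_branch = events_per_branch,
             within_cluster_extra_snvs = within, ...)
}

# ---- independent oracles -------------------------------------------------

# Hd oracle: exhaustive enumeration of unordered sample pairs drawn
# without replacement; fraction of pairs with different haplotypes
hd_oracle <- function(counts) {
  labels <- rep(seq_along(counts), times = counts)
  n <- length(labels)
  diff <- 0; tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + 1
      if (labels[i] != labels[j]) diff <- diff + 1
    }
  }
  diff / tot
}

# Pi oracle: mean pairwise p-distance over retained (gap/ambiguity-free)
# columns, written independently of the package internals
pi_oracle <- function(m) {
  ok <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  sub <- m[, ok, drop = FALSE]
  n <- nrow(sub)
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      vals <- c(vals, mean(sub[i, ] != sub[j, ]))
    }
  }
  mean(vals)
}

# TN93 oracle: direct evaluation of the closed form from explicit counts
tn93_oracle <- function(a, b) {
  pool <- c(a, b)
  pa <- mean(pool == "A"); pc <- mean(pool == "C")
  pg <- mean(pool == "G"); pt <- mean(pool == "T")
  pr <- pa + pg; py <- pc + pt
  n <- length(a)
  P1 <- sum((a == "A" & b == "G") | (a == "G" & b == "A")) / n
  P2 <- sum((a == "C" & b == "T") | (a == "T" & b == "C")) / n
  Q <- sum(a != b) / n - P1 - P2
  k1 <- 2 * pa * pg / pr
  k2 <- 2 * pt * pc / py
  k3 <- 2 * (pr * py - pa * pg * py / pr - pt * pc * pr / py)
  -k1 * log(1 - pr * P1 / (2 * pa * pg) - Q / (2 * pr)) -
    k2 * log(1 - py * P2 / (2 * pt * pc) - Q / (2 * py)) -
    k3 * log(1 - Q / (2 * pr * py))
}

# union of all minimum spanning trees by exhaustive enumeration (n <= 7)
msn_oracle_edges <- function(d) {
  n <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ne <- nrow(pairs)
  best_cost <- Inf
  best_sets <- list()
  for (sel in utils::combn(ne, n - 1, simplify = FALSE)) {
    # connectivity check of the n-1 edge subset
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    acyclic <- TRUE
    for (e in sel) {
      ra <- find(pairs[e, 1]); rb <- find(pairs[e, 2])
      if (ra == rb) { acyclic <- FALSE; break }
      parent[ra] <- rb
    }
    if (!acyclic) next
    cost <- sum(d[pairs[sel, , drop = FALSE]])
    if (cost < best_cost - 1e-9) {
      best_cost <- cost
      best_sets <- list(sel)
    } else if (abs(cost - best_cost) <= 1e-9) {
      best_sets[[length(best_sets) + 1]] <- sel
    }
  }
  edges <- unique(do.call(rbind, lapply(best_sets, function(sel)
    pairs[sel, , drop = FALSE])))
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

# haplotype_set built directly from sequences (bypassing an alignment)
make_hs <- function(seqs, members = NULL) {
  if (is.null(members)) {
    members <- lapply(seq_along(seqs), function(i) paste0("s", i))
  }
  hap <- data.frame(haplotype_id = paste0("h", seq_along(seqs)),
                    n_members = lengths(members),
                    sequence = seqs, stringsAsFactors = FALSE)
  hap$members <- members
  structure(list(haplotypes = hap,
                 retained_columns = seq_len(nchar(seqs[1]))),
            class = "haplotype_set")
}
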