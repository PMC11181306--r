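test_that("collapse_haplotypes applies complete deletion and merges", {
  aln <- plast_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  hs <- collapse_haplotypes(aln)
  expect_equal(nrow(hs$haplotypes), 1)
  expect_equal(hs$haplotypes$n_members, 3)
  # two sequences differ only at a column gapped in a third: the column is
  # removed and all three collapse
  aln <- plast_alignment(c(a = "ACGT", b = "ATGT", c = "A-GT"))
  hs <- collapse_haplotypes(aln)
  expect_equal(hs$retained_columns, c(1, 3, 4))
  expect_equal(nrow(hs$haplotypes), 1)
  # all pairwise distinct at retained columns
  aln <- plast_alignment(c(a = "AAAA", b = "AAAC", c = "AACA", d = "ACAA"))
  expect_equal(nrow(collapse_haplotypes(aln)$haplotypes), 4)
  # everything removed
  aln <- plast_alignment(c(a = "-A", b = "A-"))
  expect_error(collapse_haplotypes(aln), "no informative sites")
})

test_that("haplotype diversity matches the exhaustive pair oracle", {
  expect_equal(haplotype_diversity(c(4)), 0)
  expect_equal(haplotype_diversity(c(1, 1, 1, 1)), 1)
  expect_equal(haplotype_diversity(c(5, 3, 2)), 31 / 45)
  expect_equal(haplotype_diversity(c(5, 3, 2)), hd_oracle(c(5, 3, 2)))
  set.seed(31)
  for (i in 1:20) {
    counts <- sample(1:6, sample(2:5, 1), replace = TRUE)
    expect_equal(haplotype_diversity(counts), hd_oracle(counts))
  }
  expect_error(haplotype_diversity(c(1)), "n >= 2")
})

test_that("nucleotide diversity equals mean pairwise p-distance", {
  a <- strrep("A", 10)
  b <- paste0(strrep("A", 9), "C")
  expect_equal(nucleotide_diversity(plast_alignment(c(a = a, b = b))), 0.1)
  expect_equal(nucleotide_diversity(plast_alignment(c(a = a, b = a))), 0)
  # pairwise differences (1, 2, 3) over 100 columns -> 0.02
  base <- strrep("A", 100)
  s2 <- base; substr(s2, 1, 1) <- "C"
  s3 <- base; substr(s3, 2, 2) <- "G"; substr(s3, 3, 3) <- "G"
  aln <- plast_alignment(c(x = base, y = s2, z = s3))
  expect_equal(nucleotide_diversity(aln), 0.02)
  # oracle equivalence and relabeling invariance on random alignments
  set.seed(17)
  for (i in 1:5) {
    m <- matrix(sample(c("A", "C", "G", "T", "-"), 10 * 200,
                       replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
                nrow = 10)
    rownames(m) <- paste0("s", 1:10)
    aln <- plast_alignment(m)
    expect_equal(nucleotide_diversity(aln), pi_oracle(m))
    perm <- m[sample(10), , drop = FALSE]
    expect_equal(nucleotide_diversity(plast_alignment(perm)),
                 nucleotide_diversity(aln))
  }
})

test_that("TN93 distance matches the closed form and its limits", {
  expect_equal(tn93_distance("ACGT", "ACGT"), 0)
  # saturated purine transitions raise the defined error
  expect_error(tn93_distance(strrep("A", 50), strrep("G", 50)),
               class = "tn93_saturation")
  # frozen worked example: 100 sites, 5 A<->G, 5 C<->T, 10 transversions,
  # symmetric substitutions keep pooled base frequencies equal
  a <- rep(c("A", "C", "G", "T"), each = 25)
  b <- a
  b[1:5] <- "G";  b[26:30] <- "T"           # 5 purine, 5 pyrimidine ts
  b[51:55] <- "A"; b[76:80] <- "C"          # symmetric back-substitutions
  b[6:10] <- "C";  b[31:35] <- "A"          # transversions (symmetric)
  b[56:60] <- "T"; b[81:85] <- "G"
  d <- tn93_distance(a, b)
  expect_equal(d, tn93_oracle(a, b), tolerance = 1e-12)
  expect_equal(d, 0.58585177, tolerance = 1e-6)  # frozen from the oracle
  # TN93 >= p-distance on mildly diverged random pairs
  set.seed(8)
  for (i in 1:10) {
    x <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
    y <- x
    mut <- sample(300, 15)
    y[mut] <- vapply(y[mut], function(z)
      sample(setdiff(c("A", "C", "G", "T"), z), 1), character(1))
    expect_gte(tn93_distance(x, y) + 1e-12, p_distance(x, y))
  }
})

test_that("TN93 collapses to Jukes-Cantor in the uniform-rate limit", {
  # equal pooled frequencies with P1 = P2 = Q/4: every unordered
  # substitution pair equiprobable, the regime where TN93 reduces to JC
  a <- rep(c("A", "C", "G", "T"), each = 50)
  b <- a
  b[1:5] <- "G";  b[101:105] <- "A"       # P1 = 10/200
  b[51:55] <- "T"; b[151:155] <- "C"      # P2 = 10/200
  b[6:15] <- "C"; b[56:65] <- "A"         # Q  = 40/200, symmetric
  b[106:115] <- "T"; b[156:165] <- "G"
  p <- mean(a != b)
  expect_equal(p, 0.3)
  jc <- -(3 / 4) * log(1 - 4 * p / 3)
  expect_equal(tn93_distance(a, b), jc, tolerance = 1e-9)
})

test_that("dist_matrix is symmetric with zero diagonal", {
  set.seed(4)
  seqs <- vapply(1:4, function(i) random_dna(200), character(1))
  names(seqs) <- paste0("s", 1:4)
  dm <- dist_matrix(seqs, model = "p")
  expect_true(isSymmetric(dm$matrix))
  expect_true(all(diag(dm$matrix) == 0))
  bad <- matrix(c(0, 1, 2, 3, 0, 1, 2, 2, 0), 3, 3)
  expect_error(nj_tree(bad), "symmetric")
})

test_that("pairwise Fst boundary cases and arithmetic", {
  # two monomorphic clusters fixed for different haplotypes -> exactly 1
  hapA <- strrep("A", 30)
  hapB <- paste0(strrep("A", 10), strrep("C", 20))
  aln <- plast_alignment(c(a1 = hapA, a2 = hapA, b1 = hapB, b2 = hapB))
  expect_equal(as.numeric(pairwise_fst(aln, c("a1", "a2"), c("b1", "b2"),
                                       model = "p")), 1)
  # both clusters drawn from one pool of identical sequences -> NA
  aln <- plast_alignment(c(a1 = hapA, a2 = hapA, b1 = hapA, b2 = hapA))
  expect_true(is.na(suppressWarnings(
    pairwise_fst(aln, c("a1", "a2"), c("b1", "b2"), model = "p"))))
  # derived arithmetic: within means 0.01 each, between mean 0.03
  base <- strrep("A", 100)
  a2 <- base; substr(a2, 1, 1) <- "C"
  bb <- base; substr(bb, 5, 6) <- "CC"
  b2 <- bb; substr(b2, 2, 2) <- "C"
  aln <- plast_alignment(c(a1 = base, a2 = a2, b1 = bb, b2 = b2))
  snv_cols <- ncol(snv_matrix(aln))   # 4 variable columns
  hw <- (1 / snv_cols + 1 / snv_cols) / 2
  hb <- mean(c(2, 3, 3, 4) / snv_cols)
  expect_equal(as.numeric(pairwise_fst(aln, c("a1", "a2"),
                                       c("b1", "b2"), model = "p")),
               1 - hw / hb)
})

test_that("PCA separates two groups and respects its conventions", {
  g1 <- strrep("A", 20)
  g2 <- paste0(strrep("C", 5), strrep("A", 15))
  aln <- plast_alignment(c(x1 = g1, x2 = g1, x3 = g1,
                           y1 = g2, y2 = g2, y3 = g2))
  pca <- pca_coordinates(snv_matrix(aln))
  pc1 <- pca$coords[, 1]
  expect_equal(stats::sd(pc1[1:3]), 0)
  expect_equal(stats::sd(pc1[4:6]), 0)
  expect_true(abs(mean(pc1[1:3]) - mean(pc1[4:6])) > 0)
  expect_equal(colMeans(pca$coords), rep(0, ncol(pca$coords)),
               ignore_attr = TRUE)
  expect_true(all(diff(pca$explained) <= 1e-12))
  expect_lte(sum(pca$explained), 1 + 1e-12)
  mono <- matrix("A", 3, 2, dimnames = list(paste0("s", 1:3), NULL))
  expect_error(pca_coordinates(mono), "zero-variance")
})

test_that("neighbor joining solves 3 taxa exactly and recovers additivity", {
  m <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(m)
  # three-point closed form: da = (dab + dac - dbc)/2 etc.
  el <- stats::setNames(tr$edge.length[order(tr$edge[, 2])][1:3],
                        tr$tip.label)
  expect_equal(el[["a"]], 1)
  expect_equal(el[["b"]], 2)
  expect_equal(el[["c"]], 4)
  # additive 4-taxon matrix from a known tree is reproduced exactly
  tree <- ape::read.tree(text = "((a:1,b:2):1.5,(c:0.5,d:3):1);")
  d <- ape::cophenetic.phylo(tree)
  out <- nj_tree(d)
  expect_equal(ape::cophenetic.phylo(out)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
  expect_equal(ape::dist.topo(ape::unroot(tree), out), 0,
               ignore_attr = TRUE)
})

test_that("per-cluster diversity table is coherent", {
  cfg <- small_sim_config(seed = 3)
  sim <- simulate_population(cfg)
  sub <- plast_alignment(unclass(sim$alignment)[sim$clusters$sample_id, ])
  tab <- diversity_by_cluster(sub, sim$clusters)
  expect_equal(tab$cluster, paste0("c", 1:4))
  expect_equal(tab$n, c(3, 4, 3, 2))
  expect_true(all(tab$Hd >= 0 & tab$Hd <= 1, na.rm = TRUE))
  expect_true(all(tab$Pi >= 0, na.rm = TRUE))
  expect_true(all((tab$h == 1) == (tab$Hd == 0), na.rm = TRUE))
})
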