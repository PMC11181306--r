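test_that("zero planted events yield sequences identical to the ancestor", {
  cfg <- small_sim_config(seed = 2,
                          events_per_branch = c(SNV = 0L, InDel = 0L,
                                                BlockSub = 0L, Mixed = 0L),
                          within = c(0L, 0L, 0L, 0L))
  sim <- simulate_population(cfg)
  expect_equal(nrow(sim$truth$events), 0)
  expect_true(all(sim$sequences == sim$ancestor))
  expect_equal(nrow(call_variant_events(sim$alignment)), 0)
})

test_that("the same seed reproduces byte-identical outputs", {
  cfg <- small_sim_config(seed = 33)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(s1$ancestor, s2$ancestor)
  expect_identical(s1$truth$events, s2$truth$events)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(s1, d1); write_simulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the panel
  s3 <- simulate_population(small_sim_config(seed = 34))
  expect_false(identical(s1$sequences, s3$sequences))
})

test_that("planted counts appear in truth and are recovered exactly", {
  # one branch tree (2 clusters) planting (10, 5, 2, 1) per branch
  cfg <- sim_config(seed = 5, n_clusters = 2L,
                    samples_per_cluster = c(3L, 3L),
                    region_lengths = c(lsc = 3000L, ir = 700L, ssc = 1200L),
                    genes = list(per_region_categories = list(
                                   LSC = c(PCG = 2L, tRNA = 1L, rRNA = 0L),
                                   SSC = c(PCG = 1L, tRNA = 0L, rRNA = 0L),
                                   IR = c(PCG = 1L, tRNA = 0L, rRNA = 0L)),
                                 intron_genes = 1L, two_intron_genes = 0L,
                                 len_range = list(PCG = c(150L, 300L),
                                                  tRNA = c(70L, 90L),
                                                  rRNA = c(150L, 250L))),
                    events_per_branch = c(SNV = 5L, InDel = 3L,
                                          BlockSub = 1L, Mixed = 1L),
                    within_cluster_extra_snvs = c(0L, 0L))
  sim <- simulate_population(cfg)
  # 2 branches x (5,3,1,1)
  expect_equal(unname(c(sim$truth$expected_summary$by_category)),
               c(10, 6, 2, 2))
  ev <- call_variant_events(sim$alignment)
  tc <- truth_check(sim$truth, ev)
  expect_true(tc$events_match)
  expect_equal(tc$n_called, nrow(sim$truth$events))
  # called categories/spans equal planted ones exactly
  expect_equal(ev$category, sim$truth$events$category)
  expect_equal(ev$aln_start, sim$truth$events$aln_start)
  expect_equal(ev$aln_end, sim$truth$events$aln_end)
  # SNV-matrix column count equals planted SNV + BlockSub + Mixed
  # substitution columns
  planted_sub_cols <- sum(sim$truth$events$category == "SNV") +
    sum((sim$truth$events$aln_end -
           sim$truth$events$aln_start)[sim$truth$events$category ==
                                         "BlockSub"]) +
    sum(sim$truth$events$category == "Mixed")
  expect_equal(ncol(snv_matrix(sim$alignment)), planted_sub_cols)
})

test_that("extra within-cluster SNVs raise Hd and Pi", {
  cfg <- small_sim_config(seed = 11, within = c(0L, 2L, 0L, 0L))
  sim <- simulate_population(cfg)
  sub <- plast_alignment(unclass(sim$alignment)[sim$clusters$sample_id, ])
  tab <- diversity_by_cluster(sub, sim$clusters)
  expect_gt(tab$Hd[tab$cluster == "c2"], tab$Hd[tab$cluster == "c1"])
  expect_gt(tab$Pi[tab$cluster == "c2"], tab$Pi[tab$cluster == "c1"])
})

test_that("fully diverged fixed clusters give Fst exactly 1", {
  cfg <- sim_config(seed = 13, n_clusters = 2L,
                    samples_per_cluster = c(4L, 4L),
                    region_lengths = c(lsc = 3000L, ir = 700L,
                                       ssc = 1200L),
                    genes = list(per_region_categories = list(
                                   LSC = c(PCG = 2L, tRNA = 0L, rRNA = 0L),
                                   SSC = c(PCG = 1L, tRNA = 0L, rRNA = 0L),
                                   IR = c(PCG = 0L, tRNA = 0L, rRNA = 0L)),
                                 intron_genes = 1L, two_intron_genes = 0L,
                                 len_range = list(PCG = c(150L, 300L),
                                                  tRNA = c(70L, 90L),
                                                  rRNA = c(150L, 250L))),
                    events_per_branch = c(SNV = 12L, InDel = 0L,
                                          BlockSub = 0L, Mixed = 0L),
                    within_cluster_extra_snvs = c(0L, 0L))
  sim <- simulate_population(cfg)
  sub <- plast_alignment(unclass(sim$alignment)[sim$clusters$sample_id, ])
  # 24 fixed SNVs, no internal variation
  fst <- pairwise_fst(sub, sim$clusters$sample_id[1:4],
                      sim$clusters$sample_id[5:8], model = "p")
  expect_identical(as.numeric(fst), 1)
})

test_that("truth_check flags injected faults and scores clusterings", {
  cfg <- small_sim_config(seed = 19)
  sim <- simulate_population(cfg)
  ev <- call_variant_events(sim$alignment)
  corrupted <- ev
  corrupted$category[1] <- if (ev$category[1] == "SNV") "InDel" else "SNV"
  tc <- truth_check(sim$truth, corrupted)
  expect_false(tc$events_match)
  expect_equal(nrow(tc$mismatches), 2)  # one planted-only + one called-only
  # label-invariance of the cluster agreement
  truth_labels <- panplastome:::truth_cluster_labels(sim$truth)
  relabeled <- stats::setNames(paste0("grp_", truth_labels),
                               names(truth_labels))
  tc2 <- truth_check(sim$truth, ev, observed_clusters = relabeled)
  expect_equal(tc2$cluster_agreement, 1)
})

test_that("cluster labels are recoverable from the NJ tree", {
  cfg <- small_sim_config(seed = 23, within = c(0L, 0L, 0L, 0L))
  sim <- simulate_population(cfg)
  sub <- plast_alignment(unclass(sim$alignment)[sim$clusters$sample_id, ])
  dm <- dist_matrix(unclass(sub), model = "p")
  tr <- nj_tree(dm)
  cut <- tree_cut_clusters(tr, k = 4)
  tc <- truth_check(sim$truth, call_variant_events(sim$alignment),
                    observed_clusters = cut)
  expect_equal(tc$cluster_agreement, 1)
})

test_that("infeasible configurations error before generation", {
  expect_error(
    small_sim_config(seed = 1,
                     events_per_branch = c(SNV = 500L, InDel = 100L,
                                           BlockSub = 50L, Mixed = 50L)) |>
      simulate_population(),
    "infeasible")
})
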