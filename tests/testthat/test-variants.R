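test_that("scan_columns classifies gap, substitution and invariant", {
  aln <- plast_alignment(c(a = "AAGA-CN",
                           b = "AAAAACN",
                           c = "ACAA-CN"))
  expect_equal(scan_columns(aln),
               c("invariant", "substitution", "substitution", "invariant",
                 "gap", "invariant", "invariant"))
  # variation only through N / ambiguity is invariant
  aln2 <- plast_alignment(c(a = "ANR", b = "AAA", c = "ACA"))
  expect_equal(scan_columns(aln2),
               c("invariant", "substitution", "invariant"))
})

test_that("call_variant_events applies the four-way typology", {
  # single differing column -> SNV
  ev <- call_variant_events(plast_alignment(c(a = "ACGT", b = "ACAT")))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$category, "SNV")
  expect_equal(ev$aln_start, 2)
  expect_equal(ev$aln_end, 3)
  # two contiguous substituted columns -> one BlockSub
  ev <- call_variant_events(plast_alignment(c(a = "AAGGAA", b = "AATTAA")))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$category, "BlockSub")
  expect_equal(ev$aln_end - ev$aln_start, 2)
  # contiguous gap run -> one InDel spanning 3 columns
  ev <- call_variant_events(plast_alignment(c(a = "AAATTTAAA",
                                              b = "AAA---AAA")))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$category, "InDel")
  expect_equal(ev$aln_end - ev$aln_start, 3)
  # adjacent substitution + gap columns -> one Mixed event
  ev <- call_variant_events(plast_alignment(c(a = "AAGTCAA",
                                              b = "AAT-CAA")))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$category, "Mixed")
  # multi-allelic substitution column is one SNV
  ev <- call_variant_events(plast_alignment(c(a = "AACA", b = "AAGA",
                                              c = "AATA")))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$category, "SNV")
  expect_equal(ev$n_alleles, 3)
})

test_that("events are disjoint, ordered, and row-permutation invariant", {
  cfg <- small_sim_config(seed = 21)
  sim <- simulate_population(cfg)
  ev <- call_variant_events(sim$alignment)
  expect_true(all(diff(ev$aln_start) > 0))
  # separated by >= 1 invariant column
  expect_true(all(ev$aln_start[-1] - ev$aln_end[-nrow(ev)] >= 1))
  m <- unclass(sim$alignment)
  perm <- sample(nrow(m))
  ev2 <- call_variant_events(plast_alignment(m[perm, , drop = FALSE],
                                             ref_index = which(perm == 1)))
  expect_equal(ev2[c("aln_start", "aln_end", "category")],
               ev[c("aln_start", "aln_end", "category")])
})

test_that("reference coordinates account for reference gaps", {
  aln <- plast_alignment(c(ref = "AC--GT", alt = "ACTTGT"))
  expect_equal(attr(aln, "col_to_ref_pos"), c(0, 1, 1, 1, 2, 3))
  ev <- call_variant_events(aln)
  expect_equal(ev$category, "InDel")
  expect_equal(ev$ref_start, 1)
})

test_that("annotate_events assigns region, context and gene", {
  toy <- make_toy_genome(500, 120, 90)
  part <- detect_quadripartite(toy$seq, min_ir_len = 100)
  model <- gene_model(c("gA", "gB"), c("PCG", "PCG"), c("+", "+"),
                      list(cbind(c(50L, 120L), c(100L, 160L)),
                           cbind(630L, 700L)),
                      c(FALSE, FALSE), 830L, partition = part)
  s <- part$sequence
  mut <- function(pos0, base) {
    x <- s
    substr(x, pos0 + 1, pos0 + 1) <- base
    x
  }
  flip <- function(b) c(A = "C", C = "A", G = "T", T = "G")[b]
  b60 <- substr(s, 61, 61)    # inside gA exon (LSC)
  b110 <- substr(s, 111, 111) # gA intron
  b300 <- substr(s, 301, 301) # LSC IGS
  b650 <- substr(s, 651, 651) # gB exon in SSC
  aln <- plast_alignment(c(r = s, q = mut(60, flip(b60)),
                           w = mut(110, flip(b110)),
                           x = mut(300, flip(b300)),
                           y = mut(650, flip(b650))))
  ev <- annotate_events(call_variant_events(aln), part, model)
  expect_equal(nrow(ev), 4)
  expect_equal(ev$region, c("LSC", "LSC", "LSC", "SSC"))
  expect_equal(ev$context, c("CDS", "intron", "IGS", "CDS"))
  expect_equal(ev$gene, c("gA", "gA", NA, "gB"))
  # without partition/model the labels stay unset
  ev0 <- annotate_events(call_variant_events(aln))
  expect_true(all(is.na(ev0$region)))
})

test_that("summarize_variants totals and percentages are coherent", {
  ev <- data.frame(
    category = c(rep("SNV", 10), rep("InDel", 5), rep("BlockSub", 2),
                 "Mixed"),
    region = c(rep("LSC", 12), rep("SSC", 4), rep("IR", 2)),
    context = c(rep("IGS", 9), rep("CDS", 6), rep("intron", 3)),
    gene = NA_character_)
  s <- summarize_variants(ev)
  expect_equal(s$total, 18)
  expect_equal(s$by_category$count, c(10, 5, 2, 1))
  expect_equal(sum(s$by_category$count), s$total)
  expect_equal(sum(s$by_region$count), s$total)
  expect_equal(sum(s$by_context$count), s$total)
  expect_equal(s$by_category$pct[1], round(100 * 10 / 18, 2))
  empty <- summarize_variants(ev[0, ])
  expect_equal(empty$total, 0)
  expect_true(all(empty$by_category$count == 0))
})

test_that("snv_matrix keeps exactly the substitution columns", {
  aln <- plast_alignment(c(a = "AAGA-C", b = "ACAAAC", c = "ACAA-C"))
  m <- snv_matrix(aln)
  expect_equal(ncol(m), 2)
  expect_equal(colnames(m), c("1", "2"))
  mono <- plast_alignment(c(a = "AAAA", b = "AAAA"))
  expect_warning(m0 <- snv_matrix(mono), "no SNV")
  expect_equal(ncol(m0), 0)
})

test_that("IR-mirrored events can be collapsed", {
  toy <- make_toy_genome(500, 120, 90)
  part <- detect_quadripartite(toy$seq, min_ir_len = 100)
  s <- part$sequence
  p <- 530L  # inside IRb
  q <- part$irb[["start"]] + (part$ira[["end"]] - 1L - p)  # IRa mirror
  x <- s
  for (pos in c(p, q)) {
    old <- substr(x, pos + 1, pos + 1)
    substr(x, pos + 1, pos + 1) <- c(A = "C", C = "A", G = "T",
                                     T = "G")[old]
  }
  aln <- plast_alignment(c(r = s, m = x))
  ev <- annotate_events(call_variant_events(aln), part, NULL)
  expect_equal(nrow(ev), 2)
  expect_true(all(ev$region == "IR"))
  coll <- collapse_ir_events(ev, part)
  expect_equal(nrow(coll), 1)
  expect_true(coll$ir_mirrored)
})
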