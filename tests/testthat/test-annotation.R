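# a small in-code gene model over a 830 bp toy genome with a known
# quadripartite partition (LSC 500, IRb 120, SSC 90, IRa 120)
toy_model <- function(part = NULL) {
  gene_model(
    name = c("pcgA", "pcgB", "pcgC", "trnX", "rrnZ", "rrnZ"),
    category = c("PCG", "PCG", "PCG", "tRNA", "rRNA", "rRNA"),
    strand = c("+", "-", "+", "+", "+", "-"),
    exons = list(cbind(10L, 100L),                      # LSC, no intron
                 cbind(c(150L, 260L), c(200L, 320L)),   # LSC, 1 intron
                 cbind(c(350L, 420L, 460L), c(400L, 440L, 490L)),  # 2 introns
                 cbind(640L, 700L),                     # SSC
                 cbind(520L, 600L),                     # IRb copy
                 cbind(730L, 810L)),                    # IRa copy
    trans_spliced = rep(FALSE, 6),
    genome_length = 830L, partition = part)
}

toy_part <- function() {
  detect_quadripartite(make_toy_genome(500, 120, 90)$seq, min_ir_len = 100)
}

test_that("gene_model validates coordinates and exon order", {
  expect_error(gene_model("g", "PCG", "+", list(cbind(10L, 900L)),
                          FALSE, 830L), "out of bounds")
  expect_error(gene_model("g", "PCG", "+",
                          list(cbind(c(10L, 40L), c(60L, 90L))),
                          FALSE, 830L), "overlapping")
  expect_error(gene_model("g", "gene", "+", list(cbind(1L, 5L)),
                          FALSE, 830L), "category")
})

test_that("GFF3 loading builds features with exons and introns", {
  gff <- c("##gff-version 3",
           "chr\tsrc\tCDS\t151\t200\t.\t+\t.\tID=x1;gene=pcgB",
           "chr\tsrc\tCDS\t261\t320\t.\t+\t.\tID=x1;gene=pcgB",
           "chr\tsrc\ttRNA\t641\t700\t.\t+\t.\tID=t1;gene=trnX",
           "chr\tsrc\trepeat_region\t1\t5\t.\t+\t.\tID=r1")
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, path)
  expect_warning(model <- load_annotation(path, 830L), "unknown feature")
  f <- model$features
  expect_equal(nrow(f), 2)
  pcg <- f[f$name == "pcgB", ]
  expect_equal(pcg$category, "PCG")
  expect_equal(pcg$n_exons, 2L)
  expect_equal(f$category[f$name == "trnX"], "tRNA")
  expect_equal(f$exons[f$name == "pcgB"][[1]][, "start"], c(150, 260))
  # coordinates beyond the genome are an error
  writeLines(c("##gff-version 3",
               "chr\tsrc\tCDS\t100\t900\t.\t+\t.\tID=y;gene=far"), path)
  expect_error(load_annotation(path, 830L), "beyond genome length")
})

test_that("GenBank flat files parse joins, complements and categories", {
  gb <- c("LOCUS       toy 830 bp DNA circular",
          "FEATURES             Location/Qualifiers",
          "     CDS             join(151..200,261..320)",
          '                     /gene="pcgB"',
          "     tRNA            complement(641..700)",
          '                     /gene="trnX"',
          "     rRNA            521..600",
          '                     /gene="rrnZ"',
          "ORIGIN",
          "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  model <- load_annotation(path, 830L)
  f <- model$features
  expect_equal(sort(f$name), c("pcgB", "rrnZ", "trnX"))
  expect_equal(f$strand[f$name == "trnX"], "-")
  expect_equal(f$category[f$name == "trnX"], "tRNA")
  expect_equal(f$n_exons[f$name == "pcgB"], 2L)
  expect_equal(f$exons[f$name == "pcgB"][[1]][1, ], c(start = 150, end = 200))
})

test_that("unique-gene counting collapses IR duplicates and places genes", {
  model <- toy_model(toy_part())
  cnt <- count_unique_genes(model)
  expect_equal(cnt$total, 5L)
  expect_equal(cnt$PCG, 3L)
  expect_equal(cnt$tRNA, 1L)
  expect_equal(cnt$rRNA, 1L)
  expect_equal(unname(cnt$per_region), c(3L, 1L, 1L))
  expect_equal(cnt$table$region[cnt$table$name == "rrnZ"], "IR")
  expect_equal(cnt$table$n_copies[cnt$table$name == "rrnZ"], 2L)
  # idempotence: counting twice gives the same totals
  expect_identical(count_unique_genes(model)[1:4], cnt[1:4])
  # empty model
  empty <- gene_model(character(0), character(0), character(0), list(),
                      logical(0), 830L)
  expect_equal(count_unique_genes(empty)$total, 0L)
})

test_that("genic context index partitions every position exactly once", {
  model <- toy_model()
  idx <- genic_context_index(model)
  expect_length(idx$context, 830L)
  expect_true(all(idx$context %in% c("CDS", "intron", "IGS")))
  tab <- table(idx$context)
  expect_equal(sum(tab), 830)
  # 0-based position p maps to element p + 1
  expect_equal(idx$context[10 + 1], "CDS")     # inside single-exon gene
  expect_equal(idx$context[220 + 1], "intron") # between pcgB exons
  expect_equal(idx$context[120 + 1], "IGS")    # between genes
  expect_equal(idx$gene[220 + 1], "pcgB")
  expect_true(is.na(idx$gene[120 + 1]))
  # RNA exons fold into CDS by default, separate bucket on request
  expect_equal(idx$context[650 + 1], "CDS")
  idx2 <- genic_context_index(model, rna_exon_separate = TRUE)
  expect_equal(idx2$context[650 + 1], "RNA")
})

test_that("intron genes are listed with counts", {
  model <- toy_model()
  tab <- list_intron_genes(model)
  expect_equal(sort(tab$name), c("pcgB", "pcgC"))
  expect_equal(tab$intron_count[tab$name == "pcgB"], 1L)
  expect_equal(tab$intron_count[tab$name == "pcgC"], 2L)
  no_introns <- gene_model("g", "PCG", "+", list(cbind(1L, 50L)),
                           FALSE, 100L)
  expect_equal(nrow(list_intron_genes(no_introns)), 0L)
})
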