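mk_genes <- function(genes, exons) gene_models(genes, exons)

test_that("context calls follow exon > intron > intergenic priority", {
  genes <- data.frame(gene_id = c("g1", "g2"), scaffold = "s1",
                      start = c(1000L, 8000L), end = c(3000L, 9000L))
  exons <- data.frame(gene_id = c("g1", "g1", "g2"),
                      start = c(1000L, 2500L, 8000L),
                      end = c(1200L, 3000L, 9000L))
  gm <- mk_genes(genes, exons)

  elements <- data.frame(
    element_id = c("e_intron", "e_exon", "e_straddle", "e_far"),
    scaffold = "s1",
    start = c(1500L, 1050L, 1100L, 5000L),
    end = c(1700L, 1150L, 1400L, 5200L))
  calls <- annotate_insertions(elements, gm)
  expect_identical(calls$context,
                   c("intron", "exon", "exon", "intergenic"))
  expect_identical(calls$gene_id[1:3], c("g1", "g1", "g1"))
  expect_true(is.na(calls$gene_id[4]))
  expect_equal(calls$distance[1:3], c(0, 0, 0))
  # nearest gene boundary: g1 ends at 3000 -> distance 2000
  expect_equal(calls$distance[4], 2000)

  # explicit distance worked example: nearest gene 1234 bases away
  far <- data.frame(element_id = "e", scaffold = "s1",
                    start = 4234L, end = 4300L)
  expect_equal(annotate_insertions(far, gm)$distance, 1234)
})

test_that("malformed genes with overlapping exons are rejected by name", {
  genes <- data.frame(gene_id = "bad", scaffold = "s1",
                      start = 0L, end = 1000L)
  exons <- data.frame(gene_id = c("bad", "bad"),
                      start = c(0L, 300L), end = c(500L, 800L))
  expect_error(gene_models(genes, exons), "bad")
})

test_that("many elements can share fewer host genes", {
  # 12 elements in 10 genes: two genes host two elements each
  genes <- data.frame(gene_id = sprintf("g%02d", 1:10), scaffold = "s1",
                      start = seq(0L, 90000L, by = 10000L),
                      end = seq(5000L, 95000L, by = 10000L))
  exons <- data.frame(gene_id = genes$gene_id,
                      start = genes$start, end = genes$start + 200L)
  gm <- mk_genes(genes, exons)
  starts <- c(genes$start + 1000L, genes$start[1:2] + 3000L)
  elements <- data.frame(element_id = sprintf("e%02d", seq_along(starts)),
                         scaffold = "s1", start = starts,
                         end = starts + 250L)
  calls <- annotate_insertions(elements, gm)
  s <- summarize_insertions(calls)
  expect_equal(s$n_elements_in_genes, 12L)
  expect_equal(s$n_distinct_genes, 10L)
})

test_that("annotation equals brute-force interval intersection", {
  set.seed(71)
  n_genes <- 40
  gs <- sort(sample.int(500000, n_genes))
  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(n_genes)),
                      scaffold = "s1", start = gs, end = gs + 3000L)
  exons <- do.call(rbind, lapply(seq_len(n_genes), function(i)
    data.frame(gene_id = genes$gene_id[i],
               start = c(genes$start[i], genes$start[i] + 2000L),
               end = c(genes$start[i] + 500L, genes$end[i]))))
  gm <- mk_genes(genes, exons)
  es <- sample.int(500000, 200)
  elements <- data.frame(element_id = sprintf("e%03d", 1:200),
                         scaffold = "s1", start = es, end = es + 300L)
  calls <- annotate_insertions(elements, gm)
  for (i in seq_len(nrow(elements))) {
    want <- oracle_context(elements$start[i], elements$end[i], genes, exons)
    expect_identical(calls$context[i], want$context)
    if (want$context == "intergenic")
      expect_equal(calls$distance[i], want$distance)
  }
  s <- summarize_insertions(calls)
  expect_equal(sum(s$per_context_counts), nrow(elements))
  expect_gte(s$n_elements_in_genes, s$n_distinct_genes)
})

test_that("context calls ignore strand", {
  genes <- data.frame(gene_id = "g1", scaffold = "s1",
                      start = 100L, end = 2000L, strand = "+")
  exons <- data.frame(gene_id = "g1", start = 100L, end = 400L)
  elements <- data.frame(element_id = "e1", scaffold = "s1",
                         start = 600L, end = 900L)
  plus <- annotate_insertions(elements, mk_genes(genes, exons))
  genes$strand <- "-"
  minus <- annotate_insertions(elements, mk_genes(genes, exons))
  expect_identical(plus, minus)
})

test_that("summaries handle trivial inputs", {
  empty <- data.frame(element_id = character(), context = character(),
                      gene_id = character(), distance = numeric())
  s <- summarize_insertions(empty)
  expect_equal(s$n_elements_in_genes, 0L)
  expect_equal(s$n_distinct_genes, 0L)
  expect_equal(sum(s$per_context_counts), 0L)

  three <- data.frame(element_id = c("a", "b", "c"), context = "intron",
                      gene_id = "g1", distance = 0)
  s3 <- summarize_insertions(three)
  expect_equal(s3$n_elements_in_genes, 3L)
  expect_equal(s3$n_distinct_genes, 1L)
})

test_that("gene models round-trip through GFF3", {
  sp <- synthetic_spec(genome_length = 50000, seed = 13,
                       class_counts = c(MITE_LIKE = 6), n_genes = 8,
                       variant_extra_insertions = 0)
  ds <- generate_dataset(sp, withr::local_tempdir())
  gm <- read_gene_models(ds$gff3_path)
  expect_identical(sort(gm$genes$gene_id), sort(ds$genes$genes$gene_id))
  got <- gm$exons[order(gm$exons$gene_id, gm$exons$start), ]
  want <- ds$genes$exons[order(ds$genes$exons$gene_id, ds$genes$exons$start), ]
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
})
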