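test_that("an embedded reference CDS is detected at full identity", {
  refs <- pif_references()
  tpase <- as.character(refs$cds[["tpase_pepif1a"]])
  set.seed(51)
  elem <- paste0(rand_seq(300), tpase, rand_seq(300))
  ev <- detect_coding(elem, refs$protein)
  hit <- ev[ev$reference == "tpase_pepif1a", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$identity, 100)
  expect_equal(hit$coverage, 100)
  expect_equal(hit$frame, 1L)  # planted in frame +1 at offset 300
  # the aligned interval covers the planted CDS (minus the stop codon)
  expect_lte(hit$aligned_start, 300L)
  expect_gte(hit$aligned_end, 300L + nchar(tpase) - 3L)
})

test_that("reverse-strand copies are found in negative frames", {
  refs <- pif_references()
  orf1 <- as.character(refs$cds[["orf1_pepif1a"]])
  set.seed(52)
  elem <- paste0(rand_seq(200), rc_oracle(orf1), rand_seq(200))
  ev <- detect_coding(elem, refs$protein)
  hit <- ev[ev$reference == "orf1_pepif1a", ]
  expect_gte(nrow(hit), 1L)
  expect_true(all(hit$frame < 0))
  expect_equal(max(hit$identity), 100)
})

test_that("random sequence yields no coding evidence", {
  set.seed(53)
  ev <- detect_coding(rand_seq(3000), pif_references()$protein)
  expect_equal(nrow(ev), 0L)
  expect_equal(nrow(detect_coding("AC", pif_references()$protein)), 0L)
})

test_that("detected identity tracks the planted protein divergence", {
  refs <- pif_references()
  orf1 <- as.character(refs$cds[["orf1_pepif1a"]])
  set.seed(54)
  # mutate 10% of codons to random non-stop codons
  codons <- substring(orf1, seq(1, nchar(orf1) - 3, 3),
                      seq(3, nchar(orf1) - 3 + 2, 3))
  ncod <- length(codons) - 1L  # keep the stop codon
  idx <- sample(2:ncod, round(0.1 * ncod))
  stops <- c("TAA", "TAG", "TGA")
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    repeat {
      cd <- paste(sample(bases, 3, replace = TRUE), collapse = "")
      if (!cd %in% stops) break
    }
    codons[i] <- cd
  }
  mut_cds <- paste(codons, collapse = "")
  elem <- paste0(rand_seq(200), mut_cds, rand_seq(200))
  ev <- detect_coding(elem, refs$protein)
  hit <- ev[ev$reference == "orf1_pepif1a", ]
  expect_equal(nrow(hit), 1L)
  # oracle: align the planted (mutated) protein directly to the reference
  mut_prot <- sub("\\*$", "", as.character(Biostrings::translate(
    Biostrings::DNAString(mut_cds))))
  direct <- pairwise_identity(mut_prot,
                              as.character(refs$protein[["orf1_pepif1a"]]),
                              level = "protein_orf1")
  expect_lt(abs(hit$identity - direct$identity), 10)
})

test_that("the classification rule covers the full taxonomy", {
  cases <- rbind(
    data.frame(lt = TRUE,  rt = TRUE,  o1 = TRUE,  tp = TRUE,  len = 5053,
               want = "AUTONOMOUS"),
    data.frame(lt = TRUE,  rt = TRUE,  o1 = FALSE, tp = TRUE,  len = 4000,
               want = "DEF_NO_ORF1"),
    data.frame(lt = TRUE,  rt = TRUE,  o1 = TRUE,  tp = FALSE, len = 3700,
               want = "DEF_NO_TPASE"),
    data.frame(lt = TRUE,  rt = TRUE,  o1 = FALSE, tp = FALSE, len = 250,
               want = "MITE_LIKE"),
    data.frame(lt = TRUE,  rt = TRUE,  o1 = FALSE, tp = FALSE, len = 2100,
               want = "DEF_NO_CODING"),
    data.frame(lt = TRUE,  rt = FALSE, o1 = FALSE, tp = FALSE, len = 900,
               want = "DEF_ONE_TIR"),
    data.frame(lt = FALSE, rt = TRUE,  o1 = TRUE,  tp = TRUE,  len = 4000,
               want = "DEF_ONE_TIR"),
    data.frame(lt = FALSE, rt = FALSE, o1 = FALSE, tp = TRUE,  len = 1400,
               want = "DEF_NO_TIR_FRAGMENT"))
  got <- classify_element(cases$lt, cases$rt, cases$o1, cases$tp, cases$len)
  expect_identical(got, cases$want)
  # unclassifiable: no TIR, no coding
  expect_true(is.na(classify_element(FALSE, FALSE, FALSE, FALSE, 500)))
  # MITE boundary is inclusive
  expect_identical(classify_element(TRUE, TRUE, FALSE, FALSE, 800),
                   "MITE_LIKE")
  expect_identical(classify_element(TRUE, TRUE, FALSE, FALSE, 801),
                   "DEF_NO_CODING")
})

test_that("classification is perfect on divergence-free synthetic data", {
  sp <- synthetic_spec(
    genome_length = 2e5, seed = 88,
    class_counts = c(AUTONOMOUS = 2, DEF_NO_ORF1 = 2, DEF_NO_TPASE = 2,
                     DEF_NO_CODING = 2, DEF_ONE_TIR = 2,
                     DEF_NO_TIR_FRAGMENT = 2, MITE_LIKE = 2),
    mutation_rate = 0, n_genes = 0, variant_extra_insertions = 0)
  ds <- generate_dataset(sp, withr::local_tempdir())
  ann <- mine_elements(ds$genome)
  ev <- evaluate_against_truth(ann, ds$truth)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$class_accuracy, 1)
})

test_that("raising min_identity never increases autonomous calls", {
  refs <- pif_references()
  tpl <- element_templates()
  set.seed(55)
  elems <- c(
    mutA = pifminer::build_element(tpl$A, "AUTONOMOUS"),
    mutB = pifminer::build_element(tpl$B, "AUTONOMOUS"))
  n_auto <- function(min_id) {
    sum(vapply(elems, function(e) {
      ev <- detect_coding(e, refs$protein, min_identity = min_id)
      cls <- classify_element(TRUE, TRUE, any(grepl("^orf1", ev$reference)),
                              any(grepl("^tpase", ev$reference)), nchar(e))
      cls == "AUTONOMOUS"
    }, TRUE))
  }
  counts <- vapply(c(30, 60, 95), n_auto, 1)
  expect_true(all(diff(counts) <= 0))
})

test_that("length histograms bin per class and conserve counts", {
  ann <- data.frame(class = c("AUTONOMOUS", "MITE_LIKE", "MITE_LIKE"),
                    length = c(5053, 250, 280))
  h <- length_histogram(ann, bin_width = 1000)
  expect_equal(h$count[h$class == "AUTONOMOUS"], 1L)
  expect_equal(h$bin_start[h$class == "AUTONOMOUS"], 5000L)
  expect_equal(h$bin_end[h$class == "AUTONOMOUS"], 6000L)
  expect_equal(sum(h$count), nrow(ann))

  expect_equal(nrow(length_histogram(ann[0, ])), 0L)

  # MITE cohort: all mass in the first 1-kb bin; refined at 100-bp bins
  set.seed(56)
  mites <- data.frame(class = "MITE_LIKE",
                      length = sample(200:300, 30, replace = TRUE))
  h1 <- length_histogram(mites, 1000)
  expect_equal(h1$bin_start, 0L)
  expect_equal(h1$count, 30L)
  h2 <- length_histogram(mites, 100)
  expect_true(all(h2$bin_start %in% c(200L, 300L)))
  expect_equal(sum(h2$count), 30L)
})
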