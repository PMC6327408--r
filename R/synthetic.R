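#' Specification for a synthetic genome with planted elements
#'
#' Collects and validates all parameters of the synthetic-data generator.
#' Defaults describe the demo conditions: a 2-Mb background, a MITE-heavy
#' class inventory (miniature copies outnumber autonomous ones, as observed
#' for this element superfamily), 2% per-site divergence on planted copies,
#' and a variant genome carrying two extra insertions for transposon-display
#' testing.
#'
#' @param genome_length background length in bases (> 0).
#' @param gc_fraction expected GC proportion of the background, in `[0, 1]`.
#' @param seed integer seed; all generator randomness derives from it.
#' @param class_counts named integer vector: copies to plant per structural
#'   class (names from `PIF_CLASSES`).
#' @param mutation_rate per-site substitution rate applied to each planted
#'   copy, in `[0, 0.5)`.
#' @param n_genes total number of gene models to place.
#' @param variant_extra_insertions number of additional insertions carried
#'   by the derived variant genome.
#' @param tsd_force_tta if `TRUE` (default) insertion sites are re-drawn
#'   until the 3-bp target site is `TTA`, the preferred target of this
#'   element; if `FALSE` any site is accepted.
#' @param frac_exonic,frac_intronic fractions of planted elements that gene
#'   models are placed over so the element falls in an exon / an intron;
#'   the remainder stays intergenic.
#' @return A validated list of class `synthetic_spec`.
#' @export
#' @examples
#' sp <- synthetic_spec(genome_length = 50000,
#'                      class_counts = c(AUTONOMOUS = 1, MITE_LIKE = 2))
synthetic_spec <- function(genome_length = 2e6,
                           gc_fraction = 0.44,
                           seed = 1L,
                           class_counts = c(AUTONOMOUS = 8, DEF_NO_ORF1 = 7,
                                            DEF_NO_TPASE = 7, DEF_NO_CODING = 7,
                                            DEF_ONE_TIR = 7,
                                            DEF_NO_TIR_FRAGMENT = 4,
                                            MITE_LIKE = 40),
                           mutation_rate = 0.02,
                           n_genes = 60,
                           variant_extra_insertions = 2,
                           tsd_force_tta = TRUE,
                           frac_exonic = 0.1,
                           frac_intronic = 0.3) {
  if (!is_count(genome_length) || genome_length <= 0)
    stopf("genome_length must be a positive number")
  if (gc_fraction < 0 || gc_fraction > 1)
    stopf("gc_fraction must be in [0, 1]")
  if (mutation_rate < 0 || mutation_rate >= 0.5)
    stopf("mutation_rate must be in [0, 0.5)")
  if (length(class_counts) == 0 || is.null(names(class_counts)))
    stopf("class_counts must be a named vector")
  bad <- setdiff(names(class_counts), PIF_CLASSES)
  if (length(bad)) stopf("unknown class name(s): %s", paste(bad, collapse = ", "))
  if (any(class_counts < 0)) stopf("class counts must be >= 0")
  if (!is_count(n_genes) || !is_count(variant_extra_insertions))
    stopf("n_genes and variant_extra_insertions must be non-negative counts")
  if (frac_exonic < 0 || frac_intronic < 0 || frac_exonic + frac_intronic > 1)
    stopf("gene-context fractions must be non-negative and sum to <= 1")
  structure(list(genome_length = as.integer(genome_length),
                 gc_fraction = gc_fraction, seed = as.integer(seed),
                 class_counts = class_counts, mutation_rate = mutation_rate,
                 n_genes = as.integer(n_genes),
                 variant_extra_insertions = as.integer(variant_extra_insertions),
                 tsd_force_tta = isTRUE(tsd_force_tta),
                 frac_exonic = frac_exonic, frac_intronic = frac_intronic),
            class = "synthetic_spec")
}

#' Generate a random background genome
#'
#' @param length sequence length in bases (> 0).
#' @param gc expected GC fraction.
#' @param seed integer seed; the same seed yields the identical sequence.
#' @return A [Biostrings::DNAString].
#' @export
#' @examples
#' g <- generate_background(1000, 0.4, 7)
generate_background <- function(length, gc = 0.5, seed = 1L) {
  if (!is.numeric(length) || length(length) != 1 || is.na(length) || length <= 0)
    stopf("length must be a positive number")
  set.seed(seed)
  Biostrings::DNAString(random_dna(as.integer(length), gc))
}

#' Plant one element copy into a genome with target-site duplication
#'
#' Inserts an element of the requested structural class at `position`
#' (0-based offset into the pre-insertion sequence). The 3 bases at
#' `[position, position + 3)` become the target-site duplication: they end
#' up flanking the element on both sides, so the genome grows by
#' `element length + 3` bases. Randomness (MITE spacer, mutations) is drawn
#' from the current RNG stream.
#'
#' @param genome a [Biostrings::DNAString], character string, or single-
#'   sequence [Biostrings::DNAStringSet].
#' @param template family template from [element_templates()].
#' @param class_name structural class to plant.
#' @param position 0-based insertion offset, `3 <= position <= length - 3`.
#' @param mutation_rate per-site substitution rate applied to the copy.
#' @param tsd_len length of the duplicated target site (default 3).
#' @return List with `genome` (new [Biostrings::DNAString]) and `truth`
#'   (one-row data.frame: class, family, start, end, tsd, element_length,
#'   insert_position; start/end are 0-based half-open element bounds in the
#'   returned genome).
#' @export
plant_element <- function(genome, template, class_name, position,
                          mutation_rate = 0, tsd_len = 3L) {
  g <- as.character(as_genome(genome)[[1]])
  n <- nchar(g)
  if (!is.numeric(position) || length(position) != 1 || is.na(position) ||
      position < tsd_len || position > n - tsd_len)
    stopf("position must satisfy %d <= position <= %d", tsd_len, n - tsd_len)
  position <- as.integer(position)
  elem <- mutate_dna(build_element(template, class_name), mutation_rate)
  len <- nchar(elem)
  tsd <- substr(g, position + 1L, position + tsd_len)
  new_g <- paste0(substr(g, 1L, position + tsd_len), elem,
                  substr(g, position + 1L, n))
  truth <- data.frame(
    class = class_name, family = template$family,
    start = position + tsd_len, end = position + tsd_len + len,
    tsd = tsd, element_length = len, insert_position = position,
    stringsAsFactors = FALSE)
  list(genome = Biostrings::DNAString(new_g), truth = truth)
}

# draw `k` non-overlapping insertion positions; optionally require the
# 3-bp target site to be TTA. Errors after `max_tries` failed draws.
draw_positions <- function(g_chr, k, margin, force_tta, tsd_len = 3L,
                           min_sep = 10L, max_tries = 1000L) {
  n <- nchar(g_chr)
  if (n < 2 * margin + min_sep) stopf("background too short for planting")
  taken <- integer(0)
  out <- integer(k)
  for (i in seq_len(k)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      p <- sample.int(n - 2L * margin, 1L) + margin
      if (length(taken) && min(abs(taken - p)) < min_sep) next
      if (force_tta &&
          substr(g_chr, p + 1L, p + tsd_len) != PIF_TSD) next
      ok <- TRUE
      break
    }
    if (!ok) stopf("could not place insertion %d after %d re-draws", i, max_tries)
    out[i] <- p
    taken <- c(taken, p)
  }
  out
}

# plant a batch of elements (class/family rows) at background positions,
# returning the grown genome and truth rows with final coordinates
plant_batch <- function(g_chr, plan, templates, mutation_rate, tsd_len = 3L) {
  plan <- plan[order(plan$position), , drop = FALSE]
  pieces <- character(0)
  truth <- vector("list", nrow(plan))
  prev <- 0L
  shift <- 0L
  for (i in seq_len(nrow(plan))) {
    p <- plan$position[i]
    elem <- mutate_dna(build_element(templates[[plan$family[i]]],
                                     plan$class[i]), mutation_rate)
    len <- nchar(elem)
    tsd <- substr(g_chr, p + 1L, p + tsd_len)
    pieces <- c(pieces, substr(g_chr, prev + 1L, p + tsd_len), elem)
    truth[[i]] <- data.frame(
      class = plan$class[i], family = plan$family[i],
      start = p + tsd_len + shift, end = p + tsd_len + shift + len,
      tsd = tsd, element_length = len, insert_position = p,
      stringsAsFactors = FALSE)
    prev <- p
    shift <- shift + len + tsd_len
  }
  pieces <- c(pieces, substr(g_chr, prev + 1L, nchar(g_chr)))
  list(genome = paste(pieces, collapse = ""), truth = do.call(rbind, truth))
}

# place gene models so chosen elements fall in exons / introns, plus extra
# element-free genes; coordinates are 0-based half-open on the final genome
place_genes <- function(truth, genome_len, spec) {
  n_elem <- nrow(truth)
  genes <- list()
  gid <- 0L
  add_gene <- function(start, end, exons) {
    gid <<- gid + 1L
    id <- sprintf("gene_%03d", gid)
    genes[[length(genes) + 1L]] <<- list(
      gene = data.frame(gene_id = id, start = start, end = end,
                        stringsAsFactors = FALSE),
      exons = data.frame(gene_id = id, start = exons[, 1], end = exons[, 2],
                         stringsAsFactors = FALSE))
    id
  }
  if (n_elem > 0) {
    k_ex <- round(spec$frac_exonic * n_elem)
    k_in <- round(spec$frac_intronic * n_elem)
    idx <- sample.int(n_elem, min(n_elem, k_ex + k_in))
    ex_idx <- head(idx, k_ex)
    in_idx <- setdiff(idx, ex_idx)
    for (i in ex_idx) {
      gs <- max(0L, truth$start[i] - 500L)
      ge <- min(genome_len, truth$end[i] + 500L)
      add_gene(gs, ge, cbind(gs, ge))  # single exon spanning the element
    }
    for (i in in_idx) {
      gs <- max(0L, truth$start[i] - 500L)
      ge <- min(genome_len, truth$end[i] + 500L)
      add_gene(gs, ge, rbind(c(gs, gs + 200L), c(ge - 200L, ge)))
    }
  }
  # fill with element-free intergenic genes up to n_genes
  occupied <- rbind(cbind(truth$start, truth$end),
                    do.call(rbind, lapply(genes, function(g)
                      cbind(g$gene$start, g$gene$end))))
  while (gid < spec$n_genes) {
    placed <- FALSE
    for (try in seq_len(1000L)) {
      gs <- sample.int(genome_len - 2200L, 1L)
      ge <- gs + 2000L
      if (!is.null(occupied) && nrow(occupied) > 0 &&
          any(gs < occupied[, 2] & ge > occupied[, 1])) next
      add_gene(gs, ge, rbind(c(gs, gs + 200L),
                             c(gs + 900L, gs + 1100L),
                             c(ge - 200L, ge)))
      occupied <- rbind(occupied, c(gs, ge))
      placed <- TRUE
      break
    }
    if (!placed) break  # genome too crowded; accept fewer genes
  }
  list(genes = do.call(rbind, lapply(genes, `[[`, "gene")),
       exons = do.call(rbind, lapply(genes, `[[`, "exons")))
}

#' Generate a synthetic dataset with planted elements and ground truth
#'
#' Builds a seeded random background, plants element copies of every
#' requested structural class (each insertion creating a 3-bp target-site
#' duplication), places gene models so configurable fractions of elements
#' fall in exons / introns, and derives a variant genome carrying
#' `variant_extra_insertions` additional copies. All outputs are written to
#' `out_dir`; identical spec and seed give byte-identical files.
#'
#' The truth table records 0-based half-open element bounds on the final
#' (post-insertion) genome. Variant extra insertions are MITE-like family-B
#' copies, mirroring the observation that new transposition events in this
#' system trace to the B family and are mediated by miniature copies.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory (created if missing).
#' @param scaffold_id scaffold name used in FASTA/GFF3 output.
#' @return List with paths (`fasta_path`, `gff3_path`, `truth_table_path`,
#'   `variant_fasta_path`, `variant_truth_table_path`) and in-memory objects
#'   (`genome`, `variant_genome`, `truth`, `variant_truth`, `genes`).
#' @export
generate_dataset <- function(spec, out_dir, scaffold_id = "scaffold_1") {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  templates <- element_templates()
  bg <- as.character(generate_background(spec$genome_length,
                                         spec$gc_fraction, spec$seed))

  counts <- spec$class_counts[spec$class_counts > 0]
  classes <- rep(names(counts), counts)
  # family drawn per copy at the empirically observed A:B ratio (29:37)
  fams <- sample(c("A", "B"), length(classes), replace = TRUE,
                 prob = c(29, 37) / 66)
  plan <- data.frame(class = classes, family = fams,
                     position = draw_positions(bg, length(classes),
                                               margin = 200L,
                                               spec$tsd_force_tta),
                     stringsAsFactors = FALSE)
  base <- plant_batch(bg, plan, templates, spec$mutation_rate)
  truth <- base$truth
  if (is.null(truth)) {
    truth <- data.frame(class = character(), family = character(),
                        start = integer(), end = integer(), tsd = character(),
                        element_length = integer(), insert_position = integer())
  }
  truth <- cbind(element_id = sprintf("PePIF1_%03d", seq_len(nrow(truth))),
                 scaffold = rep(scaffold_id, nrow(truth)), truth,
                 stringsAsFactors = FALSE)

  genes <- place_genes(truth, nchar(base$genome), spec)

  # variant genome: extra MITE-like family-B insertions on top of the base
  variant <- base$genome
  vt <- NULL
  if (spec$variant_extra_insertions > 0) {
    vplan <- data.frame(
      class = rep("MITE_LIKE", spec$variant_extra_insertions),
      family = rep("B", spec$variant_extra_insertions),
      position = draw_positions(variant, spec$variant_extra_insertions,
                                margin = 200L, spec$tsd_force_tta),
      stringsAsFactors = FALSE)
    vres <- plant_batch(variant, vplan, templates, spec$mutation_rate)
    variant <- vres$genome
    vt <- cbind(element_id = sprintf("PePIF1_var_%03d", seq_len(nrow(vres$truth))),
                scaffold = rep(scaffold_id, nrow(vres$truth)), vres$truth,
                stringsAsFactors = FALSE)
  }

  paths <- list(
    fasta_path = file.path(out_dir, "genome.fa"),
    gff3_path = file.path(out_dir, "genes.gff3"),
    truth_table_path = file.path(out_dir, "truth.tsv"),
    variant_fasta_path = file.path(out_dir, "genome_variant.fa"),
    variant_truth_table_path = file.path(out_dir, "truth_variant.tsv"))

  gset <- Biostrings::DNAStringSet(setNames(base$genome, scaffold_id))
  vset <- Biostrings::DNAStringSet(setNames(variant, scaffold_id))
  Biostrings::writeXStringSet(gset, paths$fasta_path, width = 80)
  Biostrings::writeXStringSet(vset, paths$variant_fasta_path, width = 80)
  write_gene_gff3(genes, scaffold_id, paths$gff3_path)
  tt <- truth[, c("element_id", "scaffold", "class", "family",
                  "start", "end", "tsd")]
  write.table(tt, paths$truth_table_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(vt)) {
    write.table(vt[, c("element_id", "scaffold", "class", "family",
                       "start", "end", "tsd")],
                paths$variant_truth_table_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  c(paths, list(genome = gset, variant_genome = vset, truth = truth,
                variant_truth = vt, genes = genes))
}

# write gene/mRNA/exon features as GFF3 (1-based closed coordinates)
write_gene_gff3 <- function(genes, scaffold_id, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (is.null(genes$genes) || nrow(genes$genes) == 0) return(invisible(path))
  for (i in seq_len(nrow(genes$genes))) {
    g <- genes$genes[i, ]
    ex <- genes$exons[genes$exons$gene_id == g$gene_id, , drop = FALSE]
    writeLines(sprintf("%s\tpifminer\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                       scaffold_id, g$start + 1L, g$end, g$gene_id), con)
    writeLines(sprintf("%s\tpifminer\tmRNA\t%d\t%d\t.\t+\t.\tID=%s.t1;Parent=%s",
                       scaffold_id, g$start + 1L, g$end, g$gene_id, g$gene_id), con)
    for (j in seq_len(nrow(ex))) {
      writeLines(sprintf(
        "%s\tpifminer\texon\t%d\t%d\t.\t+\t.\tID=%s.t1.e%d;Parent=%s.t1",
        scaffold_id, ex$start[j] + 1L, ex$end[j], g$gene_id, j, g$gene_id), con)
    }
  }
  invisible(path)
}
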