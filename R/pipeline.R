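#' Pipeline configuration
#'
#' Every screening constant is a named, documented key: the degenerate TIR
#' motif, the mismatch budgets, the 30-kb maximum span between paired
#' TIRs, the 3-bp TSD length, the translated-alignment thresholds, the
#' MITE length ceiling, the three 80s of the family rule, and the display
#' assay parameters. Values not supplied keep their defaults.
#'
#' @param ... overrides for any configuration key.
#' @return List of class `pif_config`.
#' @export
#' @examples
#' cfg <- pif_config(max_mismatch = 1)
#' cfg$max_span
pif_config <- function(...) {
  cfg <- list(
    motif = PIF_TIR_CONSENSUS,
    max_mismatch = 2L,          # TIR motif mismatch budget
    anchor_max_mismatch = 6L,   # sub-terminal anchor budget (10% of 60 bp)
    max_span = 30000L,          # maximum length between two TIRs
    min_span = 50L,
    tsd_len = 3L,
    min_identity = 30,          # coding evidence thresholds (percent)
    min_coverage = 50,
    mite_max_len = 800L,
    family_min_identity = 80,   # the 80-80-80 rule
    family_min_coverage = 80,
    family_min_aligned = 80,
    family_level = "dna",
    display_site = "CTAG",      # BfaI, C^TAG
    display_cut_offset = 1L,
    display_window = c(50L, 700L),
    display_adapter_len = 20L,
    display_nn_set = PIF_NN_DEFAULT,
    display_primer_max_mismatch = 0L,
    seed = 1L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$max_span <= 0 || cfg$min_span <= 0 || cfg$tsd_len <= 0)
    stopf("spans and tsd_len must be positive")
  structure(cfg, class = "pif_config")
}

#' Write / read a pipeline configuration (YAML)
#'
#' The serialized form round-trips: reading a written configuration
#' reproduces it exactly.
#'
#' @param config a [pif_config()].
#' @param path file path.
#' @return `write_pif_config` returns the path invisibly;
#'   `read_pif_config` returns a `pif_config`.
#' @export
write_pif_config <- function(config, path) {
  stopifnot(inherits(config, "pif_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pif_config
#' @export
read_pif_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pif_config, raw)
}

#' Export element annotations as GFF3
#'
#' Writes one `mobile_genetic_element` feature per element with `class`,
#' `family`, `tsd` and `tsd_valid` attributes (1-based closed coordinates,
#' as GFF3 requires).
#'
#' @param annotations data.frame from [mine_elements()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
export_elements_gff3 <- function(annotations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    writeLines(sprintf(
      paste0("%s\tpifminer\tmobile_genetic_element\t%d\t%d\t.\t+\t.\t",
             "ID=%s;class=%s;family=%s;tsd=%s;tsd_valid=%s"),
      a$scaffold, a$start + 1L, a$end, a$element_id, a$class, a$family,
      a$tsd_left, tolower(a$tsd_valid)), con)
  }
  invisible(path)
}

# read an elements GFF3 back into the annotation data.frame shape
read_elements_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) && any(GenomicRanges::start(gr) < 1))
    stopf("GFF3 coordinates must be 1-based (found start < 1)")
  df <- as.data.frame(gr)
  if (nrow(df) == 0) {
    return(data.frame(element_id = character(), scaffold = character(),
                      start = integer(), end = integer(),
                      class = character(), family = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(element_id = df$ID, scaffold = as.character(df$seqnames),
             start = df$start - 1L, end = df$end,
             class = if (is.null(df$class)) NA_character_ else df$class,
             family = if (is.null(df$family)) NA_character_ else df$family,
             stringsAsFactors = FALSE)
}

#' Run the full mining pipeline
#'
#' Orchestrates scan, classification, family clustering, insertion
#' annotation and (when a variant genome is given) transposon display,
#' writing every result table plus a JSON run manifest to `out_dir`.
#' Outputs are deterministic for a fixed input and configuration, so a
#' rerun produces byte-identical files.
#'
#' @param genome_fasta path to the genome FASTA.
#' @param genes_gff3 optional path to gene models (GFF3).
#' @param variant_fasta optional path to a second genome; enables the
#'   display stage with the base genome as reference.
#' @param config a [pif_config()].
#' @param out_dir output directory.
#' @return Invisibly, a list with the annotation table, family assignment,
#'   insertion calls and summary, display diffs, and all output paths.
#' @export
run_pipeline <- function(genome_fasta, genes_gff3 = NULL,
                         variant_fasta = NULL, config = pif_config(),
                         out_dir) {
  stopifnot(inherits(config, "pif_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  templates <- element_templates()
  refs <- pif_references()

  message("[scan] mining elements ...")
  ann <- mine_elements(genome, templates, refs$protein,
                       max_span = config$max_span,
                       tir_max_mismatch = config$max_mismatch,
                       anchor_max_mismatch = config$anchor_max_mismatch,
                       min_identity = config$min_identity,
                       min_coverage = config$min_coverage,
                       mite_max_len = config$mite_max_len,
                       tsd_len = config$tsd_len)
  counts <- table(factor(ann$class, levels = PIF_CLASSES))
  message("[classify] ", paste(sprintf("%s=%d", names(counts), counts),
                               collapse = " "))

  message("[cluster] 80-80-80 families over autonomous elements ...")
  auto <- ann[!is.na(ann$class) & ann$class == "AUTONOMOUS", , drop = FALSE]
  fam_assign <- NULL
  if (nrow(auto) >= 2) {
    seqs <- setNames(vapply(seq_len(nrow(auto)), function(i)
      substr(as.character(genome[[auto$scaffold[i]]]),
             auto$start[i] + 1L, auto$end[i]), ""), auto$element_id)
    fam_assign <- cluster_families(seqs,
                                   min_identity = config$family_min_identity,
                                   min_coverage = config$family_min_coverage,
                                   min_aligned = config$family_min_aligned,
                                   level = config$family_level)
  }

  calls <- NULL
  smry <- NULL
  if (!is.null(genes_gff3)) {
    message("[annotate] intersecting with gene models ...")
    gm <- read_gene_models(genes_gff3)
    calls <- annotate_insertions(ann, gm)
    smry <- summarize_insertions(calls)
    message(sprintf("[annotate] %d elements in %d genes",
                    smry$n_elements_in_genes, smry$n_distinct_genes))
  }

  diffs <- list()
  profiles <- list()
  if (!is.null(variant_fasta)) {
    message("[display] simulating transposon display ...")
    variant <- Biostrings::readDNAStringSet(variant_fasta)
    names(variant) <- sub("\\s.*$", "", names(variant))
    for (fam in names(templates)) {
      pr <- templates[[fam]]$primer
      pb <- simulate_display(genome, pr, sample_id = "base", family = fam,
                             nn_set = config$display_nn_set,
                             window = config$display_window,
                             adapter_len = config$display_adapter_len,
                             primer_max_mismatch = config$display_primer_max_mismatch,
                             site = config$display_site,
                             cut_offset = config$display_cut_offset)
      pv <- simulate_display(variant, pr, sample_id = "variant", family = fam,
                             nn_set = config$display_nn_set,
                             window = config$display_window,
                             adapter_len = config$display_adapter_len,
                             primer_max_mismatch = config$display_primer_max_mismatch,
                             site = config$display_site,
                             cut_offset = config$display_cut_offset)
      profiles[[fam]] <- list(base = pb, variant = pv)
      diffs[[fam]] <- diff_profiles(list(pb, pv))
    }
  }

  paths <- list(elements_gff3 = file.path(out_dir, "elements.gff3"),
                class_summary = file.path(out_dir, "class_summary.tsv"),
                families = file.path(out_dir, "families.tsv"),
                identities = file.path(out_dir, "identity_records.tsv"),
                insertions = file.path(out_dir, "insertions.tsv"),
                insertion_summary = file.path(out_dir, "insertion_summary.tsv"),
                manifest = file.path(out_dir, "manifest.json"))
  export_elements_gff3(ann, paths$elements_gff3)
  hist <- length_histogram(ann)
  write.table(hist, paths$class_summary, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(fam_assign)) {
    write.table(fam_assign, paths$families, sep = "\t", quote = FALSE,
                row.names = FALSE)
    idr <- attr(fam_assign, "identities")
    if (!is.null(idr))
      write.table(idr, paths$identities, sep = "\t", quote = FALSE,
                  row.names = FALSE)
  }
  if (!is.null(calls)) {
    write.table(calls, paths$insertions, sep = "\t", quote = FALSE,
                row.names = FALSE)
    sdf <- data.frame(metric = c("n_elements_in_genes", "n_distinct_genes",
                                 paste0("context_", names(smry$per_context_counts))),
                      value = c(smry$n_elements_in_genes,
                                smry$n_distinct_genes,
                                as.integer(smry$per_context_counts)))
    write.table(sdf, paths$insertion_summary, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  for (fam in names(diffs)) {
    p <- file.path(out_dir, sprintf("differential_bands_%s.tsv", fam))
    write.table(diffs[[fam]], p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[paste0("differential_bands_", fam)]] <- p
    for (s in c("base", "variant")) {
      bp <- file.path(out_dir, sprintf("display_%s_%s.tsv", fam, s))
      write.table(profiles[[fam]][[s]]$bands, bp, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      paths[[paste0("display_", fam, "_", s)]] <- bp
    }
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  write_pif_config(config, cfg_path)
  paths$config <- cfg_path
  manifest <- list(package = "pifminer",
                   version = as.character(packageVersion("pifminer")),
                   seed = config$seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   n_elements = nrow(ann),
                   class_counts = as.list(counts))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(annotations = ann, families = fam_assign,
                 insertions = calls, insertion_summary = smry,
                 display_diffs = diffs, paths = paths))
}

#' Evaluate element calls against planted truth
#'
#' An element is recovered when both of its boundaries match a truth row
#' on the same scaffold within `tol` bases (one-to-one greedy matching).
#' Class accuracy is computed over recovered elements.
#'
#' @param calls elements GFF3 path or annotation data.frame.
#' @param truth truth-table TSV path (as written by [generate_dataset()])
#'   or equivalent data.frame with 0-based half-open `start`/`end`.
#' @param tol boundary tolerance in bases (default 2).
#' @return List: `recall`, `precision`, `class_accuracy`, `n_truth`,
#'   `n_calls`, `n_recovered`.
#' @export
evaluate_against_truth <- function(calls, truth, tol = 2L) {
  if (is.character(calls)) calls <- read_elements_gff3(calls)
  if (is.character(truth)) truth <- read.delim(truth, stringsAsFactors = FALSE)
  need <- c("scaffold", "start", "end", "class")
  if (!all(need %in% names(truth)))
    stopf("truth must have columns: %s", paste(need, collapse = ", "))
  n_truth <- nrow(truth)
  n_calls <- nrow(calls)
  matched_call <- rep(FALSE, n_calls)
  recovered <- 0L
  class_ok <- 0L
  for (i in seq_len(n_truth)) {
    cand <- which(!matched_call & calls$scaffold == truth$scaffold[i] &
                    abs(calls$start - truth$start[i]) <= tol &
                    abs(calls$end - truth$end[i]) <= tol)
    if (length(cand) == 0) next
    j <- cand[1]
    matched_call[j] <- TRUE
    recovered <- recovered + 1L
    if (!is.na(calls$class[j]) && calls$class[j] == truth$class[i])
      class_ok <- class_ok + 1L
  }
  list(recall = if (n_truth) recovered / n_truth else NA_real_,
       precision = if (n_calls) sum(matched_call) / n_calls else NA_real_,
       class_accuracy = if (recovered) class_ok / recovered else NA_real_,
       n_truth = n_truth, n_calls = n_calls, n_recovered = recovered)
}
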