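#' Gene model container
#'
#' Bundles gene spans and their exons (0-based half-open coordinates) and
#' validates that exons are disjoint within each gene. Introns are the
#' gaps between consecutive exons inside the gene span.
#'
#' @param genes data.frame with `gene_id`, `scaffold`, `start`, `end`
#'   (and optionally `strand`).
#' @param exons data.frame with `gene_id`, `start`, `end`.
#' @return List of class `gene_models` with sorted, validated components.
#' @export
gene_models <- function(genes, exons) {
  need <- c("gene_id", "scaffold", "start", "end")
  if (!all(need %in% names(genes)))
    stopf("genes must have columns: %s", paste(need, collapse = ", "))
  if (!all(c("gene_id", "start", "end") %in% names(exons)))
    stopf("exons must have columns gene_id, start, end")
  if (is.null(genes$strand)) genes$strand <- "+"
  for (gid in unique(exons$gene_id)) {
    e <- exons[exons$gene_id == gid, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      stopf("gene %s has overlapping exons", gid)
  }
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  genes <- genes[order(genes$scaffold, genes$start), , drop = FALSE]
  rownames(genes) <- rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Read gene models from GFF3
#'
#' Imports `gene`/`mRNA`/`exon` features; the first mRNA of each gene
#' provides the exon structure. Coordinates are converted to 0-based
#' half-open.
#'
#' @param path GFF3 file.
#' @return A [gene_models()] object.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) && any(GenomicRanges::start(gr) < 1))
    stopf("GFF3 coordinates must be 1-based (found start < 1)")
  df <- as.data.frame(gr)
  type <- as.character(df$type)
  gene_rows <- df[type == "gene", , drop = FALSE]
  mrna_rows <- df[type == "mRNA", , drop = FALSE]
  exon_rows <- df[type == "exon", , drop = FALSE]
  first_parent <- function(p) if (length(p)) p[[1]][1] else NA_character_
  mrna_rows$gene <- vapply(mrna_rows$Parent, function(p) p[1], "")
  # first mRNA per gene
  mrna_rows <- mrna_rows[!duplicated(mrna_rows$gene), , drop = FALSE]
  keep_mrna <- setNames(mrna_rows$gene, mrna_rows$ID)
  exon_rows$mrna <- vapply(exon_rows$Parent, function(p) p[1], "")
  exon_rows <- exon_rows[exon_rows$mrna %in% names(keep_mrna), , drop = FALSE]
  genes <- data.frame(gene_id = gene_rows$ID,
                      scaffold = as.character(gene_rows$seqnames),
                      start = gene_rows$start - 1L, end = gene_rows$end,
                      strand = as.character(gene_rows$strand),
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = unname(keep_mrna[exon_rows$mrna]),
                      start = exon_rows$start - 1L, end = exon_rows$end,
                      stringsAsFactors = FALSE)
  gene_models(genes, exons)
}

#' Annotate element insertions with their genic context
#'
#' An element overlapping any exon base of a gene is `exon` (coding
#' disruption takes priority when an element straddles a boundary); an
#' element overlapping a gene span but no exon is `intron`; anything else
#' is `intergenic`, with the distance to the nearest gene boundary
#' reported (ties broken toward the lower-coordinate gene). "Inserted in a
#' gene" means any overlap with the gene span. Context is positional, so
#' strand is ignored.
#'
#' @param elements data.frame with `element_id`, `scaffold`, `start`,
#'   `end` (0-based half-open).
#' @param genes a [gene_models()] object (or list with `genes`/`exons`).
#' @return data.frame `element_id`, `context`, `gene_id` (`NA` when
#'   intergenic), `distance` (0 when inside a gene).
#' @export
annotate_insertions <- function(elements, genes) {
  if (!inherits(genes, "gene_models")) genes <- gene_models(genes$genes, genes$exons)
  gtab <- genes$genes
  etab <- genes$exons
  etab$scaffold <- gtab$scaffold[match(etab$gene_id, gtab$gene_id)]
  out <- data.frame(element_id = elements$element_id,
                    context = "intergenic", gene_id = NA_character_,
                    distance = NA_real_, nearest_gene = NA_character_,
                    stringsAsFactors = FALSE)
  if (nrow(elements) == 0) return(out)
  eg <- GenomicRanges::GRanges(elements$scaffold,
                               IRanges::IRanges(elements$start + 1L,
                                                elements$end))
  gg <- GenomicRanges::GRanges(gtab$scaffold,
                               IRanges::IRanges(gtab$start + 1L, gtab$end))
  xg <- GenomicRanges::GRanges(etab$scaffold,
                               IRanges::IRanges(etab$start + 1L, etab$end))
  ov_gene <- GenomicRanges::findOverlaps(eg, gg)
  ov_exon <- GenomicRanges::findOverlaps(eg, xg)
  for (i in seq_len(nrow(elements))) {
    ex_hits <- S4Vectors::subjectHits(ov_exon)[S4Vectors::queryHits(ov_exon) == i]
    gn_hits <- S4Vectors::subjectHits(ov_gene)[S4Vectors::queryHits(ov_gene) == i]
    if (length(ex_hits)) {
      gids <- unique(etab$gene_id[ex_hits])
      # lowest-coordinate gene when several qualify
      g <- gids[order(gtab$start[match(gids, gtab$gene_id)])][1]
      out$context[i] <- "exon"
      out$gene_id[i] <- g
      out$nearest_gene[i] <- g
      out$distance[i] <- 0
    } else if (length(gn_hits)) {
      g <- gn_hits[order(gtab$start[gn_hits])][1]
      out$context[i] <- "intron"
      out$gene_id[i] <- gtab$gene_id[g]
      out$nearest_gene[i] <- gtab$gene_id[g]
      out$distance[i] <- 0
    } else {
      sc <- gtab[gtab$scaffold == elements$scaffold[i], , drop = FALSE]
      if (nrow(sc) == 0) { out$distance[i] <- NA_real_; next }
      d <- pmax(sc$start - elements$end[i], elements$start[i] - sc$end)
      d <- pmax(d, 0)
      j <- which(d == min(d))
      j <- j[order(sc$start[j])][1]  # tie -> lower coordinate
      out$distance[i] <- min(d)
      out$nearest_gene[i] <- sc$gene_id[j]  # gene_id stays NA: intergenic
    }
  }
  rownames(out) <- NULL
  out
}

#' Summarize insertion calls
#'
#' @param calls data.frame from [annotate_insertions()].
#' @return List: `n_elements_in_genes` (elements with exon or intron
#'   context), `n_distinct_genes` (distinct host genes), and
#'   `per_context_counts` (named vector over exon/intron/intergenic).
#' @export
#' @examples
#' summarize_insertions(data.frame(element_id = "e1", context = "intron",
#'                                 gene_id = "g1", distance = 0))
summarize_insertions <- function(calls) {
  ctx <- factor(calls$context, levels = c("exon", "intron", "intergenic"))
  genic <- calls$context %in% c("exon", "intron")
  list(n_elements_in_genes = sum(genic),
       n_distinct_genes = length(unique(calls$gene_id[genic])),
       per_context_counts = table(ctx))
}
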