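# amino-acid k-mers of a segment, used as a cheap homology prescreen
aa_kmers <- function(x, k = 5L) {
  n <- nchar(x)
  if (n < k) return(character(0))
  unique(substring(x, 1:(n - k + 1L), k:n))
}

#' Detect ORF1/transposase coding evidence by translated alignment
#'
#' Translates the element in all six frames, splits each translation at
#' stop codons, and locally aligns (BLOSUM62, gap open 11 / extend 1) the
#' stop-free segments against each reference protein, after a shared
#' 5-mer prescreen discards segments with no trace of homology. Like the
#' translated-search tools this replaces, evidence from several local
#' alignments (HSPs) in the same frame is tiled: reference coverage is the
#' union of their aligned reference spans and identity their
#' length-weighted mean, so copies fragmented by mutation-induced stop
#' codons are still recognized. Evidence is reported per frame when the
#' combined identity and coverage reach their thresholds. Spliced
#' (multi-exon) ORFs are not reconstructed.
#'
#' @param element_seq DNA sequence of the element (character or DNAString).
#' @param references named [Biostrings::AAStringSet] of reference proteins;
#'   names starting `orf1`/`tpase` drive the presence flags downstream.
#' @param min_identity minimum percent identity (default 30, low enough to
#'   pick up diverged copies of the second family).
#' @param min_coverage minimum percent of the reference length aligned
#'   (default 50).
#' @param min_hsp minimum stop-free segment length and minimum aligned
#'   reference span (in residues) for an HSP to count.
#' @return data.frame with one row per qualifying (reference, frame):
#'   `reference`, `frame` (1..3, -1..-3), `identity`, `coverage`, `score`
#'   (summed over HSPs), `aligned_start`, `aligned_end` (0-based half-open
#'   span on the element covered by the evidence).
#' @export
detect_coding <- function(element_seq, references = pif_references()$protein,
                          min_identity = 30, min_coverage = 50,
                          min_hsp = 30L) {
  if (length(references) == 0) stopf("references must be non-empty")
  seq <- as.character(as_genome(element_seq)[[1]])
  n <- nchar(seq)
  empty <- data.frame(reference = character(), frame = integer(),
                      identity = numeric(), coverage = numeric(),
                      score = numeric(), aligned_start = integer(),
                      aligned_end = integer(), stringsAsFactors = FALSE)
  if (n < 3) return(empty)

  frames <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) seq else rc_chr(seq)
    for (f in 1:3) {
      len <- ((n - f + 1L) %/% 3L) * 3L
      if (len < 3) next
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(s, f, f + len - 1L)),
        if.fuzzy.codon = "solve"))
      segs <- strsplit(aa, "*", fixed = TRUE)[[1]]
      offs <- cumsum(c(0L, nchar(segs) + 1L))[seq_along(segs)]  # aa offsets
      keep <- nchar(segs) >= min_hsp
      frames[[length(frames) + 1L]] <- list(frame = strand * f,
                                            segs = segs[keep],
                                            offs = offs[keep])
    }
  }

  rows <- list()
  for (ri in seq_along(references)) {
    ref <- references[[ri]]
    ref_len <- length(ref)
    ref_kmers <- aa_kmers(as.character(ref))
    for (fr in frames) {
      hsps <- list()
      for (k in seq_along(fr$segs)) {
        if (sum(aa_kmers(fr$segs[k]) %in% ref_kmers) < 2L) next
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(fr$segs[k]), ref, type = "local",
          substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
        idy <- Biostrings::pid(aln)
        span <- IRanges::end(Biostrings::subject(aln)) -
          IRanges::start(Biostrings::subject(aln)) + 1L
        if (idy < min_identity || span < min_hsp) next
        hsps[[length(hsps) + 1L]] <- list(
          identity = idy, span = span, score = Biostrings::score(aln),
          sub = c(IRanges::start(Biostrings::subject(aln)),
                  IRanges::end(Biostrings::subject(aln))),
          aa = c(fr$offs[k] + IRanges::start(Biostrings::pattern(aln)) - 1L,
                 fr$offs[k] + IRanges::end(Biostrings::pattern(aln))))
      }
      if (length(hsps) == 0) next
      # union of aligned reference spans
      iv <- IRanges::reduce(IRanges::IRanges(
        vapply(hsps, function(h) h$sub[1], 1L),
        vapply(hsps, function(h) h$sub[2], 1L)))
      cov <- 100 * sum(IRanges::width(iv)) / ref_len
      if (cov < min_coverage) next
      spans <- vapply(hsps, function(h) h$span, 1L)
      idy <- sum(vapply(hsps, function(h) h$identity, 1) * spans) / sum(spans)
      if (idy < min_identity) next
      aa0 <- min(vapply(hsps, function(h) h$aa[1], 1L))
      aa1 <- max(vapply(hsps, function(h) h$aa[2], 1L))
      f <- fr$frame
      nt <- if (f > 0) {
        c((f - 1L) + 3L * aa0, (f - 1L) + 3L * aa1)
      } else {
        c(n - ((-f - 1L) + 3L * aa1), n - ((-f - 1L) + 3L * aa0))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        reference = names(references)[ri], frame = f, identity = idy,
        coverage = cov, score = sum(vapply(hsps, function(h) h$score, 1)),
        aligned_start = nt[1], aligned_end = nt[2], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign a structural class from presence flags
#'
#' Deterministic classification rule: both TIRs with ORF1 and transposase
#' is `AUTONOMOUS`; both TIRs with only one coding region is `DEF_NO_ORF1`
#' or `DEF_NO_TPASE`; both TIRs without coding is `MITE_LIKE` when the
#' element is at most `mite_max_len` bases, otherwise `DEF_NO_CODING`;
#' exactly one TIR is `DEF_ONE_TIR`; no TIR with coding evidence is
#' `DEF_NO_TIR_FRAGMENT`. No TIR and no coding evidence is unclassifiable
#' and returns `NA`.
#'
#' All arguments are vectorized.
#'
#' @param has_left_tir,has_right_tir,has_orf1,has_tpase logical flags.
#' @param length element length in bases.
#' @param mite_max_len MITE length ceiling (default 800; observed miniature
#'   copies are mostly 200-300 bp, the headroom avoids absorbing 1-2 kb
#'   defective copies).
#' @return Character vector of class names.
#' @export
#' @examples
#' classify_element(TRUE, TRUE, TRUE, TRUE, 5053)   # AUTONOMOUS
#' classify_element(TRUE, TRUE, FALSE, FALSE, 250)  # MITE_LIKE
classify_element <- function(has_left_tir, has_right_tir, has_orf1,
                             has_tpase, length, mite_max_len = 800L) {
  k <- max(lengths(list(has_left_tir, has_right_tir, has_orf1, has_tpase,
                        length)))
  df <- data.frame(lt = rep_len(has_left_tir, k),
                   rt = rep_len(has_right_tir, k),
                   o1 = rep_len(has_orf1, k), tp = rep_len(has_tpase, k),
                   len = rep_len(length, k))
  with(df, ifelse(lt & rt,
    ifelse(o1 & tp, "AUTONOMOUS",
      ifelse(tp, "DEF_NO_ORF1",
        ifelse(o1, "DEF_NO_TPASE",
          ifelse(len <= mite_max_len, "MITE_LIKE", "DEF_NO_CODING")))),
    ifelse(xor(lt, rt), "DEF_ONE_TIR",
      ifelse(o1 | tp, "DEF_NO_TIR_FRAGMENT", NA_character_))))
}

#' Per-class length histogram
#'
#' Bins element lengths into `[k * bin_width, (k + 1) * bin_width)`
#' intervals per structural class, the usual way length distributions of
#' element inventories are summarized.
#'
#' @param annotations data.frame with `class` and `length` columns.
#' @param bin_width bin width in bases (default 1000).
#' @return data.frame `class`, `bin_start`, `bin_end`, `count`; counts per
#'   class sum to the class totals.
#' @export
length_histogram <- function(annotations, bin_width = 1000L) {
  if (is.null(annotations) || nrow(annotations) == 0)
    return(data.frame(class = character(), bin_start = integer(),
                      bin_end = integer(), count = integer()))
  bin <- floor(annotations$length / bin_width)
  tab <- as.data.frame(table(class = annotations$class, bin = bin),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  out <- data.frame(class = tab$class,
                    bin_start = as.integer(tab$bin) * bin_width,
                    bin_end = (as.integer(tab$bin) + 1L) * bin_width,
                    count = tab$Freq, stringsAsFactors = FALSE)
  out <- out[order(out$class, out$bin_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
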