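#' Pairwise identity between two sequences
#'
#' Global (Needleman-Wunsch) alignment; identity is the fraction of
#' matching columns among alignment columns after terminal gaps are
#' trimmed, and coverage is the fraction of each sequence falling inside
#' the trimmed alignment. DNA alignments use match +1 / mismatch -1 with
#' gap open 5 / extend 2; protein alignments use BLOSUM62 with gap open
#' 11 / extend 1.
#'
#' @param seq_a,seq_b sequences (character, DNAString or AAString).
#' @param level `"dna"`, `"protein_orf1"` or `"protein_tpase"`; any
#'   `protein_*` value aligns as protein.
#' @return One-row data.frame: `level`, `identity` (percent),
#'   `aligned_length` (columns after trimming), `coverage_a`, `coverage_b`
#'   (percent).
#' @export
#' @examples
#' pairwise_identity("ACGT", "ACGA")$identity  # 75
pairwise_identity <- function(seq_a, seq_b, level = "dna") {
  a <- as.character(seq_a)
  b <- as.character(seq_b)
  if (nchar(a) == 0 || nchar(b) == 0) stopf("sequences must be non-empty")
  protein <- grepl("^protein", level)
  if (protein) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
  }
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  both <- which(pa != "-" & pb != "-")
  if (length(both) == 0) {
    return(data.frame(level = level, identity = 0, aligned_length = 0L,
                      coverage_a = 0, coverage_b = 0))
  }
  cols <- both[1]:both[length(both)]  # trim terminal gap columns
  ident <- 100 * sum(pa[cols] == pb[cols] & pa[cols] != "-") / length(cols)
  data.frame(level = level, identity = ident,
             aligned_length = length(cols),
             coverage_a = 100 * sum(pa[cols] != "-") / nchar(a),
             coverage_b = 100 * sum(pb[cols] != "-") / nchar(b),
             stringsAsFactors = FALSE)
}

#' Cluster elements into families with the 80-80-80 rule
#'
#' Two copies are "same family" when their pairwise identity is at least
#' `min_identity` percent, coverage of both sequences is at least
#' `min_coverage` percent, and at least `min_aligned` columns align.
#' Families are the single-linkage closure of that relation (the rule is
#' stated pairwise); complete linkage is available for stricter grouping.
#' Family labels are deterministic: clusters are numbered by their
#' smallest member (first in sorted name order).
#'
#' @param seqs named character vector or XStringSet of element (or
#'   protein) sequences.
#' @param min_identity,min_coverage,min_aligned the three 80s of the rule.
#' @param level alignment level passed to [pairwise_identity()].
#' @param linkage `"single"` (default) or `"complete"`.
#' @return data.frame `element_id`, `family` (labels `F1`, `F2`, ...);
#'   the long table of pairwise identity records is attached as
#'   `attr(, "identities")`.
#' @export
#' @examples
#' cluster_families(c(a = "ACGTACGTACGT", b = "ACGTACGTACGT"),
#'                  min_aligned = 10)
cluster_families <- function(seqs, min_identity = 80, min_coverage = 80,
                             min_aligned = 80, level = "dna",
                             linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  seqs <- setNames(as.character(seqs), names(seqs))
  n <- length(seqs)
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    names(seqs) <- paste0("seq", seq_len(n))
  ids <- names(seqs)
  recs <- list()
  same <- matrix(FALSE, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        r <- pairwise_identity(seqs[[i]], seqs[[j]], level)
        r$element_a <- ids[i]
        r$element_b <- ids[j]
        recs[[length(recs) + 1L]] <- r
        same[i, j] <- same[j, i] <-
          r$identity >= min_identity && r$coverage_a >= min_coverage &&
          r$coverage_b >= min_coverage && r$aligned_length >= min_aligned
      }
    }
  }
  # union-find over the "same family" relation
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (linkage == "single") {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j > i && same[i, j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
    comp <- vapply(seq_len(n), find, 1L)
  } else {
    # complete linkage: merge clusters only when every cross pair agrees
    comp <- seq_len(n)
    repeat {
      merged <- FALSE
      cl <- unique(comp)
      for (x in cl) for (y in cl) {
        if (y <= x) next
        mi <- which(comp == x); mj <- which(comp == y)
        if (all(same[mi, mj])) {
          comp[comp == y] <- x
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
  }
  # deterministic labels: order clusters by their smallest member name
  ord <- order(ids)
  first_seen <- comp[ord][!duplicated(comp[ord])]
  fam <- paste0("F", match(comp, first_seen))
  out <- data.frame(element_id = ids, family = fam, stringsAsFactors = FALSE)
  attr(out, "identities") <- if (length(recs)) do.call(rbind, recs) else NULL
  out
}
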