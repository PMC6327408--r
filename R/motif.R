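#' IUPAC motif constructor
#'
#' Validates a degenerate DNA pattern over the IUPAC alphabet. The default
#' is the 19-bp TIR consensus of the element this package targets,
#' `GGGYCYGTTTGGGGCAGCT` (Y = C/T).
#'
#' @param pattern character string of IUPAC DNA codes.
#' @return Object of class `iupac_motif` with fields `pattern` and `length`.
#' @export
#' @examples
#' iupac_motif()          # the TIR consensus
#' iupac_motif("RRYY")
iupac_motif <- function(pattern = PIF_TIR_CONSENSUS) {
  if (!is.character(pattern) || length(pattern) != 1 || nchar(pattern) == 0)
    stopf("pattern must be a single non-empty string")
  pattern <- toupper(pattern)
  codes <- names(Biostrings::IUPAC_CODE_MAP)
  chars <- strsplit(pattern, "")[[1]]
  bad <- setdiff(unique(chars), codes)
  if (length(bad))
    stopf("invalid IUPAC code(s) in motif: %s", paste(bad, collapse = ", "))
  structure(list(pattern = pattern, length = nchar(pattern)),
            class = "iupac_motif")
}

#' @export
print.iupac_motif <- function(x, ...) {
  cat(sprintf("IUPAC motif: %s (%d bp)\n", x$pattern, x$length))
  invisible(x)
}

empty_hits <- function() {
  data.frame(scaffold = character(), start = integer(), end = integer(),
             orientation = character(), matched_seq = character(),
             mismatches = integer(), stringsAsFactors = FALSE)
}

#' Scan a genome for a degenerate motif on both strands
#'
#' Reports every position where the motif matches with at most
#' `max_mismatch` mismatches, in forward orientation or as the reverse
#' complement. Degenerate motif positions match any base of their IUPAC
#' class at zero cost; the mismatch budget applies to the remaining
#' positions. `N` bases in the genome never satisfy a motif position and
#' always consume budget. Overlapping hits are allowed.
#'
#' @param genome [Biostrings::DNAStringSet] (or DNAString / character).
#' @param motif an [iupac_motif()] (or pattern string).
#' @param max_mismatch non-negative mismatch budget.
#' @return data.frame with columns `scaffold`, `start`, `end` (0-based
#'   half-open), `orientation` (`"forward"` / `"reverse"`), `matched_seq`
#'   (genomic sequence as written on the forward strand), `mismatches`;
#'   sorted by scaffold and start.
#' @export
#' @examples
#' scan_motif("AAGGGCCCGTTTGGGGCAGCTAA", max_mismatch = 0)
scan_motif <- function(genome, motif = iupac_motif(), max_mismatch = 2L) {
  if (is.character(motif)) motif <- iupac_motif(motif)
  stopifnot(inherits(motif, "iupac_motif"))
  if (!is.numeric(max_mismatch) || max_mismatch < 0)
    stopf("max_mismatch must be >= 0")
  g <- as_genome(genome)
  pat <- Biostrings::DNAString(motif$pattern)
  pats <- list(forward = pat,
               reverse = Biostrings::reverseComplement(pat))
  rows <- list()
  for (sc in names(g)) {
    subj <- g[[sc]]
    for (ori in names(pats)) {
      m <- Biostrings::matchPattern(pats[[ori]], subj,
                                    max.mismatch = max_mismatch,
                                    fixed = "subject")
      if (length(m) == 0) next
      mm <- Biostrings::neditStartingAt(pats[[ori]], subj,
                                        starting.at = IRanges::start(m),
                                        with.indels = FALSE,
                                        fixed = "subject")
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = sc, start = IRanges::start(m) - 1L, end = IRanges::end(m),
        orientation = ori, matched_seq = as.character(m),
        mismatches = as.integer(mm), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty_hits())
  out <- do.call(rbind, rows)
  out <- out[order(out$scaffold, out$start, out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Discover maximal exact inverted repeats de novo
#'
#' Finds every pair of substrings (left arm, downstream right arm) such
#' that the left arm equals the reverse complement of the right arm, the
#' arm length is at least `min_match`, the two arms do not overlap, and the
#' overall span (right arm end minus left arm start) does not exceed
#' `max_span`. Pairs are maximal: they cannot be extended on either side
#' while keeping the arms disjoint. Used to screen 10-kb flanking contexts
#' of candidate loci for terminal repeats; the default `min_match` of 12
#' reads the "more than 11-bp matches" screening rule as >= 12.
#'
#' @param region a single DNA sequence.
#' @param min_match minimum arm length (>= 4).
#' @param max_span maximum span in bases.
#' @return data.frame with `left_start`, `left_end`, `right_start`,
#'   `right_end` (0-based half-open), `arm_length`, `span`.
#' @export
discover_inverted_repeats <- function(region, min_match = 12L,
                                      max_span = 30000L) {
  if (!is.numeric(min_match) || min_match < 4)
    stopf("min_match must be >= 4")
  s <- strsplit(toupper(as.character(as_genome(region)[[1]])), "")[[1]]
  n <- length(s)
  empty <- data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      arm_length = integer(), span = integer())
  if (n < 2 * min_match) return(empty)
  comp <- chartr("ACGT", "TGCA", s)
  comp[!s %in% c("A", "C", "G", "T")] <- "?"  # N etc. never pair
  rows <- list()
  # matched base pairs (x, y), x < y, lie on anti-diagonals d = x + y
  # (0-based); maximal runs along a diagonal are maximal inverted repeats
  for (d in seq.int(2L * min_match - 1L, 2L * n - 3L)) {
    x_lo <- max(0L, d - n + 1L)
    x_hi <- (d - 1L) %/% 2L          # enforce x < y, arms disjoint
    if (x_hi - x_lo + 1L < min_match) next
    x <- x_lo:x_hi
    ok <- s[x + 1L] == comp[d - x + 1L]
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values & r$lengths >= min_match)
    for (k in keep) {
      x0 <- x[starts[k]]
      x1 <- x[ends[k]]
      span <- d - 2L * x0 + 1L
      if (span > max_span) next
      rows[[length(rows) + 1L]] <- c(x0, x1 + 1L, d - x1, d - x0 + 1L,
                                     x1 - x0 + 1L, span)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("left_start", "left_end", "right_start", "right_end",
                  "arm_length", "span")
  out <- out[order(out$left_start, out$right_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
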