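#' Extract and validate a target-site duplication
#'
#' Reads the `tsd_len` bases immediately upstream of `left_start` and
#' immediately downstream of `right_end` and reports whether they are
#' identical — the signature a cut-and-paste insertion leaves behind. An
#' element flush against a scaffold edge gets sentinel `"NNN"` flanks and
#' `tsd_valid = FALSE`.
#'
#' @param genome genome sequence(s); see [scan_motif()].
#' @param left_start,right_end 0-based half-open element bounds.
#' @param tsd_len duplication length (default 3).
#' @param scaffold scaffold name when `genome` has several sequences.
#' @return List with `tsd_left`, `tsd_right`, `tsd_valid`.
#' @export
#' @examples
#' extract_tsd("GGTTACCCCTTAGG", left_start = 5, right_end = 9)
extract_tsd <- function(genome, left_start, right_end, tsd_len = 3L,
                        scaffold = NULL) {
  g <- as_genome(genome)
  sc <- if (is.null(scaffold)) 1L else scaffold
  seq <- as.character(g[[sc]])
  n <- nchar(seq)
  sentinel <- strrep("N", tsd_len)
  if (left_start < tsd_len || right_end + tsd_len > n)
    return(list(tsd_left = sentinel, tsd_right = sentinel, tsd_valid = FALSE))
  tl <- substr(seq, left_start - tsd_len + 1L, left_start)
  tr <- substr(seq, right_end + 1L, right_end + tsd_len)
  list(tsd_left = tl, tsd_right = tr, tsd_valid = identical(tl, tr))
}

empty_candidates <- function() {
  data.frame(scaffold = character(), left_start = integer(),
             left_end = integer(), right_start = integer(),
             right_end = integer(), span = integer(),
             tsd_left = character(), tsd_right = character(),
             tsd_valid = logical(), stringsAsFactors = FALSE)
}

#' Pair opposite-orientation TIR hits into candidate elements
#'
#' Greedily pairs each forward motif hit, scanned left to right, with a
#' downstream reverse-complement hit so that the span (right hit end minus
#' left hit start) lies in `[min_span, max_span]`. Each hit is used at most
#' once. Among the legal partners of a forward hit, pairings whose flanks
#' form a valid target-site duplication are preferred; remaining ties are
#' broken by smallest span, then leftmost right TIR.
#'
#' @param hits data.frame from [scan_motif()].
#' @param genome the scanned genome (needed for TSD extraction).
#' @param max_span maximum element span in bases (default 30000, the
#'   maximum length allowed between two TIRs).
#' @param min_span minimum span (default 50).
#' @param tsd_len TSD length (default 3).
#' @return data.frame of candidate elements: `scaffold`, `left_start`,
#'   `left_end`, `right_start`, `right_end`, `span`, `tsd_left`,
#'   `tsd_right`, `tsd_valid` (0-based half-open).
#' @export
pair_tirs <- function(hits, genome, max_span = 30000L, min_span = 50L,
                      tsd_len = 3L) {
  if (max_span <= 0 || min_span <= 0) stopf("spans must be positive")
  if (nrow(hits) == 0) return(empty_candidates())
  g <- as_genome(genome)
  out <- list()
  for (sc in unique(hits$scaffold)) {
    h <- hits[hits$scaffold == sc, , drop = FALSE]
    fwd <- h[h$orientation == "forward", , drop = FALSE]
    rev <- h[h$orientation == "reverse", , drop = FALSE]
    fwd <- fwd[order(fwd$start), , drop = FALSE]
    rev <- rev[order(rev$start), , drop = FALSE]
    used <- rep(FALSE, nrow(rev))
    for (i in seq_len(nrow(fwd))) {
      span <- rev$end - fwd$start[i]
      legal <- which(!used & rev$start >= fwd$end[i] &
                       span >= min_span & span <= max_span)
      if (length(legal) == 0) next
      tsds <- lapply(legal, function(j)
        extract_tsd(g, fwd$start[i], rev$end[j], tsd_len, scaffold = sc))
      valid <- vapply(tsds, `[[`, TRUE, "tsd_valid")
      pool <- if (any(valid)) legal[valid] else legal
      # smallest span, then leftmost right TIR
      j <- pool[order(span[pool], rev$start[pool])][1]
      tsd <- tsds[[match(j, legal)]]
      used[j] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        scaffold = sc, left_start = fwd$start[i], left_end = fwd$end[i],
        right_start = rev$start[j], right_end = rev$end[j],
        span = rev$end[j] - fwd$start[i],
        tsd_left = tsd$tsd_left, tsd_right = tsd$tsd_right,
        tsd_valid = tsd$tsd_valid, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty_candidates())
  res <- do.call(rbind, out)
  res <- res[order(res$scaffold, res$left_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Mine a genome for elements of the target families
#'
#' Full recovery stage of the pipeline. TIR motif hits locate element
#' termini; the family-specific sub-terminal blocks (the display-primer
#' landing sites, retained by defective copies) are scanned as additional
#' anchors so that copies that have lost one or both TIRs are still
#' recovered with exact bounds — this stands in for whole-element homology
#' mapping. Matching 5'/3' sub-terminal anchors of the same family are
#' paired greedily left to right; element bounds extend over immediately
#' adjacent TIR hits; coding evidence is collected by translated alignment
#' and each element is classified structurally.
#'
#' @param genome genome sequence(s).
#' @param templates family templates ([element_templates()]).
#' @param references reference proteins ([pif_references()]`$protein`).
#' @param max_span maximum element span (default 30000).
#' @param tir_max_mismatch mismatch budget for the 19-bp TIR motif.
#' @param anchor_max_mismatch mismatch budget for the 60-bp sub-terminal
#'   anchors (default 6, i.e. 10% divergence).
#' @param min_identity,min_coverage coding-evidence thresholds (percent).
#' @param mite_max_len length ceiling for the MITE-like call.
#' @param tsd_len TSD length.
#' @return data.frame of element annotations: `element_id`, `scaffold`,
#'   `start`, `end`, `length`, `family`, `has_left_tir`, `has_right_tir`,
#'   `has_orf1`, `has_tpase`, `class`, `tsd_left`, `tsd_right`, `tsd_valid`.
#' @export
mine_elements <- function(genome, templates = element_templates(),
                          references = pif_references()$protein,
                          max_span = 30000L, tir_max_mismatch = 2L,
                          anchor_max_mismatch = 6L, min_identity = 30,
                          min_coverage = 50, mite_max_len = 800L,
                          tsd_len = 3L) {
  g <- as_genome(genome)
  tir_len <- nchar(templates[[1]]$tir)
  tir_hits <- scan_motif(g, iupac_motif(), tir_max_mismatch)

  anchors <- list()
  for (fam in names(templates)) {
    for (side in c("sub5", "sub3")) {
      h <- scan_motif(g, iupac_motif(templates[[fam]][[side]]),
                      anchor_max_mismatch)
      h <- h[h$orientation == "forward", , drop = FALSE]
      if (nrow(h)) {
        h$family <- fam
        h$side <- side
        anchors[[length(anchors) + 1L]] <- h
      }
    }
  }
  cols <- c("element_id", "scaffold", "start", "end", "length", "family",
            "has_left_tir", "has_right_tir", "has_orf1", "has_tpase",
            "class", "tsd_left", "tsd_right", "tsd_valid")
  if (length(anchors) == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    return(out)
  }
  anchors <- do.call(rbind, anchors)

  rows <- list()
  for (sc in unique(anchors$scaffold)) {
    a <- anchors[anchors$scaffold == sc, , drop = FALSE]
    th <- tir_hits[tir_hits$scaffold == sc, , drop = FALSE]
    a5 <- a[a$side == "sub5", , drop = FALSE]
    a3 <- a[a$side == "sub3", , drop = FALSE]
    a5 <- a5[order(a5$start), , drop = FALSE]
    a3 <- a3[order(a3$start), , drop = FALSE]
    used3 <- rep(FALSE, nrow(a3))
    for (i in seq_len(nrow(a5))) {
      legal <- which(!used3 & a3$family == a5$family[i] &
                       a3$start >= a5$end[i] &
                       a3$end - a5$start[i] <= max_span)
      if (length(legal) == 0) next
      j <- legal[which.min(a3$start[legal])]
      used3[j] <- TRUE
      # element bounds: adjacent TIRs extend the anchor pair outward
      left_tir <- any(th$orientation == "forward" & th$end == a5$start[i])
      right_tir <- any(th$orientation == "reverse" & th$start == a3$end[j])
      start <- if (left_tir) a5$start[i] - tir_len else a5$start[i]
      end <- if (right_tir) a3$end[j] + tir_len else a3$end[j]
      rows[[length(rows) + 1L]] <- list(
        scaffold = sc, start = start, end = end,
        family = a5$family[i], has_left_tir = left_tir,
        has_right_tir = right_tir)
    }
  }
  if (length(rows) == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    return(out)
  }
  ann <- do.call(rbind, lapply(rows, as.data.frame))
  ann <- ann[order(ann$scaffold, ann$start), , drop = FALSE]
  ann$length <- ann$end - ann$start
  ann$element_id <- sprintf("PIFM_%03d", seq_len(nrow(ann)))

  ann$has_orf1 <- FALSE
  ann$has_tpase <- FALSE
  ann$tsd_left <- ann$tsd_right <- NA_character_
  ann$tsd_valid <- FALSE
  for (i in seq_len(nrow(ann))) {
    eseq <- substr(as.character(g[[ann$scaffold[i]]]),
                   ann$start[i] + 1L, ann$end[i])
    ev <- detect_coding(eseq, references, min_identity, min_coverage)
    ann$has_orf1[i] <- any(grepl("^orf1", ev$reference))
    ann$has_tpase[i] <- any(grepl("^tpase", ev$reference))
    tsd <- extract_tsd(g, ann$start[i], ann$end[i], tsd_len,
                       scaffold = ann$scaffold[i])
    ann$tsd_left[i] <- tsd$tsd_left
    ann$tsd_right[i] <- tsd$tsd_right
    ann$tsd_valid[i] <- tsd$tsd_valid
  }
  ann$class <- classify_element(ann$has_left_tir, ann$has_right_tir,
                                ann$has_orf1, ann$has_tpase, ann$length,
                                mite_max_len)
  rownames(ann) <- NULL
  ann[, cols]
}
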