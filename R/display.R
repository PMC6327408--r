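#' Restriction digest of a genome
#'
#' Cuts every scaffold at each occurrence of the recognition site,
#' `cut_offset` bases into the site. The default is BfaI (`C^TAG`):
#' site `CTAG`, cut after the first base. The returned fragments tile each
#' scaffold, so their concatenation reconstructs it exactly; a scaffold
#' without the site yields a single spanning fragment.
#'
#' @param genome genome sequence(s).
#' @param site non-degenerate recognition sequence.
#' @param cut_offset bases from the site start to the cut point.
#' @param with_sequence include fragment sequences in the result.
#' @return data.frame `scaffold`, `start`, `end` (0-based half-open) and,
#'   if requested, `sequence`.
#' @export
#' @examples
#' digest_genome("AACTAGAA")  # fragments AAC | TAGAA
digest_genome <- function(genome, site = "CTAG", cut_offset = 1L,
                          with_sequence = TRUE) {
  if (grepl("[^ACGT]", toupper(site)))
    stopf("site must be non-degenerate DNA")
  if (cut_offset < 0 || cut_offset > nchar(site))
    stopf("cut_offset must be within the site")
  g <- as_genome(genome)
  rows <- list()
  for (sc in names(g)) {
    cuts <- cut_positions(g[[sc]], site, cut_offset)
    bounds <- c(0L, cuts, length(g[[sc]]))
    start <- bounds[-length(bounds)]
    end <- bounds[-1]
    df <- data.frame(scaffold = sc, start = start, end = end,
                     stringsAsFactors = FALSE)
    if (with_sequence) {
      seq <- as.character(g[[sc]])
      df$sequence <- substring(seq, start + 1L, end)
    }
    rows[[length(rows) + 1L]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# 0-based cut coordinates within one scaffold
cut_positions <- function(subject, site, cut_offset) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(site), subject)
  sort(IRanges::start(m) - 1L + as.integer(cut_offset))
}

# the selective dinucleotides used in the published assay (8 of 16)
PIF_NN_DEFAULT <- c("AA", "AT", "AC", "AG", "CA", "CT", "CC", "CG")

#' Simulate a transposon display profile
#'
#' Models the banding readout of a transposon display assay: the genome is
#' digested ([digest_genome()]), adapters are ligated at every cut, and a
#' family-specific primer annealing in the element sub-terminal region is
#' extended outward to the nearest cut site. Each amplicon's length is the
#' primer-to-cut distance plus `adapter_len`; it is binned by the two
#' genomic bases immediately interior to the cut site (the bases the `+NN`
#' selective adapter primer reads). Amplicons outside the gel window are
#' dropped, as are those whose dinucleotide is not in `nn_set`. Forward
#' primer matches extend rightward, reverse-complement matches leftward,
#' so an intact element can yield up to two bands per family primer.
#'
#' @param genome genome sequence(s).
#' @param primer family-specific primer (character); see
#'   `element_templates()$A$primer`.
#' @param sample_id label stored in the profile.
#' @param family optional family label.
#' @param nn_set selective dinucleotides scored (default: the 8 used in
#'   the published assay; all 16 are supported).
#' @param window gel window `c(min, max)` in bases (default 50-700).
#' @param adapter_len adapter contribution to amplicon length.
#' @param primer_max_mismatch mismatch tolerance for primer annealing
#'   (default 0 = exact).
#' @param site,cut_offset restriction enzyme (default BfaI `C^TAG`).
#' @return Object of class `display_profile`: list with `sample_id`,
#'   `family`, `primer`, `window`, `nn_set` and `bands` (data.frame
#'   `NN`, `length`, `scaffold`, `position`, `direction`).
#' @export
simulate_display <- function(genome, primer, sample_id = "sample",
                             family = NA_character_,
                             nn_set = PIF_NN_DEFAULT, window = c(50, 700),
                             adapter_len = 20L, primer_max_mismatch = 0L,
                             site = "CTAG", cut_offset = 1L) {
  g <- as_genome(genome)
  if (!is.character(primer) || nchar(primer) == 0)
    stopf("primer must be a non-empty DNA string")
  p <- Biostrings::DNAString(primer)
  bands <- list()
  n_matches <- 0L
  for (sc in names(g)) {
    subj <- g[[sc]]
    seq <- as.character(subj)
    cuts <- cut_positions(subj, site, cut_offset)
    fwd <- Biostrings::matchPattern(p, subj,
                                    max.mismatch = primer_max_mismatch)
    rev <- Biostrings::matchPattern(Biostrings::reverseComplement(p), subj,
                                    max.mismatch = primer_max_mismatch)
    n_matches <- n_matches + length(fwd) + length(rev)
    for (k in seq_along(fwd)) {
      s <- IRanges::start(fwd)[k] - 1L
      e <- IRanges::end(fwd)[k]
      after <- cuts[cuts >= e]
      if (length(after) == 0) next  # runs off the scaffold
      cc <- after[1]
      if (cc < 2) next
      nn <- substr(seq, cc - 1L, cc)
      bands[[length(bands) + 1L]] <- data.frame(
        NN = nn, length = (cc - s) + adapter_len, scaffold = sc,
        position = s, direction = "right", stringsAsFactors = FALSE)
    }
    for (k in seq_along(rev)) {
      s <- IRanges::start(rev)[k] - 1L
      e <- IRanges::end(rev)[k]
      before <- cuts[cuts <= s]
      if (length(before) == 0) next
      cc <- before[length(before)]
      if (cc + 2L > nchar(seq)) next
      nn <- rc_chr(substr(seq, cc + 1L, cc + 2L))
      bands[[length(bands) + 1L]] <- data.frame(
        NN = nn, length = (e - cc) + adapter_len, scaffold = sc,
        position = s, direction = "left", stringsAsFactors = FALSE)
    }
  }
  if (n_matches == 0) warning("primer not found in genome; empty profile")
  bands <- if (length(bands)) do.call(rbind, bands) else
    data.frame(NN = character(), length = integer(), scaffold = character(),
               position = integer(), direction = character(),
               stringsAsFactors = FALSE)
  bands <- bands[bands$NN %in% nn_set &
                   bands$length >= window[1] & bands$length <= window[2], ,
                 drop = FALSE]
  bands <- bands[order(bands$NN, bands$length), , drop = FALSE]
  rownames(bands) <- NULL
  structure(list(sample_id = sample_id, family = family,
                 primer = primer, window = window, nn_set = nn_set,
                 bands = bands),
            class = "display_profile")
}

#' @export
print.display_profile <- function(x, ...) {
  cat(sprintf("display profile '%s' (family %s): %d bands in window %d-%d\n",
              x$sample_id, x$family, nrow(x$bands), x$window[1], x$window[2]))
  invisible(x)
}

#' Call differential bands between display profiles
#'
#' A band (selective dinucleotide, fragment length) is differential when
#' it is present in some samples and absent in others; bands shared by all
#' samples, like bands absent from all, are not reported. Lengths within
#' `tolerance` bases are treated as the same band.
#'
#' @param profiles list of `display_profile` objects (same family primer).
#' @param tolerance length-matching tolerance in bases (default 0).
#' @return data.frame `family`, `NN`, `length` plus one logical presence
#'   column per sample (`present.<sample_id>`).
#' @export
diff_profiles <- function(profiles, tolerance = 0L) {
  if (length(profiles) < 2) stopf("need at least two profiles")
  fams <- vapply(profiles, function(p) as.character(p$family), "")
  prms <- vapply(profiles, `[[`, "", "primer")
  if (length(unique(prms)) != 1 || length(unique(fams)) != 1)
    stopf("profiles must share the same family primer")
  samples <- vapply(profiles, `[[`, "", "sample_id")
  if (anyDuplicated(samples)) stopf("sample ids must be unique")
  all_bands <- unique(do.call(rbind, lapply(profiles, function(p)
    unique(p$bands[, c("NN", "length")]))))
  if (is.null(all_bands) || nrow(all_bands) == 0) {
    out <- data.frame(family = character(), NN = character(),
                      length = integer())
    for (s in samples) out[[paste0("present.", s)]] <- logical(0)
    return(out)
  }
  # collapse lengths within tolerance per dinucleotide
  all_bands <- all_bands[order(all_bands$NN, all_bands$length), , drop = FALSE]
  keep <- rep(TRUE, nrow(all_bands))
  if (tolerance > 0 && nrow(all_bands) > 1) {
    for (i in 2:nrow(all_bands)) {
      if (all_bands$NN[i] == all_bands$NN[i - 1] &&
          all_bands$length[i] - all_bands$length[i - 1] <= tolerance &&
          keep[i - 1])
        keep[i] <- FALSE
    }
  }
  ref <- all_bands[keep, , drop = FALSE]
  pres <- sapply(profiles, function(p) {
    vapply(seq_len(nrow(ref)), function(i) {
      b <- p$bands
      any(b$NN == ref$NN[i] & abs(b$length - ref$length[i]) <= tolerance)
    }, TRUE)
  })
  pres <- matrix(pres, nrow = nrow(ref))
  colnames(pres) <- paste0("present.", samples)
  differential <- rowSums(pres) > 0 & rowSums(pres) < length(profiles)
  out <- cbind(data.frame(family = fams[1], NN = ref$NN,
                          length = ref$length, stringsAsFactors = FALSE),
               as.data.frame(pres))
  out <- out[differential, , drop = FALSE]
  rownames(out) <- NULL
  out
}
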