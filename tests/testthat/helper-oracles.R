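# Independent reference implementations used as oracles. All are naive,
# pure-R routes kept deliberately separate from the package internals.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

rc_oracle <- function(x) {
  paste(rev(strsplit(chartr("ACGTRYKMBVDHN", "TGCAYRMKVBHDN", x), "")[[1]]),
        collapse = "")
}

# exhaustive sliding-window degenerate scan, both orientations
oracle_scan <- function(seq, pattern, max_mismatch) {
  count_mm <- function(window, pat) {
    sum(vapply(seq_along(pat), function(i)
      !(window[i] %in% IUPAC_SETS[[pat[i]]]), TRUE))
  }
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  rows <- list()
  for (ori in c("forward", "reverse")) {
    p <- if (ori == "forward") pattern else rc_oracle(pattern)
    pat <- strsplit(p, "")[[1]]
    L <- length(pat)
    if (n >= L) {
      for (off in 0:(n - L)) {
        mm <- count_mm(chars[(off + 1):(off + L)], pat)
        if (mm <= max_mismatch)
          rows[[length(rows) + 1L]] <- data.frame(
            start = off, end = off + L, orientation = ori,
            mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(start = integer(), end = integer(),
                      orientation = character(), mismatches = integer()))
  out <- do.call(rbind, rows)
  out[order(out$start, out$orientation), , drop = FALSE]
}

# naive maximal inverted repeats: walk every candidate run start
oracle_inverted_repeats <- function(seq, min_match, max_span) {
  s <- strsplit(seq, "")[[1]]
  comp <- chartr("ACGT", "TGCA", s)
  n <- length(s)
  rows <- list()
  for (x in 1:(n - 1)) {
    for (y in (x + 1):n) {
      if (s[x] != comp[y]) next
      if (x > 1 && y < n && s[x - 1] == comp[y + 1]) next  # not a run start
      L <- 0L
      while (x + L < y - L && s[x + L] == comp[y - L]) L <- L + 1L
      if (L < min_match) next
      span <- y - x + 1L
      if (span > max_span) next
      rows[[length(rows) + 1L]] <- data.frame(
        left_start = x - 1L, left_end = x - 1L + L,
        right_start = y - L, right_end = y, arm_length = L, span = span)
    }
  }
  if (length(rows) == 0)
    return(data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      arm_length = integer(), span = integer()))
  out <- do.call(rbind, rows)
  out <- out[order(out$left_start, out$right_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force digest boundaries via base-R string search
oracle_digest_bounds <- function(seq, site = "CTAG", cut_offset = 1L) {
  hits <- gregexpr(site, seq, fixed = TRUE)[[1]]
  cuts <- if (hits[1] == -1) integer(0) else as.integer(hits) - 1L + cut_offset
  c(0L, cuts, nchar(seq))
}

# brute-force genic context for one element against all genes
oracle_context <- function(es, ee, genes, exons) {
  ov <- function(a0, a1, b0, b1) a0 < b1 && b0 < a1
  exon_genes <- character(0)
  span_genes <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    in_exon <- any(vapply(seq_len(nrow(ex)), function(j)
      ov(es, ee, ex$start[j], ex$end[j]), TRUE))
    if (in_exon) exon_genes <- c(exon_genes, g$gene_id)
    if (ov(es, ee, g$start, g$end)) span_genes <- c(span_genes, g$gene_id)
  }
  if (length(exon_genes)) return(list(context = "exon"))
  if (length(span_genes)) return(list(context = "intron"))
  d <- pmax(pmax(genes$start - ee, es - genes$end), 0)
  list(context = "intergenic", distance = min(d))
}

# transitive closure of the same-family relation, via boolean powers
oracle_closure_partition <- function(ids, same) {
  n <- length(ids)
  reach <- same | diag(n) > 0
  repeat {
    nxt <- (reach %*% reach) > 0
    if (all(nxt == reach)) break
    reach <- nxt
  }
  comp <- apply(reach, 1, function(r) min(which(r)))
  unname(split(ids, comp))
}

# canonical form of a partition for comparison
canon_partition <- function(groups) {
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, `[`, "", 1))]
}

# random DNA helper for fixtures built in tests
rand_seq <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# random DNA guaranteed to avoid a given substring
rand_seq_without <- function(n, avoid) {
  repeat {
    x <- rand_seq(n)
    if (!any(vapply(avoid, function(a) grepl(a, x, fixed = TRUE), TRUE)))
      return(x)
  }
}
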