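# internal helpers shared across modules

# reverse complement of a plain character string
rc_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# random DNA string of length n with expected GC fraction `gc`
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# run `expr` under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# normalize genome input to a named DNAStringSet
as_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    g <- genome
  } else if (is(genome, "DNAString")) {
    g <- Biostrings::DNAStringSet(genome)
  } else if (is.character(genome)) {
    g <- Biostrings::DNAStringSet(genome)
  } else {
    stop("genome must be a DNAStringSet, DNAString or character vector")
  }
  if (is.null(names(g))) names(g) <- paste0("seq", seq_along(g))
  g
}

# apply random substitutions at the given per-site rate; returns character
mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  k <- stats::rbinom(1, n, rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  chars[pos] <- vapply(chars[pos],
                       function(b) sample(setdiff(bases, b), 1), "",
                       USE.NAMES = FALSE)
  paste(chars, collapse = "")
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
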