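#' Reference ORF1 and transposase sequences
#'
#' Loads the packaged coding-sequence fixtures for the two element families
#' (A and B) and returns both the CDS and the translated proteins. The
#' fixtures are synthetic stand-ins constructed at the published divergence
#' levels between the two families (about 51.5% amino-acid identity for the
#' transposase and 37.5% for ORF1); they are intronless by design. ORF1 is
#' 272 aa and the transposase 427 aa, matching the element anatomy the
#' package models.
#'
#' @return A list with elements `cds` (a [Biostrings::DNAStringSet] of four
#'   coding sequences, stop codon included) and `protein` (the corresponding
#'   [Biostrings::AAStringSet], stop removed). Names are
#'   `orf1_pepif1a`, `tpase_pepif1a`, `orf1_pepif1b`, `tpase_pepif1b`.
#' @export
#' @examples
#' refs <- pif_references()
#' Biostrings::width(refs$protein)
pif_references <- function() {
  path <- system.file("extdata", "synthetic_pepif1_cds.fna",
                      package = "pifminer", mustWork = TRUE)
  cds <- Biostrings::readDNAStringSet(path)
  prot <- Biostrings::translate(cds)
  # strip terminal stop
  prot <- Biostrings::AAStringSet(sub("\\*$", "", as.character(prot)))
  list(cds = cds, protein = prot)
}

# fixed family-specific sub-terminal blocks and display primers.
# sub5 carries the reverse complement of the display primer (so the primer
# anneals facing outward across the left TIR); sub3 carries the primer in
# forward orientation. None of these contain a BfaI site (CTAG).
PIF_SUBTERMINALS <- list(
  A = list(
    primer = "ACGTATATTCTTCTCAGGTT",
    sub5 = "AGTGTGCAAGTGTATGCCCCAACCTGAGAAGAATATACGTTAGTTTGGTAGGTGGCAAAA",
    sub3 = "ATTGGACATATTACAGGTATACGTATATTCTTCTCAGGTTTTTAGCCCGAGCTGACAGCA"),
  B = list(
    primer = "CCGAGAGTGAGCAATTACGT",
    sub5 = "TATCCATGTCATTGTCCGCAACGTAATTGCTCACTCTCGGCTTCTGTATGGTGACCTTTA",
    sub3 = "CTTCTGGAGAGGGGTGGACGCCGAGAGTGAGCAATTACGTAAATTCGATGACGCGCTACG")
)

# spacer lengths chosen so family-A autonomous elements are 5053 bp
# (the reported full length) and family-B elements fall in the 6-8 kb range
PIF_SPACER_LEN <- list(A = c(1000L, 800L, 992L), B = c(1500L, 1400L, 1500L))

#' Family element templates
#'
#' Builds the deterministic sequence templates for families A and B. Each
#' template carries the 19-bp TIR (degenerate Y positions resolved to C; the
#' two families share the same TIR), 60-bp family-specific sub-terminal
#' blocks containing the transposon-display primer landing sites, the ORF1
#' and transposase coding sequences, and fixed internal spacers. Spacers are
#' generated from a fixed internal seed so that copies of the same family
#' are identical before mutation, as family clustering presumes.
#'
#' @return Named list (`A`, `B`). Each template is a list with fields
#'   `family`, `tir` (19-base string), `sub5`, `sub3` (60-base strings),
#'   `primer` (20-base display primer), `orf1_cds`, `tpase_cds`, and
#'   `spacers` (three internal spacer strings).
#' @export
#' @examples
#' tpl <- element_templates()
#' nchar(build_element(tpl$A, "AUTONOMOUS"))  # 5053
element_templates <- function() {
  refs <- pif_references()
  out <- lapply(c(A = "A", B = "B"), function(fam) {
    sub <- PIF_SUBTERMINALS[[fam]]
    lens <- PIF_SPACER_LEN[[fam]]
    spacers <- with_local_seed(
      7200 + match(fam, c("A", "B")),
      lapply(lens, function(n) random_dna(n, gc = 0.44)))
    suffix <- if (fam == "A") "pepif1a" else "pepif1b"
    list(family = fam,
         tir = gsub("Y", "C", PIF_TIR_CONSENSUS),
         sub5 = sub$sub5, sub3 = sub$sub3, primer = sub$primer,
         orf1_cds = as.character(refs$cds[[paste0("orf1_", suffix)]]),
         tpase_cds = as.character(refs$cds[[paste0("tpase_", suffix)]]),
         spacers = spacers)
  })
  out
}

#' Assemble an element sequence of a given structural class
#'
#' Concatenates template blocks according to the structural class:
#' `AUTONOMOUS` keeps both TIRs, both sub-terminals, ORF1 and the
#' transposase; the `DEF_*` classes drop the corresponding blocks;
#' `MITE_LIKE` keeps TIRs and sub-terminals around a short random spacer so
#' total length falls in 200-300 bp (drawn from the current RNG stream).
#'
#' @param template one family template from [element_templates()].
#' @param class_name one of the structural classes in `PIF_CLASSES`.
#' @return Character string with the element sequence.
#' @export
build_element <- function(template, class_name) {
  class_name <- match.arg(class_name, PIF_CLASSES)
  t <- template
  s <- t$spacers
  rtir <- rc_chr(t$tir)
  switch(class_name,
    AUTONOMOUS = paste0(t$tir, t$sub5, s[[1]], t$orf1_cds, s[[2]],
                        t$tpase_cds, s[[3]], t$sub3, rtir),
    DEF_NO_ORF1 = paste0(t$tir, t$sub5, s[[1]], s[[2]], t$tpase_cds,
                         s[[3]], t$sub3, rtir),
    DEF_NO_TPASE = paste0(t$tir, t$sub5, s[[1]], t$orf1_cds, s[[2]],
                          s[[3]], t$sub3, rtir),
    DEF_NO_CODING = paste0(t$tir, t$sub5, s[[1]], s[[3]], t$sub3, rtir),
    DEF_ONE_TIR = paste0(t$tir, t$sub5, s[[1]], t$orf1_cds, s[[2]],
                         t$tpase_cds, s[[3]], t$sub3),
    DEF_NO_TIR_FRAGMENT = paste0(t$sub5, t$tpase_cds, t$sub3),
    MITE_LIKE = paste0(t$tir, t$sub5,
                       random_dna(sample(42:142, 1), gc = 0.44),
                       t$sub3, rtir)
  )
}
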