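# Standard genetic code (translation table 1). Plant organelles use the
# standard code; RNA editing, not a deviant table, is what rescues their
# ACG starts and creates internal stops.
.GENETIC_CODE_1 <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0)))
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1L]]
  stats::setNames(aas, codons)
})

#' Translate a coding sequence
#'
#' Standard genetic code (translation table 1, overridable). Translation does
#' *not* stop at internal stop codons -- premature stops created by C-to-U
#' editing must remain visible to downstream consequence annotation. A codon
#' containing `N` translates to `X`; a trailing incomplete codon is dropped
#' with a warning.
#'
#' @param cds DNA string, length >= 3.
#' @param code named character vector mapping codons to amino acids
#'   (default: the standard code).
#' @return protein string with `*` for stop codons.
#' @export
translate_cds <- function(cds, code = .GENETIC_CODE_1) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 3L) stop("CDS shorter than one codon")
  if (n %% 3L != 0L) {
    warning("dropping trailing incomplete codon (", n %% 3L, " nt)")
    n <- n - n %% 3L
  }
  starts <- seq(1L, n, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Describe the codon change of a single C-to-T edit
#'
#' @param codon_before 3-mer containing `C` at the edited position.
#' @param codon_position_edited position within the codon (1, 2 or 3).
#' @param code genetic code table.
#' @return a `codon_change` list: codons and amino acids before/after, plus
#'   the edited codon position.
#' @export
codon_change <- function(codon_before, codon_position_edited,
                         code = .GENETIC_CODE_1) {
  codon_before <- toupper(codon_before)
  stopifnot(nchar(codon_before) == 3L, codon_position_edited %in% 1:3)
  if (substr(codon_before, codon_position_edited, codon_position_edited) != "C")
    stop("codon ", codon_before, " has no C at position ", codon_position_edited)
  codon_after <- codon_before
  substr(codon_after, codon_position_edited, codon_position_edited) <- "T"
  aa1 <- unname(code[codon_before]); aa2 <- unname(code[codon_after])
  if (is.na(aa1)) aa1 <- "X"
  if (is.na(aa2)) aa2 <- "X"
  structure(list(codon_before = codon_before, codon_after = codon_after,
                 aa_before = aa1, aa_after = aa2,
                 codon_position_edited = as.integer(codon_position_edited)),
            class = "codon_change")
}
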