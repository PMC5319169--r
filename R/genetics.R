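# Genetic-code tables and small sequence utilities shared by all modules.
# Plant mitochondria use the standard genetic code, so the Biostrings
# GENETIC_CODE table is the single source of truth here.

.NUC <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

#' All 64 codons in lexicographic (A,C,G,T) order
#' @return character vector of length 64
#' @keywords internal
all_codons <- function() {
  if (is.null(.mr_cache$codons64)) {
    g <- expand.grid(p3 = .NUC, p2 = .NUC, p1 = .NUC, stringsAsFactors = FALSE)
    .mr_cache$codons64 <- paste0(g$p1, g$p2, g$p3)
  }
  .mr_cache$codons64
}

#' The 61 sense codons of the standard genetic code
#' @return character vector of length 61
#' @export
sense_codons <- function() {
  if (is.null(.mr_cache$codons61))
    .mr_cache$codons61 <- setdiff(all_codons(), .STOPS)
  .mr_cache$codons61
}

#' Translate a codon (standard genetic code)
#' @param codon character vector of 3-letter codons
#' @return character vector of single-letter amino acids ("*" for stop)
#' @export
codon_aa <- function(codon) {
  if (is.null(.mr_cache$gcode))
    .mr_cache$gcode <- Biostrings::GENETIC_CODE
  unname(.mr_cache$gcode[toupper(codon)])
}

#' Translate an in-frame coding sequence
#'
#' @param cds nucleotide string, length a multiple of 3
#' @param to_stop stop translating at the first stop codon?
#' @return single-letter amino-acid string ("*" marks stops when
#'   `to_stop = FALSE`)
#' @export
translate_cds <- function(cds, to_stop = FALSE) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L)
    stop("coding sequence length ", n, " is not a multiple of 3")
  if (n == 0L) return("")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- codon_aa(codons)
  aa[is.na(aa)] <- "X"
  if (to_stop) {
    hit <- which(aa == "*")
    if (length(hit)) aa <- aa[seq_len(hit[1L] - 1L)]
  }
  paste(aa, collapse = "")
}

#' Reverse complement of a nucleotide string
#' @param x nucleotide string (A/C/G/T/N, case-insensitive)
#' @return reverse-complemented upper-case string
#' @export
revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-")
  ch <- rev(strsplit(toupper(x), "", fixed = TRUE)[[1L]])
  out <- map[ch]
  if (anyNA(out)) stop("non-ACGTN character in sequence")
  paste(out, collapse = "")
}

#' Split an in-frame sequence into codons
#' @param cds nucleotide string with length a multiple of 3
#' @return character vector of codons
#' @export
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("length not a multiple of 3")
  if (n == 0L) return(character())
  substring(toupper(cds), seq(1L, n, 3L), seq(3L, n, 3L))
}

# integer encoding A=1 C=2 G=3 T=4 (0 for anything else)
.encode_nt <- function(x) {
  match(strsplit(toupper(x), "", fixed = TRUE)[[1L]], .NUC, nomatch = 0L)
}

.decode_nt <- function(i) paste(.NUC[i], collapse = "")

# transition pairs (A<->G, C<->T)
.is_transition <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G") & a != b) |
    (a %in% c("C", "T") & b %in% c("C", "T") & a != b)
}
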