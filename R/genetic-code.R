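# Universal genetic code machinery: the 61 sense-codon state space used by
# the codon substitution model, and CDS translation.

.nuc <- c("A", "C", "G", "T")

.codon_tables <- function() {
  if (!is.null(.c4env$codons)) {
    return(.c4env$codons)
  }
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  aa <- unname(gc[codons])
  stopifnot(length(codons) == 61L)

  # single-nucleotide-change classification between sense codons:
  # 0 none/multiple, 1 syn transversion, 2 syn transition,
  # 3 nonsyn transversion, 4 nonsyn transition
  spl <- do.call(rbind, strsplit(codons, ""))
  ctype <- matrix(0L, 61L, 61L, dimnames = list(codons, codons))
  is_transition <- function(x, y) {
    (x == "A" & y == "G") | (x == "G" & y == "A") |
      (x == "C" & y == "T") | (x == "T" & y == "C")
  }
  for (i in seq_len(61L)) {
    diffs <- sweep(spl, 2, spl[i, ], FUN = "!=")
    ndiff <- rowSums(diffs)
    j <- which(ndiff == 1L)
    for (jj in j) {
      pos <- which(diffs[jj, ])
      ts <- is_transition(spl[i, pos], spl[jj, pos])
      syn <- aa[i] == aa[jj]
      ctype[i, jj] <- if (syn) {
        if (ts) 2L else 1L
      } else {
        if (ts) 4L else 3L
      }
    }
  }
  .c4env$codons <- list(codons = codons, aa = aa, ctype = ctype, code = gc)
  .c4env$codons
}

#' Sense codons of the universal genetic code
#'
#' @return Character vector of the 61 stop-free codons, in the fixed order
#'   used throughout the package (alphabetical within `Biostrings::GENETIC_CODE`).
#' @export
sense_codons <- function() .codon_tables()$codons

#' Translate an in-frame coding sequence
#'
#' Translates under the universal genetic code. A terminal stop codon is
#' dropped. An internal stop codon does not abort translation but flags the
#' sequence (attribute `internal_stop`); the scan pipeline excludes groups
#' containing flagged members. Codons with ambiguous or gap characters
#' translate to `X`.
#'
#' @param cds A single nucleotide string, length divisible by 3.
#' @return Protein string with attribute `internal_stop` (logical).
#' @examples
#' translate_cds("ATGGCT")
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length must be divisible by 3, got ", nchar(cds))
  }
  tab <- .codon_tables()
  cod <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  aa <- unname(tab$code[cod])
  aa[is.na(aa)] <- ifelse(grepl("^-+$", cod[is.na(aa)]), "-", "X")
  n <- length(aa)
  internal_stop <- FALSE
  if (n > 0L && aa[n] == "*") {
    aa <- aa[-n]
    n <- n - 1L
  }
  if (any(aa == "*")) {
    internal_stop <- TRUE
    aa[aa == "*"] <- "X"
  }
  out <- paste(aa, collapse = "")
  attr(out, "internal_stop") <- internal_stop
  out
}

# codon string vector -> 1-based index into sense_codons(), NA for anything
# else (gaps, ambiguity, stops)
.codon_index <- function(cod) {
  match(cod, .codon_tables()$codons)
}

.split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}
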