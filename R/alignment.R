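# Codon-aware alignment: container, progressive guide-tree aligner over
# translated sequences (global affine-gap profile alignment, BLOSUM62),
# conserved-block trimming in the Gblocks style, and the coverage filter.

#' Codon alignment container
#'
#' A named set of equal-length, in-frame aligned CDS strings (gap codon
#' `---`). Ungapping any row reproduces the input CDS exactly.
#'
#' @param seqs Named character vector of aligned sequences.
#' @return Object of class `codon_alignment`.
#' @export
codon_alignment <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("aligned sequences must have equal length")
  if (L %% 3L != 0L) stop("alignment length must be divisible by 3")
  structure(seqs, class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment> ", length(x), " taxa x ",
      nchar(x[[1]]) / 3, " codon columns\n", sep = "")
  invisible(x)
}

#' Number of codon columns
#' @param aln A [codon_alignment()].
#' @export
n_codon_columns <- function(aln) {
  if (length(aln) == 0L) return(0L)
  nchar(unclass(aln)[[1]]) %/% 3L
}

#' @export
as.matrix.codon_alignment <- function(x, ...) {
  m <- do.call(rbind, lapply(unclass(x), .split_codons))
  rownames(m) <- names(x)
  m
}

# amino-acid character matrix of a codon alignment ("-" for gap codons)
.aa_matrix <- function(aln) {
  m <- as.matrix(aln)
  code <- .codon_tables()$code
  aa <- matrix(unname(code[m]), nrow(m), ncol(m))
  aa[is.na(aa) & m == "---"] <- "-"
  aa[is.na(aa)] <- "X"
  aa[aa == "*"] <- "X"
  rownames(aa) <- rownames(m)
  aa
}

.blosum <- function() {
  if (is.null(.c4env$blosum)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    syms <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V", "X")
    .c4env$blosum <- e$BLOSUM62[syms, syms]
  }
  .c4env$blosum
}

# column frequency profile (21 x L) of an amino-acid character matrix
.aa_profile <- function(aa) {
  syms <- rownames(.blosum())
  L <- ncol(aa)
  prof <- matrix(0, length(syms), L)
  n <- nrow(aa)
  for (j in seq_len(L)) {
    v <- aa[, j]
    v[!(v %in% syms) & v != "-"] <- "X"
    v <- v[v != "-"]
    if (length(v)) {
      prof[, j] <- tabulate(match(v, syms), length(syms)) / n
    }
  }
  prof
}

#' Codon-aware progressive alignment
#'
#' Translates the CDSs, progressively aligns the proteins following the
#' guide-tree topology (global profile-profile alignment, BLOSUM62, gap open
#' 10, gap extension 0.5), and back-translates the result to codons.
#' Deterministic: ties in the dynamic program are broken in a fixed order.
#'
#' @param cds Named character vector of in-frame CDS (names are taxa present
#'   in the guide tree).
#' @param guide Rooted `ape::phylo` guide tree containing all `names(cds)`.
#' @param gap_open,gap_ext Affine gap penalties (a gap of length L costs
#'   `gap_open + (L - 1) * gap_ext`).
#' @return A [codon_alignment()]; rows in the input order.
#' @export
codon_align <- function(cds, guide = grass_species_tree(), gap_open = 10,
                        gap_ext = 0.5) {
  stopifnot(is.character(cds), !is.null(names(cds)))
  if (length(cds) == 1L) return(codon_alignment(cds))
  guide <- keep_species(guide, names(cds))
  code <- .codon_tables()$code
  # one residue per codon, including a terminal stop (as X) so that
  # back-translation round-trips the CDS byte-for-byte
  prot <- lapply(cds, function(s) {
    if (nchar(s) %% 3L != 0L) stop("CDS length not divisible by 3")
    aa <- unname(code[.split_codons(toupper(s))])
    aa[is.na(aa) | aa == "*"] <- "X"
    aa
  })

  # progressive merge in guide postorder; profiles are aa character matrices
  po <- ape::reorder.phylo(guide, "postorder")
  ntip <- length(po$tip.label)
  prof <- vector("list", ntip + po$Nnode)
  for (i in seq_len(ntip)) {
    prof[[i]] <- matrix(prot[[po$tip.label[i]]], nrow = 1,
                        dimnames = list(po$tip.label[i], NULL))
  }
  done <- logical(ntip + po$Nnode)
  for (r in seq_len(nrow(po$edge))) {
    p <- po$edge[r, 1]; v <- po$edge[r, 2]
    if (is.null(prof[[p]])) {
      prof[[p]] <- prof[[v]]
    } else {
      prof[[p]] <- .merge_profiles(prof[[p]], prof[[v]], gap_open, gap_ext)
    }
  }
  aa <- prof[[ntip + 1L]]
  aa <- aa[names(cds), , drop = FALSE]

  # back-translate each row against its source CDS
  out <- vapply(names(cds), function(tx) {
    row <- aa[tx, ]
    cods <- .split_codons(cds[[tx]])
    res <- character(length(row))
    res[row == "-"] <- "---"
    res[row != "-"] <- cods
    paste(res, collapse = "")
  }, character(1))
  codon_alignment(out)
}

.merge_profiles <- function(a, b, gap_open, gap_ext) {
  pa <- .aa_profile(a)
  pb <- .aa_profile(b)
  al <- .cpp_profile_align(pa, pb, .blosum(), gap_open, gap_ext)
  L <- length(al$a)
  m <- matrix("-", nrow(a) + nrow(b), L,
              dimnames = list(c(rownames(a), rownames(b)), NULL))
  m[seq_len(nrow(a)), al$a != 0] <- a[, al$a[al$a != 0], drop = FALSE]
  m[nrow(a) + seq_len(nrow(b)), al$b != 0] <- b[, al$b[al$b != 0], drop = FALSE]
  m
}

#' Trimming parameters (Gblocks-style)
#'
#' Column/block rules follow the Gblocks scheme: a column is *conserved*
#' when its most frequent residue strictly exceeds `min_conserved_fraction`
#' of the rows, and *highly conserved* (flank-grade) when it reaches
#' `flank_fraction`. Runs of more than `max_nonconserved_run` contiguous
#' nonconserved columns are removed, retained blocks are trimmed to
#' highly-conserved flanks, and blocks shorter than `min_block_length`
#' columns are dropped. With `allow_gap_columns = FALSE` any column holding
#' a gap is removed.
#'
#' @param min_conserved_fraction,flank_fraction,max_nonconserved_run,min_block_length,allow_gap_columns
#'   See description; defaults mirror common Gblocks settings.
#' @export
trim_params <- function(min_conserved_fraction = 0.5, flank_fraction = 0.85,
                        max_nonconserved_run = 8L, min_block_length = 10L,
                        allow_gap_columns = FALSE) {
  stopifnot(min_conserved_fraction > 0, min_conserved_fraction <= 1,
            flank_fraction > 0, flank_fraction <= 1,
            max_nonconserved_run >= 1, min_block_length >= 1)
  structure(
    list(min_conserved_fraction = min_conserved_fraction,
         flank_fraction = flank_fraction,
         max_nonconserved_run = as.integer(max_nonconserved_run),
         min_block_length = as.integer(min_block_length),
         allow_gap_columns = isTRUE(allow_gap_columns)),
    class = "trim_params"
  )
}

#' Conserved-block trimming of a codon alignment
#'
#' Classifies amino-acid columns and retains maximal conserved blocks (see
#' [trim_params()]); codon columns are kept iff their amino-acid column is.
#'
#' @param aln A [codon_alignment()] with at least 2 rows.
#' @param params A [trim_params()].
#' @return List with `alignment` (trimmed [codon_alignment()]) and `map`
#'   (strictly increasing 1-based original codon-column indices retained).
#' @export
trim_blocks <- function(aln, params = trim_params()) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (length(aln) < 2L) stop("trimming needs at least 2 rows")
  aa <- .aa_matrix(aln)
  n <- nrow(aa)
  L <- ncol(aa)
  if (L == 0L) {
    return(list(alignment = aln, map = integer(0)))
  }
  status <- character(L) # "gap", "non", "cons", "high"
  for (j in seq_len(L)) {
    col <- aa[, j]
    if (!params$allow_gap_columns && any(col == "-")) {
      status[j] <- "gap"
      next
    }
    res <- col[col != "-"]
    top <- if (length(res)) max(tabulate(factor(res))) else 0L
    if (top >= params$flank_fraction * n) {
      status[j] <- "high"
    } else if (top > params$min_conserved_fraction * n) {
      status[j] <- "cons"
    } else {
      status[j] <- "non"
    }
  }
  # Block segmentation: gap columns and nonconserved runs longer than
  # max_nonconserved_run are barriers that split the alignment into
  # candidate segments. Within a segment, conserved/high columns are
  # retained (short interior nonconserved runs are removed without
  # splitting), segments are trimmed to highly conserved flanks, and short
  # blocks are dropped.
  keep <- status %in% c("cons", "high")
  r <- rle(status)
  pos <- cumsum(r$lengths) - r$lengths + 1L
  is_barrier_run <- r$values == "gap" |
    (r$values == "non" & r$lengths > params$max_nonconserved_run)
  seg_id <- integer(L)
  cur_id <- 1L
  for (k in seq_along(r$lengths)) {
    cols <- seq(pos[k], length.out = r$lengths[k])
    if (is_barrier_run[k]) {
      seg_id[cols] <- 0L
      cur_id <- cur_id + 1L
    } else {
      seg_id[cols] <- cur_id
    }
  }
  map <- integer(0)
  for (s in setdiff(unique(seg_id), 0L)) {
    seg <- which(seg_id == s)
    st <- status[seg]
    hi <- which(st == "high")
    if (length(hi) == 0L) next
    block <- seg[hi[1]:hi[length(hi)]]
    block <- block[keep[block]]
    if (length(block) >= params$min_block_length) {
      map <- c(map, block)
    }
  }
  map <- sort(unique(map))
  m <- as.matrix(aln)[, map, drop = FALSE]
  seqs <- apply(m, 1, paste, collapse = "")
  if (length(map) == 0L) {
    seqs <- setNames(rep("", length(aln)), names(aln))
  }
  list(alignment = codon_alignment(setNames(seqs, names(aln))), map = map)
}

#' Write a codon alignment (and optional column map) to disk
#'
#' Writes aligned FASTA; when a retained-column map from [trim_blocks()] is
#' given, a companion TSV `<path>.colmap.tsv` with columns `aln_col`,
#' `orig_col` (both 1-based codon-column indices, inclusive) records where
#' each retained column came from.
#'
#' @param aln A [codon_alignment()].
#' @param path Output FASTA path.
#' @param map Optional integer vector of original codon-column indices.
#' @return `path`, invisibly.
#' @export
write_codon_alignment <- function(aln, path, map = NULL) {
  stopifnot(inherits(aln, "codon_alignment"))
  .write_fasta(unclass(aln), path)
  if (!is.null(map)) {
    readr::write_tsv(
      tibble::tibble(aln_col = seq_along(map), orig_col = as.integer(map)),
      paste0(path, ".colmap.tsv"))
  }
  invisible(path)
}

#' Alignment coverage filter
#'
#' Coverage is the fraction of original codon columns retained by trimming;
#' alignments with coverage below 30% are discarded (kept at exactly 0.30).
#'
#' @param trimmed Trimmed [codon_alignment()] (or the list from
#'   [trim_blocks()]).
#' @param original The pre-trimming [codon_alignment()].
#' @param threshold Minimum coverage to keep (default 0.30).
#' @return List with `keep` (logical) and `coverage` (numeric).
#' @export
coverage_filter <- function(trimmed, original, threshold = 0.30) {
  if (is.list(trimmed) && !inherits(trimmed, "codon_alignment")) {
    trimmed <- trimmed$alignment
  }
  L0 <- n_codon_columns(original)
  if (L0 == 0L) {
    return(list(keep = FALSE, coverage = NA_real_))
  }
  cov <- n_codon_columns(trimmed) / L0
  list(keep = cov >= threshold, coverage = cov)
}
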