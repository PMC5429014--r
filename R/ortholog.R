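# Ortholog-group construction: synteny table parsing, maize homeolog
# merging, Dichanthelium best-hit attachment, and pattern classification.

#' Read a synteny table
#'
#' TSV with header columns `group_id`, `species`, `gene_id` (one row per
#' member; maize homeologs appear as two rows).
#'
#' @param path File path.
#' @return Tibble with those three character columns.
#' @export
read_synteny <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  need <- c("group_id", "species", "gene_id")
  if (!all(need %in% names(tbl))) {
    stop("synteny table must have columns: ", paste(need, collapse = ", "))
  }
  tbl[need]
}

#' Merge maize whole-genome-duplication homeologs
#'
#' Groups that are identical in every non-maize member are unified into a
#' single group holding both maize genes (ordered lexicographically).
#' Idempotent. Groups ending up with three or more maize members are
#' marked excluded.
#'
#' @param rows Synteny tibble (`group_id`, `species`, `gene_id`).
#' @return Tibble of the same shape plus an `excluded` logical column;
#'   merged groups keep the lexicographically first `group_id`.
#' @export
merge_homeologs <- function(rows) {
  stopifnot(all(c("group_id", "species", "gene_id") %in% names(rows)))
  anchor_key <- rows |>
    dplyr::filter(.data$species != "Zm") |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(
      key = paste(sort(paste(.data$species, .data$gene_id)), collapse = "|"),
      .groups = "drop")
  # groups with no non-maize member keep their own key (never merged)
  all_groups <- unique(rows$group_id)
  key <- setNames(anchor_key$key, anchor_key$group_id)
  miss <- setdiff(all_groups, names(key))
  key[miss] <- paste0("self:", miss)

  canon <- tibble::tibble(group_id = names(key), key = unname(key)) |>
    dplyr::group_by(.data$key) |>
    dplyr::mutate(canonical = min(.data$group_id)) |>
    dplyr::ungroup()
  map <- setNames(canon$canonical, canon$group_id)

  merged <- rows |>
    dplyr::mutate(group_id = unname(map[.data$group_id])) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$group_id, .data$species, .data$gene_id)
  n_zm <- merged |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(n_zm = sum(.data$species == "Zm"), .groups = "drop")
  merged |>
    dplyr::left_join(n_zm, by = "group_id") |>
    dplyr::mutate(excluded = .data$n_zm > 2L) |>
    dplyr::select(-"n_zm")
}

#' Best-hit homolog search
#'
#' Scores the query against every candidate with a local Smith-Waterman
#' alignment (match +2, mismatch -3, gap open 5, gap extension 2 -- an
#' internal, deterministic stand-in for a BLASTN search) and returns the
#' best-scoring candidate. Ties break lexicographically by candidate name;
#' scores below `min_score`, or an empty candidate set, give a missing
#' result.
#'
#' @param query CDS string.
#' @param candidates Named character vector of candidate CDS.
#' @param min_score Minimum acceptable score (default 50).
#' @return List with `gene_id` (or `NA`) and `score`.
#' @export
best_hit_homolog <- function(query, candidates, min_score = 50) {
  if (length(candidates) == 0L) {
    return(list(gene_id = NA_character_, score = NA_real_))
  }
  stopifnot(!is.null(names(candidates)))
  qi <- .dna_int(query)
  ord <- order(names(candidates))
  scores <- vapply(candidates[ord], function(s) {
    .cpp_sw_score(qi, .dna_int(s), 2, -3, 5, 2)
  }, numeric(1))
  best <- which.max(scores) # first max = lexicographic tie-break
  if (scores[best] < min_score) {
    return(list(gene_id = NA_character_, score = unname(scores[best])))
  }
  list(gene_id = names(candidates[ord])[best],
       score = unname(scores[best]))
}

.dna_int <- function(s) {
  v <- match(strsplit(toupper(s), "")[[1]], .nuc)
  v[is.na(v)] <- 0L
  as.integer(v)
}

# shared 8-mer prescreen used by the pipeline before full Smith-Waterman
.kmer_prescreen <- function(query, candidates, k = 8L, top = 3L) {
  qk <- unique(substring(query, seq_len(max(nchar(query) - k + 1L, 1L)),
                         seq_len(max(nchar(query) - k + 1L, 1L)) + k - 1L))
  shared <- vapply(candidates, function(s) {
    sk <- unique(substring(s, seq_len(max(nchar(s) - k + 1L, 1L)),
                           seq_len(max(nchar(s) - k + 1L, 1L)) + k - 1L))
    length(intersect(qk, sk))
  }, numeric(1))
  ord <- order(-shared, names(candidates))
  names(candidates)[ord][seq_len(min(top, length(candidates)))]
}

#' Classify an ortholog group into the four tested patterns
#'
#' Pattern (i): one member in all six species. Pattern (ii): two maize
#' members, one in each other species. Pattern (iii): rice missing, one
#' member in the other five. Pattern (iv): Brachypodium missing, one
#' member in the other five. Anything else is excluded.
#'
#' @param counts Named integer vector of member counts per species code
#'   (absent species may be omitted).
#' @return `"i"`, `"ii"`, `"iii"`, `"iv"` or `"excluded"`.
#' @export
classify_pattern <- function(counts) {
  sp <- names(c4_tags())
  n <- setNames(rep(0L, length(sp)), sp)
  n[names(counts)] <- as.integer(counts)
  others <- c("Sb", "Si", "Do", "Os", "Bd")
  if (n[["Zm"]] == 1L && all(n[others] == 1L)) return("i")
  if (n[["Zm"]] == 2L && all(n[others] == 1L)) return("ii")
  if (n[["Os"]] == 0L && n[["Zm"]] == 1L &&
      all(n[setdiff(others, "Os")] == 1L)) return("iii")
  if (n[["Bd"]] == 0L && n[["Zm"]] == 1L &&
      all(n[setdiff(others, "Bd")] == 1L)) return("iv")
  "excluded"
}

#' Build ortholog groups from a synteny table and CDS sets
#'
#' Merges maize homeologs, attaches the closest Dichanthelium homolog to
#' each group's *S. italica* ortholog by best-hit search (unless the table
#' already has Do rows), and classifies each group into patterns i-iv.
#' The pipeline-scale search prescreens Do candidates by shared 8-mers and
#' runs the full Smith-Waterman on the top hits only.
#'
#' @param synteny Synteny tibble (`group_id`, `species`, `gene_id`).
#' @param sequences Named list per species of named CDS vectors.
#' @param min_score Best-hit acceptance threshold.
#' @param prescreen_top Number of prescreened Do candidates scored fully.
#' @return List with `members` (tibble `group_id`, `species`, `gene_id`)
#'   and `groups` (tibble `group_id`, `pattern`).
#' @export
build_groups <- function(synteny, sequences, min_score = 50,
                         prescreen_top = 3L) {
  merged <- merge_homeologs(synteny)
  members <- merged |> dplyr::filter(!.data$excluded)
  excluded_ids <- unique(merged$group_id[merged$excluded])

  if (!"Do" %in% members$species && !is.null(sequences$Do) &&
      length(sequences$Do)) {
    do_cds <- sequences$Do
    si <- members |> dplyr::filter(.data$species == "Si")
    do_rows <- purrr::map_dfr(seq_len(nrow(si)), function(i) {
      q <- sequences$Si[[si$gene_id[i]]]
      if (is.null(q)) return(NULL)
      cand_names <- .kmer_prescreen(q, do_cds, top = prescreen_top)
      hit <- best_hit_homolog(q, do_cds[cand_names], min_score = min_score)
      if (is.na(hit$gene_id)) return(NULL)
      tibble::tibble(group_id = si$group_id[i], species = "Do",
                     gene_id = hit$gene_id, excluded = FALSE)
    })
    members <- dplyr::bind_rows(members, do_rows) |>
      dplyr::arrange(.data$group_id, .data$species, .data$gene_id)
  }

  groups <- members |>
    dplyr::count(.data$group_id, .data$species) |>
    tidyr::nest(data = -"group_id") |>
    dplyr::mutate(pattern = purrr::map_chr(
      .data$data, function(d) classify_pattern(setNames(d$n, d$species)))) |>
    dplyr::select("group_id", "pattern")
  if (length(excluded_ids)) {
    groups <- dplyr::bind_rows(
      groups,
      tibble::tibble(group_id = excluded_ids, pattern = "excluded"))
  }
  list(members = dplyr::select(members, -"excluded"),
       groups = dplyr::arrange(groups, .data$group_id))
}
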