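# End-to-end workflow: group -> align -> trim -> coverage -> congruence ->
# scan -> FDR -> candidates -> enrichment, with stage-count bookkeeping and
# fixed output schemas. The pipeline is a pure function of
# (inputs, config, seed).

#' Pipeline configuration
#'
#' @param fasta Named character vector of per-species CDS FASTA paths
#'   (names are species codes); alternatively supply `sequences` directly.
#' @param synteny Path to the synteny TSV (or a tibble).
#' @param sequences Optional named list (per species) of named CDS vectors;
#'   overrides `fasta`.
#' @param species_tree `ape::phylo` or a Newick path; defaults to the
#'   six-taxon grass tree.
#' @param trim A [trim_params()].
#' @param coverage_threshold Minimum trimming coverage (default 0.30).
#' @param fdr_threshold Candidate FDR threshold (default 0.2).
#' @param fdr_method `"bh"` or `"storey"`.
#' @param foreground_rule `"stem_only"` or `"clade_all"`.
#' @param conditions Condition ids to test (default 1-9).
#' @param known_groups Optional character vector of group ids with known
#'   C4 relevance, for the enrichment report.
#' @param gamma_categories Gamma categories for gene trees.
#' @param n_starts Optimizer starts for the LRT (see [lrt_branch_model()]).
#' @param min_score Do best-hit acceptance threshold.
#' @param seed Integer seed (defaults to 1; the pipeline itself is
#'   deterministic, the seed is recorded for provenance and used by any
#'   downstream simulation helpers).
#' @param out_dir Optional output directory for the result bundle.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta = NULL, synteny = NULL, sequences = NULL,
                            species_tree = grass_species_tree(),
                            trim = trim_params(),
                            coverage_threshold = 0.30,
                            fdr_threshold = 0.2,
                            fdr_method = "bh",
                            foreground_rule = "stem_only",
                            conditions = 1:9,
                            known_groups = NULL,
                            gamma_categories = 4L,
                            n_starts = 1L,
                            min_score = 50,
                            seed = 1L,
                            out_dir = NULL) {
  stopifnot(coverage_threshold > 0, coverage_threshold < 1,
            fdr_threshold > 0, fdr_threshold < 1)
  if (is.character(species_tree)) {
    species_tree <- ape::read.tree(species_tree)
  }
  structure(
    list(fasta = fasta, synteny = synteny, sequences = sequences,
         species_tree = species_tree, trim = trim,
         coverage_threshold = coverage_threshold,
         fdr_threshold = fdr_threshold, fdr_method = fdr_method,
         foreground_rule = foreground_rule,
         conditions = as.integer(conditions),
         known_groups = known_groups,
         gamma_categories = as.integer(gamma_categories),
         n_starts = as.integer(n_starts), min_score = min_score,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Read pipeline configuration from YAML
#'
#' @param path YAML file with fields named as in [pipeline_config()]
#'   (`species_tree` may be a Newick path).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$trim)) y$trim <- do.call(trim_params, y$trim)
  if (!is.null(y$fasta)) y$fasta <- unlist(y$fasta)
  do.call(pipeline_config, y)
}

#' Run the full selection-scan pipeline
#'
#' Stage order: ortholog grouping (homeolog merge, Do attachment, pattern
#' classification) -> codon-aware alignment -> conserved-block trimming ->
#' coverage filter -> gene-tree congruence filter -> branch-model scan
#' over the phylogenetic conditions -> per-condition FDR -> candidate
#' merging -> optional known-gene enrichment. Per-stage counts are
#' conserved (groups in = kept + excluded at every stage) and reported in
#' the QC funnel; per-group failures are recorded, never fatal.
#'
#' @param config A [pipeline_config()].
#' @param progress Print per-stage progress lines.
#' @return Object of class `c4_pipeline_result`: `scan`, `candidates`,
#'   `qc` (per-group QC table), `funnel` (stage counts), `enrichment`,
#'   `log`, `config`. If `config$out_dir` is set the tables are also
#'   written as TSV (plus a manifest).
#' @export
run_pipeline <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  logline <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    logline <<- c(logline, msg)
    if (progress) message(msg)
  }

  # ---- inputs
  sequences <- config$sequences
  if (is.null(sequences)) {
    if (is.null(config$fasta)) stop("config needs `sequences` or `fasta`")
    sequences <- lapply(config$fasta, .read_fasta)
  }
  synteny <- config$synteny
  if (is.character(synteny)) synteny <- read_synteny(synteny)
  if (is.null(synteny)) stop("config needs a synteny table")
  say("inputs: ", length(unique(synteny$group_id)), " synteny groups, ",
      length(sequences), " species")

  # ---- stage 1: grouping + patterns
  grp <- build_groups(synteny, sequences, min_score = config$min_score)
  groups <- grp$groups
  n_in <- nrow(groups)
  say("grouping: ", n_in, " groups; ",
      sum(groups$pattern == "excluded"), " excluded by pattern")

  all_seqs <- unlist(unname(sequences))
  gene_of <- function(gid) {
    m <- grp$members[grp$members$group_id == gid, ]
    # homeolog naming: Zm.1 / Zm.2 by lexicographic gene id
    sp <- m$species
    tx <- sp
    if (sum(sp == "Zm") == 2L) {
      zm <- sort(m$gene_id[sp == "Zm"])
      tx[sp == "Zm"] <- paste0("Zm.", match(m$gene_id[sp == "Zm"], zm))
    }
    setNames(all_seqs[m$gene_id], tx)
  }

  keep_ids <- groups$group_id[groups$pattern != "excluded"]
  patterns <- setNames(groups$pattern, groups$group_id)

  # ---- stage 2: alignment + trimming + coverage, internal-stop exclusion
  alignments <- list()
  aln_status <- character(0)
  coverage <- numeric(0)
  for (gid in keep_ids) {
    cds <- gene_of(gid)
    guide <- config$species_tree
    if (sum(grepl("^Zm\\.", names(cds))) == 2L) {
      guide <- .add_homeolog_cherry(guide, "Zm")
    }
    has_stop <- any(vapply(cds, function(s) {
      isTRUE(attr(translate_cds(s), "internal_stop"))
    }, logical(1)))
    if (has_stop) {
      aln_status[gid] <- "excluded_internal_stop"
      coverage[gid] <- NA_real_
      next
    }
    aln <- tryCatch(codon_align(cds, guide), error = function(e) NULL)
    if (is.null(aln)) {
      aln_status[gid] <- "excluded_alignment_failed"
      coverage[gid] <- NA_real_
      next
    }
    tr <- trim_blocks(aln, config$trim)
    cv <- coverage_filter(tr, aln, config$coverage_threshold)
    coverage[gid] <- cv$coverage
    if (!cv$keep) {
      aln_status[gid] <- "excluded_coverage"
      next
    }
    aln_status[gid] <- "aligned"
    alignments[[gid]] <- tr$alignment
  }
  say("alignment: ", sum(aln_status == "aligned"), " kept, ",
      sum(aln_status != "aligned"), " excluded (",
      sum(aln_status == "excluded_internal_stop"), " internal stop, ",
      sum(aln_status == "excluded_coverage"), " low coverage)")

  # ---- stage 3: congruence filter
  cong_pass <- character(0)
  cong_rows <- list()
  for (gid in names(alignments)) {
    verdict <- tryCatch(
      congruence_test(alignments[[gid]], config$species_tree,
                      k = config$gamma_categories),
      error = function(e) NULL)
    if (is.null(verdict)) {
      cong_rows[[gid]] <- tibble::tibble(
        group_id = gid, qdist_all = NA_integer_,
        qdist_third = NA_integer_, pass = FALSE,
        status = "congruence_failed")
      next
    }
    cong_rows[[gid]] <- tibble::tibble(
      group_id = gid, qdist_all = verdict$qdist_all,
      qdist_third = verdict$qdist_third, pass = verdict$pass,
      status = if (verdict$pass) "congruent" else "excluded_incongruent")
    if (verdict$pass) cong_pass <- c(cong_pass, gid)
  }
  congruence <- dplyr::bind_rows(cong_rows)
  say("congruence: ", length(cong_pass), " pass, ",
      length(alignments) - length(cong_pass), " excluded")

  # ---- stage 4: scan
  scan <- run_scan(alignments[cong_pass], patterns,
                   species_tree = config$species_tree,
                   conditions = config$conditions,
                   rule = config$foreground_rule,
                   n_starts = config$n_starts)
  say("scan: ", sum(scan$status == "tested"), " tests over ",
      length(cong_pass), " groups (",
      sum(scan$status == "skipped_min_taxa"), " condition skips)")

  # ---- stage 5: FDR + candidates
  scan <- add_fdr(scan, method = config$fdr_method)
  candidates <- merge_candidates(scan, config$fdr_threshold)
  say("candidates: ", nrow(candidates), " groups at q < ",
      config$fdr_threshold)

  # ---- stage 6: enrichment (optional)
  enrichment <- NULL
  if (!is.null(config$known_groups)) {
    tested_ids <- unique(scan$group_id[scan$status == "tested"])
    known <- intersect(config$known_groups, tested_ids)
    detected <- intersect(known, candidates$group_id)
    p <- enrichment_fisher(length(tested_ids), nrow(candidates),
                           length(known), length(detected))
    enrichment <- tibble::tibble(
      n_tested = length(tested_ids), n_candidates = nrow(candidates),
      n_known = length(known), n_detected = length(detected), p = p)
    say("enrichment: ", length(detected), "/", length(known),
        " known groups among candidates, one-sided P = ",
        format(p, digits = 3))
  }

  # ---- QC funnel
  qc <- groups |>
    dplyr::mutate(
      aln_status = dplyr::coalesce(aln_status[.data$group_id],
                                   "excluded_pattern"),
      coverage = unname(coverage[.data$group_id])) |>
    dplyr::left_join(congruence, by = "group_id")
  funnel <- tibble::tibble(
    stage = c("input", "pattern_ok", "aligned", "congruent", "tested",
              "candidates"),
    n = c(n_in,
          length(keep_ids),
          sum(aln_status == "aligned"),
          length(cong_pass),
          length(unique(scan$group_id[scan$status == "tested"])),
          nrow(candidates))
  )

  out <- structure(
    list(scan = scan, candidates = candidates, qc = qc, funnel = funnel,
         congruence = congruence, enrichment = enrichment, log = logline,
         config = config),
    class = "c4_pipeline_result"
  )
  if (!is.null(config$out_dir)) .write_bundle(out, config$out_dir)
  out
}

#' @export
print.c4_pipeline_result <- function(x, ...) {
  cat("<c4_pipeline_result>\n")
  f <- x$funnel
  cat(paste0("  ", format(f$stage, width = 12), f$n, collapse = "\n"), "\n")
  invisible(x)
}

.write_bundle <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(scan = "scan.tsv", candidates = "candidates.tsv",
             qc = "qc_report.tsv", funnel = "funnel.tsv")
  readr::write_tsv(res$scan, file.path(dir, paths["scan"]))
  readr::write_tsv(res$candidates, file.path(dir, paths["candidates"]))
  readr::write_tsv(res$qc, file.path(dir, paths["qc"]))
  readr::write_tsv(res$funnel, file.path(dir, paths["funnel"]))
  if (!is.null(res$enrichment)) {
    readr::write_tsv(res$enrichment, file.path(dir, "enrichment.tsv"))
    paths <- c(paths, enrichment = "enrichment.tsv")
  }
  writeLines(res$log, file.path(dir, "run.log"))
  manifest <- tibble::tibble(file = unname(paths),
                             description = names(paths))
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(paths)
}
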