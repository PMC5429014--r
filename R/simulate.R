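# Forward simulation: codon alignments under branch-specific omega, full
# synthetic cohorts with maize homeologs / gene losses / discordant
# histories, and the calibration / power experiment harness.

#' Simulate a codon alignment on a labeled tree
#'
#' Draws root codons from the model's stationary frequencies and evolves
#' them along each branch with the transition matrix of the branch's omega
#' class. The output is gap-free and in frame; identical seeds give
#' identical alignments.
#'
#' @param tree Rooted `ape::phylo`; branch classes from the `eclass`
#'   attribute (all background if absent).
#' @param model A [codon_model()]; `omega` must cover the tree's classes.
#' @param n_codons Number of codon sites (>= 1).
#' @param seed Integer seed (mandatory; all randomness derives from it).
#' @return A [codon_alignment()] over the tree's tips.
#' @export
simulate_codon_alignment <- function(tree, model, n_codons, seed) {
  stopifnot(inherits(model, "codon_model"))
  if (!is.numeric(n_codons) || n_codons < 1) {
    stop("n_codons must be >= 1")
  }
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  n_codons <- as.integer(n_codons)
  codons <- .codon_tables()$codons

  eclass <- attr(tree, "eclass")
  if (is.null(eclass)) eclass <- rep(1L, nrow(tree$edge))
  if (max(eclass) > length(model$omega)) {
    stop("tree has ", max(eclass), " branch classes but model provides ",
         length(model$omega), " omega value(s)")
  }
  po <- ape::reorder.phylo(tree, "postorder")
  # carry eclass through the reorder by matching (parent, child) rows
  key0 <- paste(tree$edge[, 1], tree$edge[, 2])
  keyp <- paste(po$edge[, 1], po$edge[, 2])
  eclass <- eclass[match(keyp, key0)]

  ntip <- length(po$tip.label)
  nnode <- ntip + po$Nnode
  root <- ntip + 1L

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(seed))

  states <- matrix(NA_integer_, nnode, n_codons)
  states[root, ] <- sample.int(61L, n_codons, replace = TRUE, prob = model$pi)
  # preorder: reverse postorder edge order
  Qs <- lapply(seq_along(model$omega), function(cl) {
    codon_rate_matrix(model, omega = model$omega[[cl]])
  })
  # P matrices repeat across branches sharing (class, length); cache them
  Pcache <- new.env(parent = emptyenv())
  P_for <- function(cl, t) {
    key <- paste(cl, format(t, digits = 17))
    if (is.null(Pcache[[key]])) Pcache[[key]] <- transition_matrix(Qs[[cl]], t)
    Pcache[[key]]
  }
  for (r in rev(seq_len(nrow(po$edge)))) {
    p <- po$edge[r, 1]; v <- po$edge[r, 2]
    P <- P_for(eclass[r], po$edge.length[r])
    sv <- integer(n_codons)
    par <- states[p, ]
    for (s in unique(par)) {
      i <- which(par == s)
      sv[i] <- sample.int(61L, length(i), replace = TRUE, prob = P[s, ])
    }
    states[v, ] <- sv
  }
  seqs <- vapply(seq_len(ntip), function(i) {
    paste(codons[states[i, ]], collapse = "")
  }, character(1))
  names(seqs) <- po$tip.label
  codon_alignment(seqs)
}

#' Cohort configuration
#'
#' Study conditions for a synthetic ortholog-group cohort. Counts of
#' selected / duplicated / lost / discordant groups are exact allocations
#' (`round(n_groups * fraction)`), assigned to seed-derived group indices,
#' so truth tables are deterministic. Pattern fractions default to the
#' composition observed in real pan-grass synteny data (about 19% maize
#' homeolog pairs, 6% rice losses, 4% Brachypodium losses).
#'
#' @param n_groups Number of ortholog groups.
#' @param fraction_selected Fraction with elevated foreground omega.
#' @param omega_bg Background dN/dS (all branches of neutral groups).
#' @param omega_fg Foreground dN/dS of selected groups.
#' @param n_codons Codon sites per group.
#' @param p_duplicate Probability a group carries a maize homeolog pair.
#' @param p_loss_rice,p_loss_brachy Gene-loss probabilities.
#' @param discordant_fraction Fraction simulated on a discordant topology
#'   (Sb and Si exchanged).
#' @param kappa Transition/transversion ratio.
#' @param terminal,internal Species-tree branch lengths (substitutions per
#'   codon).
#' @param homeolog_twig Branch length of each maize homeolog twig.
#' @param seed Mandatory integer seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_groups = 200L, fraction_selected = 0.1,
                          omega_bg = 0.2, omega_fg = 4.0, n_codons = 300L,
                          p_duplicate = 0.19, p_loss_rice = 0.06,
                          p_loss_brachy = 0.04, discordant_fraction = 0.1,
                          kappa = 2, terminal = 0.1, internal = 0.15,
                          homeolog_twig = 0.05, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  probs <- c(fraction_selected, p_duplicate, p_loss_rice, p_loss_brachy,
             discordant_fraction)
  if (any(probs < 0 | probs > 1)) stop("fractions must lie in [0, 1]")
  if (p_duplicate + p_loss_rice + p_loss_brachy > 1) {
    stop("pattern probabilities must not sum above 1")
  }
  stopifnot(n_groups >= 1, n_codons >= 1, omega_bg >= 0, omega_fg >= 0)
  structure(
    list(n_groups = as.integer(n_groups),
         fraction_selected = fraction_selected, omega_bg = omega_bg,
         omega_fg = omega_fg, n_codons = as.integer(n_codons),
         p_duplicate = p_duplicate, p_loss_rice = p_loss_rice,
         p_loss_brachy = p_loss_brachy,
         discordant_fraction = discordant_fraction, kappa = kappa,
         terminal = terminal, internal = internal,
         homeolog_twig = homeolog_twig, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# discordant topology: Sb and Si exchanged relative to the species tree
.discordant_tree <- function(terminal, internal) {
  txt <- sprintf(
    "(((Zm:%f,Si:%f):%f,(Sb:%f,Do:%f):%f):%f,(Os:%f,Bd:%f):%f);",
    terminal, terminal, internal, terminal, terminal, internal,
    internal, terminal, terminal, internal)
  ape::read.tree(text = txt)
}

# per-group generating tree for a cohort row
.group_tree <- function(cfg, pattern, discordant) {
  tr <- if (discordant) {
    .discordant_tree(cfg$terminal, cfg$internal)
  } else {
    grass_species_tree(cfg$terminal, cfg$internal)
  }
  if (pattern == "iii") tr <- ape::drop.tip(tr, "Os")
  if (pattern == "iv") tr <- ape::drop.tip(tr, "Bd")
  if (pattern == "ii") tr <- .add_homeolog_cherry(tr, "Zm", cfg$homeolog_twig)
  tr
}

#' Generate a synthetic ortholog-group cohort
#'
#' Simulates `n_groups` codon alignments on the grass species tree (or the
#' discordant alternative), with exact-count allocation of selected,
#' duplicated, lost and discordant groups, and writes the files the
#' pipeline consumes: one CDS FASTA per species, a synteny table (without
#' Dichanthelium rows -- the pipeline attaches Do by best-hit search), the
#' ground-truth table and a YAML echo of the configuration.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory (created if needed); `NULL` for in-memory
#'   only.
#' @return List with `truth` (tibble), `sequences` (per-species named CDS
#'   vectors), `synteny` (tibble) and `paths` (if written).
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  n <- cfg$n_groups

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(cfg$seed)

  n_sel <- round(n * cfg$fraction_selected)
  n_dup <- round(n * cfg$p_duplicate)
  n_rice <- round(n * cfg$p_loss_rice)
  n_bd <- round(n * cfg$p_loss_brachy)
  n_dis <- round(n * cfg$discordant_fraction)

  sel_idx <- sort(sample.int(n, n_sel))
  dis_idx <- sort(sample.int(n, n_dis))
  pat_idx <- sample.int(n, n_dup + n_rice + n_bd)
  pattern <- rep("i", n)
  pattern[pat_idx[seq_len(n_dup)]] <- "ii"
  if (n_rice > 0) pattern[pat_idx[n_dup + seq_len(n_rice)]] <- "iii"
  if (n_bd > 0) pattern[pat_idx[n_dup + n_rice + seq_len(n_bd)]] <- "iv"

  group_seeds <- sample.int(.Machine$integer.max - 1L, n)

  truth <- tibble::tibble(
    group_id = sprintf("g%04d", seq_len(n)),
    pattern = pattern,
    selected = seq_len(n) %in% sel_idx,
    discordant = seq_len(n) %in% dis_idx,
    omega_fg = ifelse(seq_len(n) %in% sel_idx, cfg$omega_fg, cfg$omega_bg),
    omega_bg = cfg$omega_bg,
    seed = group_seeds
  )

  species <- names(c4_tags())
  seqs <- setNames(lapply(species, function(s) character(0)), species)
  synteny <- list()

  for (g in seq_len(n)) {
    tr <- .group_tree(cfg, pattern[g], truth$discordant[g])
    if (truth$selected[g]) {
      tr <- label_foreground(tr, "stem_only")
      model <- codon_model(
        kappa = cfg$kappa,
        omega = c(background = cfg$omega_bg, foreground = cfg$omega_fg)
      )
    } else {
      model <- codon_model(kappa = cfg$kappa,
                           omega = c(background = cfg$omega_bg))
    }
    aln <- simulate_codon_alignment(tr, model, cfg$n_codons,
                                    seed = group_seeds[g])
    gid <- truth$group_id[g]
    for (tx in names(aln)) {
      sp <- .species_of(tx)
      gene <- if (grepl("\\.", tx)) {
        sprintf("%s_%s_h%s", sp, gid, sub("^.*\\.", "", tx))
      } else {
        sprintf("%s_%s", sp, gid)
      }
      seqs[[sp]][gene] <- unclass(aln)[[tx]]
      if (sp != "Do") {
        synteny[[length(synteny) + 1L]] <-
          tibble::tibble(group_id = gid, species = sp, gene_id = gene)
      }
    }
  }
  synteny <- dplyr::bind_rows(synteny)

  out <- list(truth = truth, sequences = seqs, synteny = synteny,
              config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(synteny = file.path(dir, "synteny.tsv"),
                  truth = file.path(dir, "truth.tsv"),
                  config = file.path(dir, "cohort_config.yml"),
                  fasta = setNames(
                    file.path(dir, paste0(species, ".fa")), species))
    readr::write_tsv(synteny, paths$synteny)
    readr::write_tsv(truth, paths$truth)
    yaml::write_yaml(unclass(cfg), paths$config)
    for (sp in species) {
      .write_fasta(seqs[[sp]], paths$fasta[[sp]])
    }
    out$paths <- paths
  }
  out
}

.write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
}

.read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Type-I error and power experiment
#'
#' For each grid cell, simulates replicate alignments on a condition tree
#' (pattern-i species tree pruned per condition, stem-rule foreground) with
#' the given foreground omega, runs the branch-model LRT, and reports the
#' rejection fraction at `p < 0.05` and at BH `q < 0.2` within the cell.
#' Cells with `omega_fg == omega_bg` measure type-I error; others power.
#'
#' @param omega_fg Vector of foreground omegas to scan.
#' @param n_codons Vector of alignment lengths.
#' @param conditions Condition ids (see [condition_catalog()]).
#' @param n_rep Replicates per cell.
#' @param omega_bg,kappa,terminal,internal Simulation parameters.
#' @param seed Mandatory integer seed.
#' @return Tibble: one row per (omega_fg, n_codons, condition) cell with
#'   `reject_p05`, `reject_q20`, `n_rep`.
#' @export
power_experiment <- function(omega_fg = c(0.2, 1.5, 4.0), n_codons = 300L,
                             conditions = 1L, n_rep = 50L, omega_bg = 0.2,
                             kappa = 2, terminal = 0.1, internal = 0.15,
                             seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  grid <- tidyr::expand_grid(omega_fg = omega_fg, n_codons = n_codons,
                             condition = as.integer(conditions))
  cat_tbl <- condition_catalog()
  base <- grass_species_tree(terminal, internal)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(seed))
  cell_seeds <- matrix(
    sample.int(.Machine$integer.max - 1L, nrow(grid) * n_rep),
    nrow(grid), n_rep)

  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    removed <- cat_tbl$removed[[row$condition]]
    tr <- base
    if (length(removed)) tr <- ape::drop.tip(tr, removed)
    tr <- label_foreground(tr, "stem_only")
    ps <- vapply(seq_len(n_rep), function(r) {
      model <- codon_model(
        kappa = kappa,
        omega = c(background = omega_bg, foreground = row$omega_fg))
      aln <- simulate_codon_alignment(tr, model, row$n_codons,
                                      seed = cell_seeds[i, r])
      lrt_branch_model(aln, tr)$p
    }, numeric(1))
    q <- bh_fdr(ps)
    tibble::tibble(
      omega_fg = row$omega_fg, n_codons = row$n_codons,
      condition = row$condition, n_rep = as.integer(n_rep),
      reject_p05 = mean(ps < 0.05), reject_q20 = mean(q < 0.2))
  })
  res
}
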