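#' Gene families
#'
#' The unit of phylogenomic dataset curation: a per-family alignment, its
#' gene tree, and the map from sequence labels to taxon labels (a taxon may
#' own several sequences when paralogues were retrieved).  Filters return an
#' updated family carrying a `verdict` (`"kept"`, `"excluded_too_short"`,
#' `"excluded_out_paralog"`) and an append-only curation log (a tibble, one
#' row per removed sequence with its reason and pass).
#'
#' @param family_id identifier string.
#' @param alignment an [aa_alignment()]; row names are sequence labels.
#' @param gene_tree an [ape::phylo] tree whose leaves are sequence labels
#'   present in the alignment.
#' @param taxon_of named character vector mapping every sequence label to a
#'   taxon label; defaults to identity (all single-copy).
#' @return an object of class `gene_family`.
#' @export
gene_family <- function(family_id, alignment, gene_tree, taxon_of = NULL) {
  stopifnot(inherits(alignment, "aa_alignment"))
  seqs <- rownames(alignment)
  if (is.null(taxon_of)) taxon_of <- stats::setNames(seqs, seqs)
  missing_map <- setdiff(seqs, names(taxon_of))
  if (length(missing_map) > 0) {
    stop("taxon_of lacks entries for: ", paste(missing_map, collapse = ", "))
  }
  stray <- setdiff(gene_tree$tip.label, seqs)
  if (length(stray) > 0) {
    stop("gene tree leaves missing from alignment: ",
         paste(stray, collapse = ", "))
  }
  structure(
    list(family_id = family_id, alignment = alignment, gene_tree = gene_tree,
         taxon_of = taxon_of[seqs], verdict = "kept",
         log = empty_curation_log()),
    class = "gene_family"
  )
}

empty_curation_log <- function() {
  tibble::tibble(family_id = character(), sequence = character(),
                 reason = character(), pass = integer())
}

#' @export
print.gene_family <- function(x, ...) {
  cat(sprintf("<gene_family> %s: %d sequences x %d sites, %d tree leaves [%s]\n",
              x$family_id, nrow(x$alignment), ncol(x$alignment),
              length(x$gene_tree$tip.label), x$verdict))
  invisible(x)
}

# drop sequences from alignment + tree + map, appending to the log
drop_sequences <- function(fam, seqs, reason, pass = NA_integer_) {
  if (length(seqs) == 0L) return(fam)
  keep <- setdiff(rownames(fam$alignment), seqs)
  fam$alignment <- aa_alignment(unclass(fam$alignment)[keep, , drop = FALSE])
  in_tree <- intersect(seqs, fam$gene_tree$tip.label)
  if (length(in_tree) > 0) {
    fam$gene_tree <- prune_leaves(fam$gene_tree, in_tree)
  }
  fam$taxon_of <- fam$taxon_of[keep]
  fam$log <- dplyr::bind_rows(fam$log, tibble::tibble(
    family_id = fam$family_id, sequence = seqs,
    reason = reason, pass = pass
  ))
  fam
}

#' Gap/length filter
#'
#' Removes sequences whose unobserved fraction (gaps + ambiguity codes)
#' exceeds `max_gap_frac`, then excludes the family outright unless the
#' alignment keeps strictly more than `min_sites` columns and at least two
#' sequences.  These are verdicts, not errors: the returned family's
#' `verdict` field says what happened.
#'
#' @param fam a [gene_family()].
#' @param max_gap_frac maximum tolerated gap fraction per sequence.
#' @param min_sites alignments must have more than this many columns.
#' @return the filtered `gene_family`.
#' @export
gap_length_filter <- function(fam, max_gap_frac = 0.25, min_sites = 50) {
  stopifnot(inherits(fam, "gene_family"))
  if (fam$verdict != "kept") return(fam)
  m <- encode_alignment(fam$alignment)
  gap_frac <- rowMeans(m == 0L)
  gappy <- rownames(fam$alignment)[gap_frac > max_gap_frac]
  fam <- drop_sequences(fam, gappy, "gap_fraction")
  if (ncol(fam$alignment) <= min_sites || nrow(fam$alignment) < 2L) {
    fam$verdict <- "excluded_too_short"
  }
  fam
}

#' Iterated long-branch filter
#'
#' Each pass computes the mean and sample SD of the current gene tree's
#' branch lengths and removes every leaf whose *terminal* branch exceeds
#' `mean + z_threshold * SD`, then prunes the tree (no re-inference) and
#' repeats.  Iterating matters: a single extreme branch inflates the SD
#' enough to shield lesser outliers, which only the second pass catches.
#' By default the mean/SD pool is all branches (internal + terminal); set
#' `pool = "terminal"` to use terminal branches only.  If a pass would
#' leave fewer than 4 leaves it is skipped and the family is flagged
#' (`fam$flags`).
#'
#' @param fam a [gene_family()] whose tree has >= 4 leaves.
#' @param z_threshold SD multiplier above the mean.
#' @param n_passes number of removal passes.
#' @param pool `"all"` branches or `"terminal"` branches for the mean/SD.
#' @return the filtered `gene_family`.
#' @export
long_branch_filter <- function(fam, z_threshold = 2, n_passes = 2,
                               pool = c("all", "terminal")) {
  stopifnot(inherits(fam, "gene_family"))
  pool <- match.arg(pool)
  if (fam$verdict != "kept") return(fam)
  if (length(fam$gene_tree$tip.label) < 4L) {
    stop("long-branch filtering needs a gene tree with >= 4 leaves")
  }
  for (pass in seq_len(n_passes)) {
    tr <- fam$gene_tree
    lens <- if (pool == "all") tr$edge.length else terminal_branch_lengths(tr)
    mu <- mean(lens)
    sdv <- stats::sd(lens)
    if (is.na(sdv) || sdv == 0) break
    term <- terminal_branch_lengths(tr)
    long <- names(term)[term > mu + z_threshold * sdv]
    if (length(long) == 0L) next
    if (length(tr$tip.label) - length(long) < 4L) {
      fam$flags <- c(fam$flags,
                     sprintf("long_branch_pass%d_skipped_small_tree", pass))
      break
    }
    fam <- drop_sequences(fam, long, paste0("long_branch_pass", pass),
                          pass = pass)
  }
  fam
}

#' Resolve paralogues
#'
#' For every taxon owning more than one sequence: if the copies form a
#' monophyletic group on the (unrooted) gene tree they are in-paralogues,
#' and only the copy with the shortest terminal branch is kept; if any
#' multi-copy taxon's sequences are *not* monophyletic (out-paralogues), the
#' whole family is excluded (`verdict = "excluded_out_paralog"`) to keep
#' hidden paralogy out of the supermatrix.
#'
#' @param fam a [gene_family()].
#' @return the resolved `gene_family`.
#' @export
resolve_paralogs <- function(fam) {
  stopifnot(inherits(fam, "gene_family"))
  if (fam$verdict != "kept") return(fam)
  by_taxon <- split(names(fam$taxon_of), fam$taxon_of)
  multi <- by_taxon[lengths(by_taxon) > 1L]
  if (length(multi) == 0L) return(fam)
  tr <- fam$gene_tree
  for (copies in multi) {
    in_tree <- intersect(copies, tr$tip.label)
    if (length(in_tree) < length(copies) || !is_monophyletic(tr, copies)) {
      fam$verdict <- "excluded_out_paralog"
      return(fam)
    }
  }
  term <- terminal_branch_lengths(tr)
  for (copies in multi) {
    keep <- copies[which.min(term[copies])]
    fam <- drop_sequences(fam, setdiff(copies, keep), "paralog_pruned")
  }
  fam
}

#' Curate a gene family
#'
#' The full per-family pipeline in its documented order: gap/length filter,
#' paralogue resolution, then the iterated long-branch filter.  Each filter
#' is a no-op on an already-excluded family.
#'
#' @param fam a [gene_family()].
#' @param max_gap_frac,min_sites passed to [gap_length_filter()].
#' @param z_threshold,n_passes,pool passed to [long_branch_filter()].
#' @return the curated `gene_family`.
#' @export
curate_family <- function(fam, max_gap_frac = 0.25, min_sites = 50,
                          z_threshold = 2, n_passes = 2,
                          pool = c("all", "terminal")) {
  fam <- gap_length_filter(fam, max_gap_frac, min_sites)
  fam <- resolve_paralogs(fam)
  if (fam$verdict == "kept" && length(fam$gene_tree$tip.label) >= 4L) {
    fam <- long_branch_filter(fam, z_threshold, n_passes, match.arg(pool))
  }
  fam
}

#' Replay a curation log
#'
#' Applies the removals recorded in a curation log to the original family,
#' reproducing the curated family exactly (the log is a complete audit
#' trail: every removed sequence appears exactly once with one reason).
#'
#' @param fam the *original* (uncurated) [gene_family()].
#' @param log a curation-log tibble (`fam$log` of the curated family).
#' @param verdict the curated family's verdict to restore.
#' @return the reconstructed `gene_family`.
#' @export
replay_curation_log <- function(fam, log, verdict = "kept") {
  stopifnot(inherits(fam, "gene_family"))
  if (anyDuplicated(log$sequence)) {
    stop("curation log lists a sequence more than once")
  }
  for (i in seq_len(nrow(log))) {
    fam <- drop_sequences(fam, log$sequence[i], log$reason[i], log$pass[i])
  }
  fam$verdict <- verdict
  fam
}

#' Read a gene family from files
#'
#' Per-family inputs as produced by standard tooling: a FASTA (or relaxed
#' PHYLIP) alignment, a Newick gene tree, and an optional two-column TSV
#' (no header: sequence label, taxon label).
#'
#' @param family_id identifier.
#' @param aln_file,tree_file,map_file input paths (`map_file` optional).
#' @return a [gene_family()].
#' @export
read_gene_family <- function(family_id, aln_file, tree_file, map_file = NULL) {
  aln <- read_alignment(aln_file)
  tr <- parse_newick(file = tree_file)
  taxon_of <- NULL
  if (!is.null(map_file)) {
    m <- utils::read.table(map_file, sep = "\t", header = FALSE,
                           col.names = c("sequence", "taxon"),
                           colClasses = "character")
    taxon_of <- stats::setNames(m$taxon, m$sequence)
  }
  gene_family(family_id, aln, tr, taxon_of)
}

#' Write a curated gene family
#'
#' Emits the filtered FASTA, the pruned Newick tree, and the curation log as
#' TSV, under a common path prefix.
#'
#' @param fam a [gene_family()].
#' @param out_prefix output path prefix.
#' @return invisibly, the files written.
#' @export
write_gene_family <- function(fam, out_prefix) {
  fa <- paste0(out_prefix, ".fasta")
  nwk <- paste0(out_prefix, ".nwk")
  logf <- paste0(out_prefix, "_curation_log.tsv")
  write_alignment(fam$alignment, fa)
  write_newick(fam$gene_tree, nwk)
  log <- fam$log
  log$verdict <- fam$verdict
  utils::write.table(log, logf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fa, nwk, logf))
}
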