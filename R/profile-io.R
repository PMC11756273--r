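#' Read site-profile files
#'
#' Two dialects of per-site amino-acid frequency tables are understood:
#' \describe{
#'   \item{`iqtree_fs`}{the IQ-TREE site-frequency layout (`-fs`): one line
#'     per site, `site_index` followed by 20 frequencies.  A file holds one
#'     profile set.}
#'   \item{`phylobayes_ss`}{a Phylobayes `readpb -ss`-style block layout: a
#'     header line listing the 20 amino acids, then one block per posterior
#'     sample, each block one line per site (`site_index` + 20
#'     frequencies, the site index restarting at 1 in every block).}
#' }
#' Rows are renormalized to sum to one (input files are usually rounded);
#' frequencies are always in the package's alphabetical amino-acid order
#' (see [aa_states()]).
#'
#' @param path input file.
#' @param dialect `"iqtree_fs"` or `"phylobayes_ss"`.
#' @return a list of profile sets, one per posterior sample (always length 1
#'   for `iqtree_fs`); each set is an n_sites x 20 matrix.
#' @export
read_site_profiles <- function(path, dialect = c("iqtree_fs", "phylobayes_ss")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("empty site-profile file: ", path)
  first_data <- 1L
  if (dialect == "phylobayes_ss") first_data <- keep[keep > min(keep)][1]  # skip header

  parse_row <- function(ln) {
    fields <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      stop("non-numeric value on line ", ln, " of ", path)
    }
    if (length(vals) != 21L) {
      stop("line ", ln, " of ", path, " has ", length(vals),
           " fields; expected a site index plus 20 frequencies")
    }
    vals
  }

  data_lines <- if (dialect == "iqtree_fs") keep else keep[keep >= first_data]
  rows <- lapply(data_lines, parse_row)
  idx <- vapply(rows, `[`, numeric(1), 1)
  freqs <- do.call(rbind, lapply(rows, function(r) r[-1]))

  blocks <- split(seq_along(idx), cumsum(idx == idx[1]))
  n_sites <- length(blocks[[1]])
  samples <- lapply(blocks, function(b) {
    if (length(b) != n_sites) {
      stop("inconsistent block length in ", path, ": ", length(b),
           " sites vs ", n_sites)
    }
    m <- as_profile_matrix(freqs[b, , drop = FALSE])
    colnames(m) <- AA_STATES
    rownames(m) <- NULL
    m
  })
  names(samples) <- NULL
  samples
}

#' Write site profiles
#'
#' Inverse of [read_site_profiles()].  `iqtree_fs` writes a single profile
#' set; `phylobayes_ss` writes one block per supplied sample under an
#' amino-acid header line.
#'
#' @param profiles an n_sites x 20 matrix (or list of them for the
#'   `phylobayes_ss` dialect, one per posterior sample), or a site-profile
#'   `aa_model`.
#' @param path output file.
#' @param dialect `"iqtree_fs"` or `"phylobayes_ss"`.
#' @param digits significant digits written.
#' @return `path`, invisibly.
#' @export
write_site_profiles <- function(profiles, path,
                                dialect = c("iqtree_fs", "phylobayes_ss"),
                                digits = 15) {
  dialect <- match.arg(dialect)
  if (inherits(profiles, "aa_model")) {
    if (profiles$flavour != "site_profile") {
      stop("only site-profile models carry per-site profiles")
    }
    profiles <- profiles$site_profiles
  }
  if (!is.list(profiles)) profiles <- list(profiles)
  profiles <- lapply(profiles, as_profile_matrix)
  fmt_block <- function(m) {
    paste(seq_len(nrow(m)),
          apply(m, 1, function(r) paste(formatC(r, digits = digits, format = "g"),
                                        collapse = " ")))
  }
  if (dialect == "iqtree_fs") {
    if (length(profiles) != 1L) {
      stop("iqtree_fs holds a single profile set; got ", length(profiles))
    }
    writeLines(fmt_block(profiles[[1]]), path)
  } else {
    out <- c(paste(AA_STATES, collapse = " "),
             unlist(lapply(profiles, fmt_block)))
    writeLines(out, path)
  }
  invisible(path)
}

#' Average site profiles across posterior samples
#'
#' The posterior-mean step of the PMSF export: given per-site profiles from
#' several posterior samples (as read by [read_site_profiles()]), take the
#' arithmetic mean per site across samples and renormalize.  The result is
#' the per-site profile set fed to a site-profile model or written out in
#' the IQ-TREE dialect.
#'
#' @param samples list of n_sites x 20 matrices with a common site count.
#' @return an n_sites x 20 matrix of averaged profiles.
#' @export
average_site_profiles <- function(samples) {
  if (!is.list(samples)) samples <- list(samples)
  samples <- lapply(samples, as_profile_matrix)
  ns <- vapply(samples, nrow, integer(1))
  if (length(unique(ns)) != 1L) {
    stop("samples disagree on the site count: ", paste(unique(ns), collapse = ", "))
  }
  avg <- Reduce(`+`, samples) / length(samples)
  as_profile_matrix(avg)
}
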