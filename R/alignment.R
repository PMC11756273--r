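#' Amino-acid alignments
#'
#' An `aa_alignment` is a rectangular taxa-by-sites character matrix over the
#' 20 canonical amino acids plus gap (`-`, `?`) and ambiguity
#' (`X B Z J * .`) characters, with unique ordered taxon labels as row
#' names.  It is the unit on which the diversity statistic is computed and
#' the output of the simulator.
#'
#' @param x a character matrix (rows = taxa) or a list/vector of equal-length
#'   sequence strings named by taxon.
#' @return an object of class `aa_alignment`.
#' @examples
#' aln <- aa_alignment(c(s1 = "ACD", s2 = "A-D"))
#' dim(aln)
#' @export
aa_alignment <- function(x) {
  if (!is.matrix(x)) {
    x <- unlist(x)
    if (is.null(names(x))) stop("sequences must be named by taxon")
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) {
      stop("sequences are not aligned: lengths ", paste(unique(lens), collapse = ", "))
    }
    x <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(x) <- names(lens)
  } else {
    x <- toupper(x)
  }
  if (is.null(rownames(x))) stop("alignment needs taxon row names")
  if (anyDuplicated(rownames(x))) stop("duplicate taxon labels in alignment")
  aa_encode(as.vector(x))  # validates the character set
  structure(x, class = c("aa_alignment", "matrix"))
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("<aa_alignment> %d taxa x %d sites (%.1f%% unobserved)\n",
              nrow(x), ncol(x), 100 * mean(encode_alignment(x) == 0L)))
  invisible(x)
}

# integer encoding (0 = unobserved), same shape
encode_alignment <- function(aln) {
  m <- matrix(aa_encode(as.vector(unclass(aln))), nrow = nrow(aln))
  rownames(m) <- rownames(aln)
  m
}

decode_alignment <- function(m) {
  out <- matrix(aa_decode(as.vector(m)), nrow = nrow(m))
  rownames(out) <- rownames(m)
  aa_alignment(out)
}

#' Read an amino-acid alignment
#'
#' FASTA is read through Biostrings; relaxed PHYLIP (sequential, taxon names
#' of any length separated from the sequence by whitespace) through
#' phangorn.
#'
#' @param file input path.
#' @param format `"fasta"` or `"phylip"`; `"auto"` sniffs for a leading `>`.
#' @return an [aa_alignment()].
#' @export
read_alignment <- function(file, format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(file, n = 1)
    format <- if (startsWith(trimws(first), ">")) "fasta" else "phylip"
  }
  if (format == "fasta") {
    # BStringSet rather than AAStringSet: '?' gaps are outside the AA alphabet
    seqs <- Biostrings::readBStringSet(file)
    aa_alignment(stats::setNames(as.character(seqs), names(seqs)))
  } else {
    pd <- phangorn::read.phyDat(file, format = "phylip", type = "AA")
    m <- as.character(pd)
    rn <- rownames(m)
    m <- matrix(toupper(m), nrow = nrow(m))
    rownames(m) <- rn
    aa_alignment(m)
  }
}

#' Write an amino-acid alignment
#'
#' @param aln an [aa_alignment()].
#' @param file output path.
#' @param format `"fasta"` or `"phylip"` (relaxed, sequential).
#' @return `file`, invisibly.
#' @export
write_alignment <- function(aln, file, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  seqs <- apply(unclass(aln), 1, paste, collapse = "")
  if (format == "fasta") {
    writeLines(paste0(">", names(seqs), "\n", seqs), file)
  } else {
    writeLines(c(paste(nrow(aln), ncol(aln)),
                 paste(format(names(seqs)), seqs)), file)
  }
  invisible(file)
}

#' Copy a gap mask onto a simulated alignment
#'
#' Every cell that is a gap or ambiguity character in `template` becomes a
#' gap in `sim`; all other cells are untouched.  Used so that
#' parametric-bootstrap replicates share the observed alignment's
#' missing-data pattern, which the per-column diversity statistic is
#' sensitive to.  Taxa are matched by label (order free); site counts must
#' agree.
#'
#' @param sim the simulated [aa_alignment()].
#' @param template the observed alignment supplying the mask.
#' @return `sim` with the template's unobserved cells gapped.
#' @export
apply_gap_mask <- function(sim, template) {
  if (ncol(sim) != ncol(template)) {
    stop("site count mismatch: ", ncol(sim), " vs ", ncol(template))
  }
  if (!setequal(rownames(sim), rownames(template))) {
    stop("taxa of simulated alignment and template differ")
  }
  tm <- encode_alignment(template)[rownames(sim), , drop = FALSE]
  out <- unclass(sim)
  out[tm == 0L] <- "-"
  aa_alignment(out)
}
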