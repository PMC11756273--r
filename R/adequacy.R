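#' Across-sites amino-acid diversity (div)
#'
#' The mean, over alignment columns, of the number of distinct canonical
#' amino acids observed in the column.  Gap and ambiguity characters are
#' unobserved and never count as residues; columns in which no residue is
#' observed carry no compositional information and are excluded from the
#' mean (an alignment with no scorable column is an error).  `div` lies in
#' `[1, 20]`, is invariant to taxon and site order, and is the statistic
#' compared between real and simulated data in the parametric-bootstrap
#' adequacy test.
#'
#' @param aln an [aa_alignment()].
#' @return the div value, a single number in `[1, 20]`.
#' @examples
#' div(aa_alignment(c(a = "AA", b = "AC", c = "CD")))  # (2 + 3) / 2
#' @export
div <- function(aln) {
  div_int(encode_alignment(aln))
}

div_int <- function(m) {
  counts <- integer(ncol(m))
  for (s in 1:20) counts <- counts + as.integer(colSums(m == s) > 0L)
  scorable <- counts > 0L
  if (!any(scorable)) {
    stop("alignment has no column with an observed residue; div is undefined")
  }
  mean(counts[scorable])
}

#' Parametric-bootstrap Z-score
#'
#' Standard deviate of the observed statistic against the replicate
#' distribution, with the sign convention used by Phylobayes-style adequacy
#' reports: `(mean(replicates) - observed) / sd(replicates)` -- i.e. the
#' negative of the usual standardisation, so a model that *over*produces
#' diversity in simulation (simulated mean above the observed value) gets a
#' positive Z.  `sign = "standard"` gives the plain
#' `(observed - mean) / sd` instead; the two differ only in sign.  The SD is
#' the sample SD (n - 1 denominator).
#'
#' @param div_observed observed statistic.
#' @param div_replicates numeric vector of >= 2 replicate values.
#' @param sign `"phylobayes"` (default, reported convention) or
#'   `"standard"`.
#' @return the signed Z-score.
#' @examples
#' z_score(4.0, c(5.0, 5.2, 4.8))  # +5
#' @export
z_score <- function(div_observed, div_replicates,
                    sign = c("phylobayes", "standard")) {
  sign <- match.arg(sign)
  if (length(div_replicates) < 2L) {
    stop("need at least 2 replicates to form a standard deviate")
  }
  s <- stats::sd(div_replicates)
  if (s == 0) {
    stop("replicate statistics are all identical (SD = 0); ",
         "increase the number of replicates or check the simulation")
  }
  z <- (mean(div_replicates) - div_observed) / s
  if (sign == "standard") z <- -z
  z
}

#' Parametric-bootstrap test of model adequacy
#'
#' Simulates `n_reps` replicate alignments of the observed alignment's size
#' under the candidate model on the fixed tree, computes [div()] for each,
#' and summarises the deviation of the observed div as a signed
#' [z_score()].  A model is declared `adequate` when `-2 < Z < 2`; Z grows
#' past 2 as the model increasingly *under*states the data's across-site
#' compositional heterogeneity (simulated columns too diverse).  The full
#' replicate distribution is retained: Z-scores are only trustworthy when
#' that distribution is roughly normal, so inspect it (see
#' [autoplot.adequacy_result()]).
#'
#' @param obs the observed [aa_alignment()].
#' @param model the candidate `aa_model`, parametrized exactly as it was (or
#'   would be) used to analyse the data.
#' @param tree the fixed [ape::phylo] tree with branch lengths.
#' @param n_reps number of bootstrap replicates (>= 2; 100 is conventional).
#' @param seed master integer seed; replicate r simulates from a substream
#'   derived from it.
#' @param gap_mode `"copy"` (default) copies the observed alignment's
#'   gap/ambiguity mask onto every replicate, so replicate columns have the
#'   observed per-column sample sizes, to which div is sensitive; `"none"`
#'   simulates complete matrices.
#' @param model_spec optional label stored in the result.
#' @return an object of class `adequacy_result`; see [tidy()][generics::tidy]
#'   / [glance()][generics::glance] methods and [adequacy_report()].
#' @export
adequacy_test <- function(obs, model, tree, n_reps = 100, seed,
                          gap_mode = c("copy", "none"),
                          model_spec = NULL) {
  gap_mode <- match.arg(gap_mode)
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 2L) {
    stop("n_reps must be >= 2 (one replicate cannot yield an SD)")
  }
  if (!setequal(rownames(obs), tree$tip.label)) {
    stop("observed alignment taxa and tree leaves differ")
  }
  fixed <- model_fixed_length(model)
  if (!is.na(fixed) && fixed != ncol(obs)) {
    stop("site-profile model length (", fixed,
         ") does not match the observed alignment (", ncol(obs), " sites)")
  }
  gap_mask <- if (gap_mode == "copy") encode_alignment(obs) == 0L else NULL
  div_obs <- div(obs)
  div_reps <- vapply(seq_len(n_reps), function(r) {
    st <- simulate_states(tree, model, n_sites = ncol(obs),
                          seed = replicate_seed(seed, r),
                          gap_mask = gap_mask)
    div_int(st)
  }, numeric(1))
  z <- z_score(div_obs, div_reps)
  structure(
    list(
      div_observed = div_obs,
      div_replicates = div_reps,
      sim_mean = mean(div_reps),
      sim_sd = stats::sd(div_reps),
      z_score = z,
      n_replicates = n_reps,
      verdict = if (z > -2 && z < 2) "adequate" else "inadequate",
      model_spec = model_spec %||% paste0(model$flavour, "/",
                                          attr(model$exchangeabilities, "name")),
      seed = seed,
      gap_mode = gap_mode
    ),
    class = "adequacy_result"
  )
}

# substream master seed for bootstrap replicate r
replicate_seed <- function(seed, r) {
  as.integer((as.double(seed) * 48271 + r * 69621) %% 2147483399 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.adequacy_result <- function(x, ...) {
  cat(sprintf(
    paste0("<adequacy_result> %s\n",
           "  observed div %.4f | simulated %.4f +/- %.4f (n = %d, gaps: %s)\n",
           "  Z = %.2f -> %s (adequate iff -2 < Z < 2)\n"),
    x$model_spec, x$div_observed, x$sim_mean, x$sim_sd,
    x$n_replicates, x$gap_mode, x$z_score, x$verdict))
  invisible(x)
}

#' Tidy an adequacy result
#'
#' `tidy()` returns one row per bootstrap replicate (its div value);
#' `glance()` returns the one-row model-level summary in the layout of a
#' results table: observed div, simulated mean and SD, Z-score, verdict.
#'
#' @param x an `adequacy_result`.
#' @param ... unused.
#' @return a tibble.
#' @importFrom generics tidy
#' @exportS3Method generics::tidy
tidy.adequacy_result <- function(x, ...) {
  tibble::tibble(
    model = x$model_spec,
    replicate = seq_len(x$n_replicates),
    div = x$div_replicates
  )
}

#' @rdname tidy.adequacy_result
#' @importFrom generics glance
#' @exportS3Method generics::glance
glance.adequacy_result <- function(x, ...) {
  tibble::tibble(
    model = x$model_spec,
    div_observed = x$div_observed,
    sim_mean = x$sim_mean,
    sim_sd = x$sim_sd,
    z_score = x$z_score,
    n_replicates = x$n_replicates,
    verdict = x$verdict,
    gap_mode = x$gap_mode,
    seed = x$seed
  )
}

#' Plot the replicate div distribution
#'
#' Histogram of the bootstrap replicate div values with the observed value
#' marked -- the visual check that should accompany any Z-score reading,
#' since the +/-2 rule presumes near-normal replicate distributions.
#'
#' @param object an `adequacy_result`.
#' @param bins histogram bins.
#' @param ... unused.
#' @return a ggplot object.
#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.adequacy_result <- function(object, bins = 20, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$div)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$div_observed,
                        colour = "red", linetype = 2) +
    ggplot2::labs(
      title = object$model_spec,
      subtitle = sprintf("observed div = %.3f, Z = %.2f (%s)",
                         object$div_observed, object$z_score, object$verdict),
      x = "simulated div", y = "replicates"
    )
}

#' Write an adequacy report
#'
#' Writes the results-table view of one or more adequacy tests: a summary
#' TSV with one row per model (observed div, simulated mean and SD, Z-score,
#' verdict), a JSON copy of the same summary plus the decision flags in
#' effect, and one distribution TSV per model holding every replicate div
#' value together with the observed value, ready for histogram plotting.
#'
#' @param results an `adequacy_result` or list of them.
#' @param out_prefix path prefix for the output files.
#' @return invisibly, a character vector of the files written.
#' @export
adequacy_report <- function(results, out_prefix) {
  if (inherits(results, "adequacy_result")) results <- list(results)
  if (length(results) == 0L) stop("no adequacy results to report")
  stopifnot(all(vapply(results, inherits, logical(1), "adequacy_result")))
  summary_tbl <- dplyr::bind_rows(lapply(results, glance))
  summary_file <- paste0(out_prefix, "_summary.tsv")
  utils::write.table(summary_tbl, summary_file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  json_file <- paste0(out_prefix, "_summary.json")
  jsonlite::write_json(summary_tbl, json_file, digits = NA, pretty = TRUE)
  dist_files <- vapply(seq_along(results), function(i) {
    r <- results[[i]]
    safe <- gsub("[^A-Za-z0-9._-]+", "_", r$model_spec)
    f <- paste0(out_prefix, "_", safe, "_div.tsv")
    d <- dplyr::bind_rows(
      tibble::tibble(model = r$model_spec, kind = "observed",
                     replicate = NA_integer_, div = r$div_observed),
      dplyr::mutate(tidy(r), kind = "replicate", .after = "model")
    )
    utils::write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }, character(1))
  invisible(c(summary_file, json_file, dist_files))
}
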