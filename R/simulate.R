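#' Per-site random substreams
#'
#' Each alignment site is simulated from its own deterministic substream,
#' derived from the master seed and the site index by an integer hash.  This
#' makes simulating a multi-site alignment in one call bit-identical to
#' simulating each site separately (with the matching derived seed) and
#' concatenating -- the "one site at a time" scheme PMSF simulation needs.
#'
#' @param seed master integer seed.
#' @param n_sites number of sites.
#' @return integer vector of `n_sites` derived seeds, each in `[1, 2^31)`.
#' @export
derive_site_seeds <- function(seed, n_sites) {
  seed <- as.double(seed)
  i <- seq_len(n_sites)
  as.integer((seed * 1000003 + i * 7919) %% 2147483629 + 1)
}

#' Simulate an amino-acid alignment on a tree
#'
#' Forward simulation under any of the three model flavours.  Per site: a
#' gamma rate category is drawn uniformly over the K categories; for mixture
#' models a profile class is drawn by its weight; the root state is drawn
#' from the governing profile; states then evolve down the tree through the
#' rate-scaled transition probabilities of the site's rate matrix.  With
#' Poisson exchangeabilities the transition kernel has the closed form
#' `exp(-b*r*t) I + (1 - exp(-b*r*t)) 1 pi'` (`b = 1/(1 - sum(pi^2))`),
#' which is used directly; other exchangeabilities go through the
#' eigendecomposition kernel.
#'
#' Identical `(tree, model, n_sites, seed)` always reproduce the identical
#' alignment.  Randomness is organised per site (see
#' [derive_site_seeds()]), so site-at-a-time simulation concatenates to the
#' batch result bit-for-bit.
#'
#' @param tree an [ape::phylo] tree; every edge must have a non-negative
#'   length.  Unrooted (trifurcating-root) trees are simulated from their
#'   stored root node, which for a reversible model does not affect the
#'   distribution.
#' @param model an `aa_model`.
#' @param n_sites number of sites; for a site-profile model the profile
#'   count fixes the length and `n_sites` must be `NULL` or equal to it.
#' @param seed master integer seed.
#' @param gap_template optional observed [aa_alignment()] whose gap pattern
#'   is copied onto the simulated alignment (see [apply_gap_mask()]).
#' @param site_seeds advanced: explicit per-site substream seeds, overriding
#'   the derivation from `seed` (used to reproduce single sites of a larger
#'   simulation).
#' @return an [aa_alignment()] with the tree's leaf labels as taxa.
#' @examples
#' tr <- parse_newick("((A:0.2,B:0.2):0.1,(C:0.2,D:0.2):0.1);")
#' m <- homogeneous_model(exchangeability("Poisson"), uniform_profile())
#' simulate_alignment(tr, m, n_sites = 10, seed = 1)
#' @export
simulate_alignment <- function(tree, model, n_sites = NULL, seed,
                               gap_template = NULL, site_seeds = NULL) {
  m <- simulate_states(tree, model, n_sites, seed, gap_template, site_seeds)
  decode_alignment(m)
}

# integer-state core of simulate_alignment (0 = gap); the adequacy loop
# uses this directly to skip character decode/re-encode on every replicate
simulate_states <- function(tree, model, n_sites = NULL, seed,
                            gap_template = NULL, site_seeds = NULL,
                            gap_mask = NULL) {
  stopifnot(inherits(model, "aa_model"))
  check_branch_lengths(tree)
  fixed <- model_fixed_length(model)
  if (!is.na(fixed)) {
    if (!is.null(n_sites) && n_sites != fixed) {
      stop("site-profile model fixes the length at ", fixed,
           " sites; n_sites = ", n_sites, " conflicts")
    }
    n_sites <- fixed
  }
  if (is.null(n_sites) || n_sites < 1L) stop("n_sites must be >= 1")
  n_sites <- as.integer(n_sites)
  if (!is.null(gap_template)) {
    if (!setequal(rownames(gap_template), tree$tip.label)) {
      stop("gap template taxa do not match the tree's leaves")
    }
    if (ncol(gap_template) != n_sites) {
      stop("gap template has ", ncol(gap_template), " sites, expected ", n_sites)
    }
  }
  if (is.null(site_seeds)) site_seeds <- derive_site_seeds(seed, n_sites)
  if (length(site_seeds) != n_sites) stop("need one substream seed per site")

  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  ntip <- length(tree$tip.label)
  n_edge <- nrow(tree$edge)
  is_mix <- model$flavour == "mixture"
  poisson <- is_poisson_exchangeability(model$exchangeabilities)
  n_rand <- as.integer(is_mix) + 2L + n_edge * (if (poisson) 2L else 1L)

  U <- vapply(site_seeds, function(s) {
    set.seed(s)
    stats::runif(n_rand)
  }, numeric(n_rand))           # n_rand x n_sites
  row_at <- 0L
  take <- function() {
    row_at <<- row_at + 1L
    U[row_at, ]
  }

  K <- model$gamma$n_categories
  rates <- model$gamma$category_rates
  if (is_mix) {
    u <- take()
    cls <- findInterval(u, cumsum(model$class_weights),
                        left.open = TRUE) + 1L
    cls[cls > nrow(model$class_profiles)] <- nrow(model$class_profiles)
  }
  cat_i <- pmin(ceiling(take() * K), K)
  cat_i[cat_i < 1L] <- 1L
  site_rate <- rates[cat_i]

  # per-site governing profile, as an n_sites x 20 matrix (possibly shared)
  prof <- switch(model$flavour,
    homogeneous = matrix(model$profile, n_sites, 20, byrow = TRUE),
    mixture = model$class_profiles[cls, , drop = FALSE],
    site_profile = model$site_profiles
  )
  cum_prof <- t(apply(prof, 1, cumsum))
  cum_prof[, 20] <- 1
  draw_from_profile <- function(rows, u) {
    # one categorical draw per row of cum_prof[rows, ]
    cp <- cum_prof[rows, , drop = FALSE]
    pmin(rowSums(cp < u) + 1L, 20L)
  }

  states <- matrix(0L, ntip + tree$Nnode, n_sites)
  root <- tree$edge[1, 1]
  states[root, ] <- draw_from_profile(seq_len(n_sites), take())

  if (poisson) {
    beta <- 1 / (1 - rowSums(prof^2))
    for (e in seq_len(n_edge)) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      t_e <- tree$edge.length[e]
      u_keep <- take()
      u_draw <- take()
      keep <- u_keep < exp(-beta * site_rate * t_e)
      st <- states[parent, ]
      if (any(!keep)) {
        redo <- which(!keep)
        st[redo] <- draw_from_profile(redo, u_draw[redo])
      }
      states[child, ] <- st
    }
  } else {
    # group sites sharing (profile row, rate category); one P per group/edge
    prof_id <- switch(model$flavour,
      homogeneous = rep(1L, n_sites),
      mixture = cls,
      site_profile = seq_len(n_sites)
    )
    groups <- split(seq_len(n_sites), paste(prof_id, cat_i))
    rate_of_group <- lapply(groups, function(ix) {
      list(sites = ix,
           rm = with_eigen(build_rate_matrix(model$exchangeabilities,
                                             prof[ix[1], ])),
           rate = site_rate[ix[1]])
    })
    for (e in seq_len(n_edge)) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      t_e <- tree$edge.length[e]
      u_draw <- take()
      st <- states[parent, ]
      out <- integer(n_sites)
      for (g in rate_of_group) {
        P <- transition_matrix(g$rm, t_e * g$rate)
        Pcum <- t(apply(P, 1, cumsum))
        Pcum[, 20] <- 1
        rows <- Pcum[st[g$sites], , drop = FALSE]
        out[g$sites] <- pmin(rowSums(rows < u_draw[g$sites]) + 1L, 20L)
      }
      states[child, ] <- out
    }
  }

  m <- states[seq_len(ntip), , drop = FALSE]
  rownames(m) <- tree$tip.label
  if (!is.null(gap_template) && is.null(gap_mask)) {
    gap_mask <- encode_alignment(gap_template) == 0L
  }
  if (!is.null(gap_mask)) {
    m[gap_mask[rownames(m), , drop = FALSE]] <- 0L
  }
  m
}
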