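#' Mean pairwise distance of a species set
#'
#' Average distance over all unordered pairs of the given species
#' (presence-weighted only: the data are binary).
#'
#' @param present_species character vector of species present.
#' @param distances labelled distance matrix covering them.
#' @return the mean pairwise distance, or `NA` when fewer than 2 species.
#' @export
mpd <- function(present_species, distances) {
  idx <- match(present_species, rownames(distances))
  if (anyNA(idx)) stop("species missing from distance matrix: ",
                       paste(present_species[is.na(idx)], collapse = ", "))
  if (length(idx) < 2) return(NA_real_)
  row <- matrix(0L, 1, nrow(distances))
  row[1, idx] <- 1L
  mpd_rows_cpp(row, distances)[1]
}

#' Mean nearest-taxon distance of a species set
#'
#' Average, over present species, of each species' minimum distance to
#' another present species.
#'
#' @inheritParams mpd
#' @return the mean nearest-neighbour distance, or `NA` when fewer than 2.
#' @export
mntd <- function(present_species, distances) {
  idx <- match(present_species, rownames(distances))
  if (anyNA(idx)) stop("species missing from distance matrix: ",
                       paste(present_species[is.na(idx)], collapse = ", "))
  if (length(idx) < 2) return(NA_real_)
  row <- matrix(0L, 1, nrow(distances))
  row[1, idx] <- 1L
  mntd_rows_cpp(row, distances)[1]
}

#' Independent-swap null draws of a binary community matrix
#'
#' Runs a Markov chain of checkerboard swaps: at each attempt two random
#' rows and two random columns are picked and, if the 2x2 submatrix is one
#' of the two checkerboard states, it is exchanged for the other. Snapshots
#' are emitted after `burn_in` attempted swaps and every `thin` attempts
#' thereafter. Every draw has exactly the original row sums (site richness)
#' and column sums (species prevalence); the chain is symmetric, so its
#' stationary distribution is uniform over the fixed-margin set.
#'
#' @param community community list or a binary sites x species matrix.
#' @param n_draws number of matrices to emit.
#' @param burn_in attempted swaps before the first draw.
#' @param thin attempted swaps between consecutive draws.
#' @param seed optional integer seed.
#' @return list of `n_draws` integer matrices with dimnames preserved.
#' @export
independent_swap <- function(community, n_draws = 999, burn_in = 10000,
                             thin = 1000, seed = NULL) {
  occ <- if (is.list(community)) community$occupancy else community
  if (!all(occ %in% c(0L, 1L))) stop("independent swap requires a binary matrix")
  storage.mode(occ) <- "integer"
  if (!has_checkerboard(occ)) {
    warning("matrix has no checkerboard 2x2 submatrix; draws equal the input")
  }
  if (!is.null(seed)) set.seed(seed)
  draws <- swap_chain_cpp(occ, as.integer(n_draws), as.integer(burn_in),
                          as.integer(thin))
  lapply(draws, function(m) { dimnames(m) <- dimnames(occ); m })
}

# does any pair of rows/columns form a [[1,0],[0,1]]-type submatrix?
has_checkerboard <- function(occ) {
  a <- occ %*% t(1L - occ)  # a[i,j] = #columns with 1 in row i, 0 in row j
  any(a > 0 & t(a) > 0)
}

#' Standardized effect sizes of MPD / MNTD against the independent-swap null
#'
#' For each site, the observed metric on its membership is compared with
#' the same metric on that site's row across `n_null` fixed-margin null
#' matrices: `SES = (obs - mean_null) / sd_null`. Positive values indicate
#' overdispersion, negative values clustering. Sites with fewer than 2
#' species (or a degenerate null spread) are flagged undefined and carry no
#' SES; downstream analyses drop them.
#'
#' @param community community list or binary matrix (all species in
#'   `distances` columns).
#' @param distances labelled species distance matrix (phylogenetic or trait).
#' @param metric `"mpd"` or `"mntd"`.
#' @param n_null number of null draws (999 by default).
#' @param burn_in,thin swap-chain schedule, see [independent_swap()].
#' @param seed optional integer seed.
#' @param basis label recorded in the output (e.g. `"phylogeny"`,
#'   `"trait:HL"`).
#' @return tibble with one row per site: `site`, `metric`, `basis`,
#'   `richness`, `obs`, `null_mean`, `null_sd`, `ses`, `rank` (rank of obs
#'   among obs + null draws), `n_null`, `undefined_flag`.
#' @export
ses_dispersion <- function(community, distances, metric = c("mpd", "mntd"),
                           n_null = 999, burn_in = 10000, thin = 1000,
                           seed = NULL, basis = "phylogeny") {
  metric <- match.arg(metric)
  occ <- if (is.list(community)) community$occupancy else community
  missing_sp <- setdiff(colnames(occ), rownames(distances))
  if (length(missing_sp)) {
    stop("distance matrix lacks species: ", paste(missing_sp, collapse = ", "))
  }
  d <- distances[colnames(occ), colnames(occ)]
  storage.mode(occ) <- "integer"
  rows_fun <- if (metric == "mpd") mpd_rows_cpp else mntd_rows_cpp
  obs <- rows_fun(occ, d)
  draws <- independent_swap(occ, n_draws = n_null, burn_in = burn_in,
                            thin = thin, seed = seed)
  nulls <- vapply(draws, rows_fun, numeric(nrow(occ)), d = d)
  if (nrow(occ) == 1) nulls <- matrix(nulls, nrow = 1)
  null_mean <- rowMeans(nulls)
  null_sd <- apply(nulls, 1, sd)
  undefined <- is.na(obs) | is.na(null_sd) | null_sd == 0
  ses <- ifelse(undefined, NA_real_, (obs - null_mean) / null_sd)
  rank_obs <- vapply(seq_len(nrow(occ)), function(i) {
    if (undefined[i]) return(NA_real_)
    sum(nulls[i, ] < obs[i]) + 1
  }, numeric(1))
  tibble::tibble(
    site = rownames(occ), metric = toupper(metric), basis = basis,
    richness = as.integer(rowSums(occ)), obs = obs,
    null_mean = ifelse(is.na(obs), NA_real_, null_mean),
    null_sd = ifelse(is.na(obs), NA_real_, null_sd),
    ses = ses, rank = rank_obs, n_null = as.integer(n_null),
    undefined_flag = undefined
  )
}

#' SES dispersion for several bases at once
#'
#' Convenience wrapper running [ses_dispersion()] for both metrics over the
#' phylogenetic basis and each requested trait basis, reusing one set of
#' community margins. Seeds derive from `seed` via [split_seed()] so every
#' (basis, metric) combination gets its own reproducible null stream.
#'
#' @param community community list.
#' @param tree phylogeny or `NULL` to skip the phylogenetic basis.
#' @param traits trait tibble.
#' @param trait_kind named kind vector (see [trait_distance()]).
#' @param bases character vector of trait selections (names or `"all"`).
#' @param phylo_species species usable on the tree (defaults to tips).
#' @inheritParams ses_dispersion
#' @return row-bound SES tibble across bases and metrics.
#' @export
ses_all_bases <- function(community, tree, traits, trait_kind = NULL,
                          bases = c(setdiff(names(traits), "species"), "all"),
                          phylo_species = NULL, n_null = 999,
                          burn_in = 10000, thin = 1000, seed = 1L) {
  out <- list()
  ctr <- 0L
  for (metric in c("mpd", "mntd")) {
    if (!is.null(tree)) {
      sp <- phylo_species %||% tree$tip.label
      occ <- community$occupancy[, intersect(colnames(community$occupancy), sp),
                                 drop = FALSE]
      out[[length(out) + 1]] <- ses_dispersion(
        occ, cophenetic_distance(tree), metric, n_null, burn_in, thin,
        seed = split_seed(seed, ctr), basis = "phylogeny")
      ctr <- ctr + 1L
    }
    for (b in bases) {
      d <- trait_distance(traits, b, trait_kind)
      out[[length(out) + 1]] <- ses_dispersion(
        community, d, metric, n_null, burn_in, thin,
        seed = split_seed(seed, ctr),
        basis = if (identical(b, "all")) "trait:all" else paste0("trait:", b))
      ctr <- ctr + 1L
    }
  }
  dplyr::bind_rows(out)
}
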