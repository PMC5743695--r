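#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the sampling design of a montane small-mammal survey: a ~45-species pool
#' on a pure-birth phylogeny, 15 elevational transects of 5 sites spanning
#' 1000-4000 m, two continuous traits and one binary trait (prevalence 0.3),
#' and eight elevation-correlated environmental covariates.
#'
#' @param n_species number of species in the pool.
#' @param birth_rate per-lineage speciation rate of the pure-birth tree.
#' @param bm_rate Brownian variance per unit branch length (sigma^2).
#' @param noise_sd white noise, as the standard deviation added to tip
#'   trait values and, proportionally, to each environmental covariate
#'   (fraction of the covariate's elevational range). 0.1 by default —
#'   measurement error is present but does not swamp the gradient.
#' @param n_transects,sites_per_transect sampling design.
#' @param elevation_range numeric length-2, metres.
#' @param assembly_mode `"filtering"`, `"limiting_similarity"` or `"neutral"`.
#' @param filter_strength half-width (m) of each species' elevational
#'   tolerance window under filtering assembly. `NULL` (default) resolves
#'   by mode: 750 m under `"filtering"`; the full elevational span under
#'   `"limiting_similarity"`, so that each mode isolates a single
#'   structuring process (abiotic filtering vs. biotic exclusion).
#' @param spacing minimum pairwise distance (filter-trait units) enforced
#'   within sites under limiting-similarity assembly; `NULL` = one tenth of
#'   the pool's trait range.
#' @param prevalence fraction of 1s for the binary trait.
#' @param seed master integer seed; per-stage seeds derive via [split_seed()].
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_species = 45, birth_rate = 1, bm_rate = 1,
                       noise_sd = 0.1, n_transects = 15, sites_per_transect = 5,
                       elevation_range = c(1000, 4000),
                       assembly_mode = c("filtering", "limiting_similarity", "neutral"),
                       filter_strength = NULL, spacing = NULL,
                       prevalence = 0.3, seed = 1L) {
  assembly_mode <- match.arg(assembly_mode)
  if (is.null(filter_strength)) {
    filter_strength <- if (assembly_mode == "limiting_similarity")
      diff(range(elevation_range)) else 750
  }
  stopifnot(n_species >= 2, birth_rate > 0, bm_rate > 0, noise_sd >= 0,
            n_transects >= 1, sites_per_transect >= 1,
            length(elevation_range) == 2,
            elevation_range[1] < elevation_range[2],
            filter_strength > 0, prevalence > 0, prevalence < 1)
  structure(list(n_species = as.integer(n_species), birth_rate = birth_rate,
                 bm_rate = bm_rate, noise_sd = noise_sd,
                 n_transects = as.integer(n_transects),
                 sites_per_transect = as.integer(sites_per_transect),
                 elevation_range = as.numeric(elevation_range),
                 assembly_mode = assembly_mode,
                 filter_strength = filter_strength, spacing = spacing,
                 prevalence = prevalence, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Grows a tree under a constant per-lineage speciation rate until it has
#' `n_species` tips; the final waiting period (while `n_species` lineages
#' are extant) is included, so the expected root-to-tip depth is
#' `sum(1/(k * birth_rate))` over `k = 2..n_species`. Tips are labelled
#' `sp001`, `sp002`, ...
#'
#' @param n_species number of tips (>= 2).
#' @param birth_rate per-lineage speciation rate.
#' @param seed optional integer seed.
#' @return an [ape::phylo] object.
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = NULL) {
  stopifnot(n_species >= 2, birth_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_species)
  # lineage bookkeeping: each active lineage hangs from `parent` since `start`
  root <- n + 1L
  next_node <- n + 2L
  parent <- c(root, root)
  start <- c(0, 0)
  edges <- matrix(integer(0), ncol = 2)
  lens <- numeric(0)
  t_now <- 0
  k <- 2L
  while (k < n) {
    t_now <- t_now + rexp(1, rate = k * birth_rate)
    i <- sample.int(k, 1)
    edges <- rbind(edges, c(parent[i], next_node))
    lens <- c(lens, t_now - start[i])
    parent <- c(parent[-i], next_node, next_node)
    start <- c(start[-i], t_now, t_now)
    next_node <- next_node + 1L
    k <- k + 1L
  }
  t_now <- t_now + rexp(1, rate = n * birth_rate)
  tip_ids <- seq_len(n)
  edges <- rbind(edges, cbind(parent, tip_ids))
  lens <- c(lens, t_now - start)
  tree <- list(edge = unname(as.matrix(edges)),
               edge.length = unname(lens),
               tip.label = sprintf("sp%03d", tip_ids),
               Nnode = n - 1L)
  storage.mode(tree$edge) <- "integer"
  class(tree) <- "phylo"
  ape::reorder.phylo(tree, "cladewise")
}

# preorder edge propagation of Brownian motion; returns (tips+nodes) x n matrix
bm_node_values <- function(tree, sigma2, n = 1) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  ord <- rev(seq_len(nrow(po$edge)))  # preorder: parents before children
  val <- matrix(0, n_node, n)
  for (e in ord) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    bl <- po$edge.length[e]
    val[ch, ] <- val[p, ] + rnorm(n, sd = sqrt(sigma2 * bl))
  }
  val
}

#' Simulate continuous traits under Brownian motion
#'
#' Evolves a trait from a root value of 0 along every branch with
#' independent normal increments of variance `sigma2 * branch length`,
#' optionally adding white noise at the tips. With `n > 1` the replicates
#' share the tree but draw independent increments.
#'
#' @param tree an [ape::phylo] object.
#' @param sigma2 Brownian rate (variance per unit branch length), > 0.
#' @param noise_sd white-noise standard deviation added per tip.
#' @param seed optional integer seed.
#' @param n number of independent replicate traits.
#' @return named numeric vector of tip values (or a tips x `n` matrix).
#' @export
simulate_bm_trait <- function(tree, sigma2 = 1, noise_sd = 0, seed = NULL, n = 1) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (!is.null(seed)) set.seed(seed)
  n_tip <- length(tree$tip.label)
  val <- bm_node_values(tree, sigma2, n)[seq_len(n_tip), , drop = FALSE]
  if (noise_sd > 0) val <- val + matrix(rnorm(n_tip * n, sd = noise_sd), n_tip, n)
  rownames(val) <- tree$tip.label
  if (n == 1) setNames(val[, 1], tree$tip.label) else val
}

#' Simulate a binary trait on a phylogeny
#'
#' `mode = "random"` scatters state 1 over a uniformly chosen subset of
#' `round(prevalence * n)` tips (no phylogenetic signal); `mode = "clumped"`
#' simulates a Brownian trait and assigns state 1 to the top
#' `round(prevalence * n)` tips — the threshold model that concentrates 1s
#' within clades.
#'
#' @param tree an [ape::phylo] object.
#' @param mode `"random"` or `"clumped"`.
#' @param prevalence target fraction of 1s, in (0, 1).
#' @param seed optional integer seed.
#' @return named 0/1 vector over tips, both states present.
#' @export
simulate_binary_trait <- function(tree, mode = c("random", "clumped"),
                                  prevalence = 0.3, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(prevalence > 0, prevalence < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  k <- round(prevalence * n)
  if (k < 1 || k > n - 1) {
    stop("prevalence ", prevalence, " leaves no tips in one state for n = ", n)
  }
  x <- setNames(integer(n), tree$tip.label)
  if (mode == "random") {
    x[sample.int(n, k)] <- 1L
  } else {
    z <- simulate_bm_trait(tree, sigma2 = 1)
    x[order(z, decreasing = TRUE)[seq_len(k)]] <- 1L
  }
  x
}

#' Simulate an elevationally structured landscape
#'
#' Places `n_transects` transects (each a short line of sites) across a
#' mountain-block region, with elevations evenly spanning
#' `elevation_range` within each transect and eight environmental
#' covariates generated as linear functions of elevation plus independent
#' normal noise. Temperature- and productivity-like variables (AMT, AP,
#' NPP, NDVI, AET, PET) decrease with elevation; seasonality-like variables
#' (TS, PS) increase.
#'
#' @param config a [sim_config()].
#' @return a site tibble with `site`, `transect`, `elevation`, `lat`,
#'   `lon` and the eight covariates.
#' @export
simulate_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(split_seed(config$seed, 1))
  nt <- config$n_transects; ns <- config$sites_per_transect
  er <- config$elevation_range
  # transect origins scattered over a Hengduan-like block (~22-35N, 98-105E)
  t_lat <- runif(nt, 22, 35)
  t_lon <- runif(nt, 98, 105)
  site <- sprintf("s%03d", seq_len(nt * ns))
  transect <- rep(sprintf("t%02d", seq_len(nt)), each = ns)
  elevation <- as.vector(vapply(seq_len(nt), function(i) seq(er[1], er[2], length.out = ns),
                                numeric(ns)))
  # sites climb the slope: small coordinate steps along the transect line
  lat <- rep(t_lat, each = ns) + rep(seq(0, 0.05, length.out = ns), nt)
  lon <- rep(t_lon, each = ns) + rep(seq(0, 0.05, length.out = ns), nt)
  z <- (elevation - mean(er)) / diff(er)  # centred, unit-range elevation
  nz <- config$noise_sd
  covar <- function(base, slope_sign, scale) {
    base + slope_sign * scale * z + rnorm(length(z), sd = nz * scale)
  }
  tibble::tibble(
    site = site, transect = transect, elevation = elevation,
    lat = lat, lon = lon,
    AMT = covar(12, -1, 15),    # annual mean temperature, degC
    TS = covar(600, +1, 200),   # temperature seasonality
    AP = covar(900, -1, 400),   # annual precipitation, mm
    PS = covar(60, +1, 20),     # precipitation seasonality
    NPP = covar(0.6, -1, 0.4),  # net primary productivity
    NDVI = covar(0.5, -1, 0.3),
    AET = covar(700, -1, 300),  # actual evapotranspiration, mm
    PET = covar(1000, -1, 350)  # potential evapotranspiration, mm
  )
}

#' Assemble communities on a landscape
#'
#' Builds a sites x species presence/absence matrix from one continuous
#' "filter trait" under one of three processes:
#' \describe{
#'   \item{filtering}{each species gets an elevational optimum by linearly
#'     rescaling its filter-trait value onto the elevation range, and
#'     occupies exactly the sites within `filter_strength` metres of that
#'     optimum — a contiguous elevational band, so occupied ranges satisfy
#'     the interpolation assumption by construction.}
#'   \item{limiting_similarity}{starts from the filtering memberships
#'     (an unrestricted window by default, so competition is the only
#'     structuring process), then per site repeatedly deletes one member —
#'     chosen at random — of the closest trait pair until all pairwise
#'     filter-trait distances exceed `spacing`; the random removal keeps
#'     retained sets heterogeneous across sites.}
#'   \item{neutral}{each species occupies an independently drawn contiguous
#'     elevational band in each transect, unrelated to its traits.}
#' }
#'
#' @param tree an [ape::phylo] (labels define the species pool).
#' @param traits named numeric vector: the continuous filter trait per species.
#' @param sitetable site tibble from [simulate_landscape()] (needs `site`,
#'   `transect`, `elevation`).
#' @param config a [sim_config()].
#' @return community list (`occupancy` integer matrix, `transect_of`).
#' @export
assemble_communities <- function(tree, traits, sitetable, config) {
  stopifnot(inherits(config, "sim_config"))
  species <- tree$tip.label
  stopifnot(all(species %in% names(traits)))
  x <- traits[species]
  set.seed(split_seed(config$seed, 4))
  er <- config$elevation_range
  elev <- sitetable$elevation
  n_site <- nrow(sitetable)
  occ <- matrix(0L, n_site, length(species),
                dimnames = list(sitetable$site, species))

  if (config$assembly_mode %in% c("filtering", "limiting_similarity")) {
    rng <- range(x)
    opt <- if (rng[1] == rng[2]) rep(mean(er), length(x)) else
      er[1] + (x - rng[1]) / diff(rng) * diff(er)
    for (j in seq_along(species)) {
      occ[abs(elev - opt[j]) < config$filter_strength, j] <- 1L
    }
    if (config$assembly_mode == "limiting_similarity") {
      spacing <- config$spacing %||% (diff(range(x)) / 10)
      for (i in seq_len(n_site)) {
        present <- which(occ[i, ] == 1L)
        while (length(present) >= 2) {
          xv <- x[present]
          dm <- abs(outer(xv, xv, "-"))
          diag(dm) <- Inf
          mn <- min(dm)
          if (mn >= spacing) break
          pair <- which(dm == mn, arr.ind = TRUE)[1, ]
          drop_i <- pair[sample.int(2, 1)]
          occ[i, present[drop_i]] <- 0L
          present <- present[-drop_i]
        }
      }
    }
  } else {  # neutral: random contiguous band per species per transect
    for (tr in unique(sitetable$transect)) {
      rows <- which(sitetable$transect == tr)
      ord <- rows[order(elev[rows])]
      m <- length(ord)
      for (j in seq_along(species)) {
        b <- sort(sample.int(m, 2, replace = TRUE))
        occ[ord[b[1]:b[2]], j] <- 1L
      }
    }
  }
  empty <- rownames(occ)[rowSums(occ) == 0]
  if (length(empty)) {
    warning("sites with zero richness retained: ", paste(empty, collapse = ", "))
  }
  list(occupancy = occ,
       transect_of = setNames(as.character(sitetable$transect), sitetable$site))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a full synthetic dataset
#'
#' One call producing every object downstream stages consume: tree, traits
#' (two Brownian continuous traits `HL`-like and `TR`-like plus one binary
#' trait `ACD`-like), landscape, and an assembled community. All randomness
#' derives from `config$seed` through [split_seed()] (counters: 0 tree,
#' 1 landscape, 2 continuous traits, 3 binary trait, 4 assembly).
#'
#' @param config a [sim_config()].
#' @param binary_mode mode passed to [simulate_binary_trait()].
#' @return list: `tree`, `traits` (tibble), `trait_kind`, `sites`,
#'   `community`, `config`.
#' @export
simulate_dataset <- function(config = sim_config(), binary_mode = "clumped") {
  tree <- simulate_tree(config$n_species, config$birth_rate,
                        seed = split_seed(config$seed, 0))
  sites <- simulate_landscape(config)
  cont <- simulate_bm_trait(tree, config$bm_rate, config$noise_sd,
                            seed = split_seed(config$seed, 2), n = 2)
  bin <- simulate_binary_trait(tree, binary_mode, config$prevalence,
                               seed = split_seed(config$seed, 3))
  traits <- tibble::tibble(species = tree$tip.label,
                           HL = cont[, 1], TR = cont[, 2],
                           ACD = as.numeric(bin[tree$tip.label]))
  community <- assemble_communities(tree, setNames(traits$HL, traits$species),
                                    sites, config)
  list(tree = tree, traits = traits,
       trait_kind = c(HL = "continuous", TR = "continuous", ACD = "binary"),
       sites = sites, community = community, config = config)
}
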