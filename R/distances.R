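#' Cophenetic (patristic) distance matrix of a phylogeny
#'
#' Entry (i, j) is the sum of branch lengths on the tree path between tips
#' i and j, computed with [ape::cophenetic.phylo()].
#'
#' @param tree an [ape::phylo] object.
#' @return labelled symmetric distance matrix.
#' @export
cophenetic_distance <- function(tree) {
  d <- ape::cophenetic.phylo(validate_phylogeny(tree))
  validate_distance_matrix(d)
  d
}

#' Trait distance matrix among species
#'
#' For a single continuous trait, the distance is the absolute difference
#' after standardizing the trait to zero mean and unit variance over the
#' species pool; for a single binary trait, the 0/1 mismatch; for
#' `selection = "all"`, the Gower distance — per-trait components are the
#' range-normalized absolute difference (continuous) or the mismatch
#' (binary), averaged over traits.
#'
#' @param traits trait tibble with a `species` column.
#' @param selection one trait name, or `"all"`.
#' @param trait_kind named character vector flagging each trait
#'   `"continuous"` or `"binary"` (inferred from \{0,1\} values if `NULL`).
#' @return labelled symmetric distance matrix over species.
#' @export
trait_distance <- function(traits, selection, trait_kind = NULL) {
  tr_names <- setdiff(names(traits), "species")
  if (is.null(trait_kind)) {
    trait_kind <- vapply(tr_names, function(tr)
      if (all(traits[[tr]] %in% c(0, 1))) "binary" else "continuous", character(1))
  }
  sp <- traits$species
  one_component <- function(tr, normalize) {
    x <- traits[[tr]]
    if (trait_kind[[tr]] == "binary") {
      return(abs(outer(x, x, "-")))
    }
    if (normalize == "sd") {
      s <- sd(x)
      if (s == 0) stop("zero-variance continuous trait: ", tr)
      x <- (x - mean(x)) / s
      abs(outer(x, x, "-"))
    } else {
      r <- diff(range(x))
      if (r == 0) stop("zero-range continuous trait: ", tr)
      abs(outer(x, x, "-")) / r
    }
  }
  if (identical(selection, "all")) {
    comps <- lapply(tr_names, one_component, normalize = "range")
    d <- Reduce(`+`, comps) / length(comps)
  } else {
    if (!selection %in% tr_names) stop("unknown trait: ", selection)
    d <- one_component(selection, normalize = "sd")
  }
  dimnames(d) <- list(sp, sp)
  diag(d) <- 0
  validate_distance_matrix(d)
  d
}

#' Combined horizontal + vertical geographic distance
#'
#' In steep terrain two sites can be near-neighbours on the map yet far
#' apart ecologically; the spatial distance therefore adds the great-circle
#' (haversine, sphere radius 6,371,000 m) horizontal distance and the
#' absolute elevation difference, both in metres.
#'
#' @param sitetable site tibble with `site`, `lat`, `lon`, `elevation`.
#' @return labelled symmetric distance matrix over sites, metres.
#' @export
geo_distance <- function(sitetable) {
  validate_sites(sitetable)
  pts <- cbind(sitetable$lon, sitetable$lat)
  n <- nrow(pts)
  h <- matrix(0, n, n)
  for (i in seq_len(n)) {
    h[i, ] <- geosphere::distHaversine(pts[i, , drop = FALSE], pts, r = 6371000)
  }
  h <- (h + t(h)) / 2  # symmetrize away floating-point asymmetry
  v <- abs(outer(sitetable$elevation, sitetable$elevation, "-"))
  d <- h + v
  diag(d) <- 0
  dimnames(d) <- list(sitetable$site, sitetable$site)
  validate_distance_matrix(d)
  d
}
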