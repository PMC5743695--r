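#' Binarize an abundance community matrix
#'
#' Survey data pooled across sources carry incomparable abundances; the
#' analyses therefore work on presence/absence. Any positive count becomes
#' a 1. Idempotent on already-binary input.
#'
#' @param community community list (`occupancy`, `transect_of`).
#' @return the community with a 0/1 occupancy matrix.
#' @export
binarize <- function(community) {
  occ <- community$occupancy
  if (any(occ < 0)) stop("negative counts in community matrix")
  occ[] <- as.integer(occ > 0)
  community$occupancy <- occ
  community
}

#' Interpolate elevational ranges within transects
#'
#' Within each transect independently, a species recorded at two
#' elevations is assumed present at every sampled site whose elevation lies
#' strictly between its lowest and highest occupied elevations there
#' (occurrences are never removed). Sites at elevations exactly equal to a
#' range endpoint count as the endpoint itself, not as interior. The result
#' is idempotent and, per transect and species, the occupied elevations form
#' an interval of that transect's sampled elevations.
#'
#' @param community *binary* community list.
#' @param sitetable site tibble with `site` and `elevation`.
#' @return the community with interpolated occupancy.
#' @export
interpolate_ranges <- function(community, sitetable) {
  occ <- community$occupancy
  if (!all(occ %in% c(0L, 1L))) stop("interpolate_ranges needs a binary matrix; run binarize() first")
  elev <- setNames(sitetable$elevation, sitetable$site)
  miss <- setdiff(rownames(occ), names(elev))
  if (length(miss)) stop("sites missing elevation: ", paste(miss, collapse = ", "))
  e <- elev[rownames(occ)]
  for (tr in unique(community$transect_of)) {
    rows <- which(community$transect_of[rownames(occ)] == tr)
    if (length(rows) < 3) next
    sub <- occ[rows, , drop = FALSE]
    esub <- e[rows]
    for (j in which(colSums(sub) >= 2)) {
      occ_e <- esub[sub[, j] == 1L]
      fill <- esub > min(occ_e) & esub < max(occ_e)
      occ[rows[fill], j] <- 1L
    }
  }
  community$occupancy <- occ
  community
}
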