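#' Principal coordinates of neighbour matrices (spatial eigenvectors)
#'
#' Canonical PCNM recipe: the truncation threshold `t` is the longest edge
#' of a minimum spanning tree of the complete distance graph (so the
#' neighbourhood graph stays connected); distances above `t` are replaced
#' by `4t`; `-d*^2 / 2` is Gower double-centred and eigendecomposed; axes
#' with eigenvalue above `max(eigenvalue) * 1e-9` are kept, scaled by the
#' square root of their eigenvalue. Columns are centred, mutually
#' orthogonal, and deterministic: each column's sign is fixed by forcing
#' its largest-magnitude entry positive.
#'
#' @param distances labelled site distance matrix (e.g. [geo_distance()]),
#'   n >= 3.
#' @param truncation optional threshold in distance units; defaults to the
#'   MST maximum edge.
#' @return object of class `pcnm_basis`: list with `site` (labels),
#'   `values` (positive eigenvalues, descending), `vectors` (site x axis
#'   matrix, columns `PCNM1`, `PCNM2`, ...), `truncation`.
#' @export
pcnm <- function(distances, truncation = NULL) {
  validate_distance_matrix(distances)
  n <- nrow(distances)
  if (n < 3) stop("PCNM needs at least 3 sites")
  if (is.null(truncation)) {
    mst <- vegan::spantree(stats::as.dist(distances))
    truncation <- max(mst$dist)
  }
  dstar <- distances
  dstar[dstar > truncation] <- 4 * truncation
  diag(dstar) <- 0
  a <- -0.5 * dstar^2
  # Gower double-centring
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  g <- (g + t(g)) / 2
  eig <- eigen(g, symmetric = TRUE)
  tol <- max(eig$values) * 1e-9
  keep <- which(eig$values > tol)
  if (!length(keep)) {
    warning("no positive eigenvalues; empty PCNM basis")
    vectors <- matrix(numeric(0), n, 0, dimnames = list(rownames(distances), NULL))
    return(structure(list(site = rownames(distances), values = numeric(0),
                          vectors = vectors, truncation = truncation),
                     class = "pcnm_basis"))
  }
  values <- eig$values[keep]
  vectors <- eig$vectors[, keep, drop = FALSE] %*% diag(sqrt(values), length(keep))
  # deterministic sign: largest-|entry| positive
  for (j in seq_len(ncol(vectors))) {
    i <- which.max(abs(vectors[, j]))
    if (vectors[i, j] < 0) vectors[, j] <- -vectors[, j]
  }
  dimnames(vectors) <- list(rownames(distances),
                            paste0("PCNM", seq_along(values)))
  structure(list(site = rownames(distances), values = values,
                 vectors = vectors, truncation = truncation),
            class = "pcnm_basis")
}

#' @export
print.pcnm_basis <- function(x, ...) {
  cat("PCNM basis:", length(x$values), "positive axes over", length(x$site),
      "sites (truncation =", format(x$truncation, digits = 6), ")\n")
  invisible(x)
}

#' Spatial eigenvectors as a tibble
#'
#' @param x a `pcnm_basis`.
#' @param ... unused.
#' @return tibble with `site` and one column per PCNM axis.
#' @export
tidy.pcnm_basis <- function(x, ...) {
  tibble::as_tibble(x$vectors, rownames = "site")
}
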