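#' Read a phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the contracts the
#' rest of the package relies on: at least two uniquely labelled tips,
#' branch lengths present and nonnegative. Labels are trimmed of
#' surrounding whitespace and matched case-sensitively everywhere.
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("Newick file not found: ", path)
  tree <- tryCatch(
    ape::read.tree(path),
    error = function(e) stop("malformed Newick in ", path, ": ", conditionMessage(e))
  )
  if (is.null(tree)) stop("malformed Newick in ", path)
  validate_phylogeny(tree)
}

#' Write a phylogeny to a Newick file
#'
#' Branch lengths are rendered with 15 significant digits so that a
#' write-then-read round trip preserves cophenetic distances to numerical
#' precision.
#'
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(validate_phylogeny(tree), file = path, digits = 15)
  invisible(path)
}

#' Validate a phylogeny object
#'
#' @param tree an [ape::phylo] object.
#' @return the tree, with trimmed tip labels, after validation.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  tree$tip.label <- trimws(tree$tip.label)
  if (length(tree$tip.label) < 2) stop("tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) stop("tree has missing branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths are not allowed")
  tree
}

read_id_csv <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) stop(what, " table is empty: ", path)
  ids <- trimws(as.character(df[[1]]))
  if (anyDuplicated(ids)) {
    stop("duplicate ids in ", what, " table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  df[[1]] <- ids
  df
}

#' Read the community, trait and site tables
#'
#' All three tables are comma-separated UTF-8 text with a header row whose
#' first column holds the id (site or species). The community table must
#' additionally carry a `transect` column mapping each site to its
#' elevational transect; the site table must carry `elevation`, `lat`,
#' `lon` and the environmental covariates. Trait columns whose values are
#' all in \{0, 1\} are flagged binary unless overridden via `binary_traits`.
#'
#' @param community_path CSV of sites x species occurrences (counts or 0/1)
#'   plus a `transect` column.
#' @param trait_path CSV of species x traits.
#' @param site_path CSV of sites with `elevation`, `lat`, `lon` and
#'   environmental covariates.
#' @param binary_traits optional character vector naming the binary traits,
#'   overriding the \{0,1\}-valued inference.
#' @return a list with elements `community` (list: `occupancy` integer
#'   matrix, `transect_of` named character vector), `traits` (tibble with a
#'   `species` column), `trait_kind` (named character vector,
#'   `"continuous"` or `"binary"`), and `sites` (tibble).
#' @export
read_tables <- function(community_path, trait_path, site_path,
                        binary_traits = NULL) {
  comm_df <- read_id_csv(community_path, "community")
  if (!"transect" %in% names(comm_df)) {
    stop("community table must have a 'transect' column")
  }
  sp_cols <- setdiff(names(comm_df)[-1], "transect")
  occ <- as.matrix(comm_df[sp_cols])
  if (!is.numeric(occ)) stop("non-numeric occurrence values in community table")
  if (anyNA(occ)) stop("missing occurrence values in community table")
  rownames(occ) <- comm_df[[1]]
  colnames(occ) <- trimws(sp_cols)
  community <- list(
    occupancy = as_comm_matrix(occ),
    transect_of = setNames(as.character(comm_df$transect), comm_df[[1]])
  )

  traits <- read_id_csv(trait_path, "trait")
  names(traits)[1] <- "species"
  tr_names <- setdiff(names(traits), "species")
  for (tr in tr_names) {
    if (!is.numeric(traits[[tr]])) stop("non-numeric trait column: ", tr)
    if (anyNA(traits[[tr]]) || any(!is.finite(traits[[tr]]))) {
      stop("non-finite values in trait column: ", tr)
    }
  }
  trait_kind <- vapply(tr_names, function(tr) {
    if (all(traits[[tr]] %in% c(0, 1))) "binary" else "continuous"
  }, character(1))
  if (!is.null(binary_traits)) {
    bad <- setdiff(binary_traits, tr_names)
    if (length(bad)) stop("unknown binary_traits: ", paste(bad, collapse = ", "))
    trait_kind[] <- "continuous"
    trait_kind[binary_traits] <- "binary"
    for (tr in binary_traits) {
      if (!all(traits[[tr]] %in% c(0, 1))) {
        stop("trait declared binary has values outside {0,1}: ", tr)
      }
    }
  }

  sites <- read_id_csv(site_path, "site")
  names(sites)[1] <- "site"
  validate_sites(sites)

  missing_sites <- setdiff(rownames(community$occupancy), sites$site)
  if (length(missing_sites)) {
    stop("sites missing from site table: ", paste(missing_sites, collapse = ", "))
  }
  no_transect <- rownames(community$occupancy)[
    is.na(community$transect_of) | community$transect_of == ""
  ]
  if (length(no_transect)) {
    stop("sites without transect assignment: ", paste(no_transect, collapse = ", "))
  }
  list(community = community, traits = tibble::as_tibble(traits),
       trait_kind = trait_kind, sites = sites)
}

validate_sites <- function(sites) {
  need <- c("site", "elevation", "lat", "lon")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("site table lacks columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(sites$elevation))) stop("non-finite elevations in site table")
  if (any(abs(sites$lat) > 90)) stop("latitude out of range [-90, 90]")
  if (any(abs(sites$lon) > 180)) stop("longitude out of range [-180, 180]")
  env_cols <- setdiff(names(sites), c(need, "transect"))
  for (v in env_cols) {
    if (!is.numeric(sites[[v]])) stop("non-numeric site covariate: ", v)
  }
  invisible(sites)
}

#' Write the community matrix (plus transect column) to CSV
#'
#' Numeric cells are rendered with full precision (15+ significant digits)
#' so a read-write-read round trip is value-exact.
#'
#' @param community community list as returned by [read_tables()].
#' @param path output path.
#' @export
write_community_csv <- function(community, path) {
  df <- tibble::as_tibble(community$occupancy, rownames = "site")
  df <- dplyr::mutate(df,
                      transect = unname(community$transect_of[.data$site]),
                      .after = "site")
  readr::write_csv(df, path)
  invisible(path)
}

#' Reconcile species and site names across community, traits, tree and sites
#'
#' Species occur in four places (community matrix columns, trait table rows,
#' tree tips) and sites in two (community rows, site table); field datasets
#' rarely agree exactly — e.g. a species may lack a tree placement because no
#' sequence data exist. Under `policy = "drop_with_warning"` such species are
#' removed from the *tree-based* objects only: they stay in the community and
#' trait tables so trait-only analyses keep them, mirroring standard
#' practice. Tree tips absent from the community are pruned from the working
#' copy of the tree (pruning never changes cophenetic distances among the
#' remaining tips). Under `policy = "error"` any mismatch aborts.
#'
#' @param community community list (see [read_tables()]).
#' @param traits trait tibble with a `species` column.
#' @param tree an [ape::phylo] object.
#' @param sites site tibble.
#' @param policy `"drop_with_warning"` (default) or `"error"`.
#' @return a list: `community`, `traits`, `sites` (possibly reordered),
#'   `tree` (pruned copy), `phylo_species` (species usable in tree-based
#'   analyses), and `report`, a tibble of every dropped/retained name with
#'   its reason. Applying the function twice equals applying it once.
#' @export
concordance_check <- function(community, traits, tree, sites,
                              policy = c("drop_with_warning", "error")) {
  policy <- match.arg(policy)
  comm_sp <- colnames(community$occupancy)
  trait_sp <- traits$species
  tip_sp <- tree$tip.label
  comm_sites <- rownames(community$occupancy)

  report <- list()
  note <- function(name, kind, action, where) {
    report[[length(report) + 1]] <<- tibble::tibble(
      name = name, kind = kind, action = action, context = where)
  }

  no_traits <- setdiff(comm_sp, trait_sp)
  if (length(no_traits)) {
    stop("community species missing from trait table: ",
         paste(no_traits, collapse = ", "))
  }

  not_in_tree <- setdiff(comm_sp, tip_sp)
  if (length(not_in_tree)) {
    if (policy == "error") {
      stop("species absent from tree: ", paste(not_in_tree, collapse = ", "))
    }
    for (sp in not_in_tree) {
      note(sp, "species", "retained_traits_only", "absent from tree")
    }
    warning("species absent from tree, excluded from phylogenetic analyses: ",
            paste(not_in_tree, collapse = ", "))
  }
  extra_tips <- setdiff(tip_sp, comm_sp)
  if (length(extra_tips)) {
    if (policy == "error") {
      stop("tree tips absent from community: ", paste(extra_tips, collapse = ", "))
    }
    for (sp in extra_tips) note(sp, "species", "pruned_from_tree", "absent from community")
    tree <- ape::drop.tip(tree, extra_tips)
  }

  missing_sites <- setdiff(comm_sites, sites$site)
  if (length(missing_sites)) {
    stop("community sites missing from site table: ",
         paste(missing_sites, collapse = ", "))
  }
  sites <- sites[match(comm_sites, sites$site), , drop = FALSE]

  report <- if (length(report)) dplyr::bind_rows(report) else
    tibble::tibble(name = character(), kind = character(),
                   action = character(), context = character())

  list(community = community,
       traits = traits,
       sites = sites,
       tree = tree,
       phylo_species = intersect(comm_sp, tree$tip.label),
       report = report)
}
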