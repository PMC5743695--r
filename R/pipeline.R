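#' Run the full community-structure analysis
#'
#' Orchestrates every stage on one dataset: binarize, range-interpolate,
#' build distance matrices, SES dispersion for the phylogenetic and trait
#' bases (both metrics), phylogenetic-signal statistics, PCNM spatial
#' eigenvectors from the combined horizontal+vertical distance, forward
#' selection of environmental and spatial predictors, three-set variance
#' partitioning (environment / space / phylogeny) of every trait-based SES
#' response, and elevational regressions of SES values. All randomness
#' derives from `seed` through [split_seed()] (counters: 100 SES block,
#' 200 signal block, 300 forward selection, 400 variance partitioning), so
#' reruns with the same inputs are identical.
#'
#' @param data list with `tree`, `community`, `traits`, `trait_kind`,
#'   `sites` — as from [simulate_dataset()] or assembled from
#'   [read_tables()] + a tree. `tree` may be `NULL`: phylogeny-based
#'   outputs are then absent and trait-based outputs unchanged.
#' @param n_null null draws for SES.
#' @param n_perm permutations for signal, selection and partitioning.
#' @param alpha forward-selection entry level.
#' @param seed master integer seed.
#' @param out_dir optional directory; when given, every result table is
#'   written there as CSV along with a run manifest.
#' @param quiet suppress INFO messages (warnings always surface).
#' @return list of tibbles: `ses`, `signal` (NULL without a tree),
#'   `pcnm_axes`, `selection`, `varpart`, `gradient`, plus `community`
#'   (processed) and `report` (concordance report).
#' @export
run_all <- function(data, n_null = 999, n_perm = 999, alpha = 0.05,
                    seed = 1L, out_dir = NULL, quiet = FALSE) {
  t0 <- Sys.time()
  info <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"),
                                            "] INFO ", ...)
  stopifnot(is.list(data), !is.null(data$community), !is.null(data$traits),
            !is.null(data$sites))
  traits <- data$traits
  trait_kind <- data$trait_kind
  tr_names <- setdiff(names(traits), "species")
  if (is.null(trait_kind)) {
    trait_kind <- vapply(tr_names, function(tr)
      if (all(traits[[tr]] %in% c(0, 1))) "binary" else "continuous", character(1))
  }

  info("preparing community (binarize + range interpolation)")
  community <- interpolate_ranges(binarize(data$community), data$sites)

  tree <- data$tree
  report <- NULL
  phylo_species <- NULL
  if (!is.null(tree)) {
    conc <- concordance_check(community, traits, tree, data$sites,
                              policy = "drop_with_warning")
    community <- conc$community
    tree <- conc$tree
    phylo_species <- conc$phylo_species
    report <- conc$report
  }
  sites <- data$sites[match(rownames(community$occupancy), data$sites$site), ,
                      drop = FALSE]

  info("SES dispersion (", n_null, " independent-swap nulls)")
  ses <- ses_all_bases(community, tree, traits, trait_kind,
                       phylo_species = phylo_species, n_null = n_null,
                       seed = split_seed(seed, 100))
  n_undef <- sum(ses$undefined_flag)
  if (n_undef > 0) {
    warning(n_undef, " site-basis combinations have undefined SES ",
            "(richness < 2 or degenerate null)")
  }

  signal <- NULL
  if (!is.null(tree)) {
    info("phylogenetic signal (K / D)")
    signal <- phylo_signal_table(tree, traits, trait_kind, n_perm = n_perm,
                                 seed = split_seed(seed, 200))
  }

  info("PCNM spatial eigenvectors")
  basis <- pcnm(geo_distance(sites))
  pcnm_axes <- tidy.pcnm_basis(basis)

  env_cols <- setdiff(names(sites), c("site", "transect", "elevation", "lat", "lon"))
  env <- as.matrix(sites[env_cols])
  rownames(env) <- sites$site
  spa <- basis$vectors

  trait_bases <- unique(ses$basis[ses$basis != "phylogeny"])
  phylo_wide <- NULL
  if (!is.null(tree)) {
    ph <- dplyr::filter(ses, .data$basis == "phylogeny")
    phylo_wide <- tidyr::pivot_wider(ph[c("site", "metric", "ses")],
                                     names_from = "metric", values_from = "ses")
  }

  info("forward selection and variance partitioning per response")
  selection <- list(); varpart <- list(); gradient <- list()
  ctr <- 0L
  for (b in trait_bases) {
    for (m in c("MPD", "MNTD")) {
      resp_tbl <- dplyr::filter(ses, .data$basis == b, .data$metric == m)
      resp <- setNames(resp_tbl$ses, resp_tbl$site)
      label <- paste0(if (m == "MPD") "SES.PW" else "SES.NN", "[", b, "]")
      keep <- names(resp)[!is.na(resp)]
      if (!is.null(phylo_wide)) {
        ph_ok <- phylo_wide$site[!is.na(phylo_wide$MPD) & !is.na(phylo_wide$MNTD)]
        keep <- intersect(keep, ph_ok)
      }
      if (length(keep) < 10) {
        warning("skipping ", label, ": too few sites with defined SES")
        next
      }
      y <- resp[keep]
      gradient[[length(gradient) + 1]] <-
        regress_on_elevation(y, sites, response_name = label)
      fs_env <- forward_select(y, env[keep, , drop = FALSE], alpha, n_perm,
                               seed = split_seed(seed, 300 + ctr))
      # PCNM axes are ordered broad -> fine; cap candidates so the global
      # model keeps residual degrees of freedom
      n_spa <- min(ncol(spa), length(keep) - 5L)
      fs_spa <- forward_select(y, spa[keep, seq_len(n_spa), drop = FALSE],
                               alpha, n_perm,
                               seed = split_seed(seed, 320 + ctr))
      selection[[length(selection) + 1]] <- dplyr::bind_rows(
        dplyr::mutate(fs_env, response = label, set = "environment", .before = 1),
        dplyr::mutate(fs_spa, response = label, set = "space", .before = 1))
      set_E <- if (nrow(fs_env)) env[keep, fs_env$variable, drop = FALSE] else NULL
      set_S <- if (nrow(fs_spa)) spa[keep, fs_spa$variable, drop = FALSE] else NULL
      set_P <- if (!is.null(phylo_wide)) {
        pm <- as.matrix(phylo_wide[match(keep, phylo_wide$site),
                                   c("MPD", "MNTD")])
        rownames(pm) <- keep
        colnames(pm) <- c("SES.MPD", "SES.MNTD")
        pm
      } else NULL
      vp <- variance_partition3(y, set_E, set_S, set_P, n_perm = n_perm,
                                seed = split_seed(seed, 400 + ctr),
                                response_name = label)
      varpart[[length(varpart) + 1]] <- tidy.varpart3(vp)
      ctr <- ctr + 1L
    }
  }

  res <- list(
    community = community,
    report = report,
    ses = ses,
    signal = signal,
    pcnm_axes = pcnm_axes,
    selection = if (length(selection)) dplyr::bind_rows(selection) else NULL,
    varpart = if (length(varpart)) dplyr::bind_rows(varpart) else NULL,
    gradient = if (length(gradient)) dplyr::bind_rows(gradient) else NULL
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_community_csv(community, file.path(out_dir, "community_interpolated.csv"))
    for (nm in c("ses", "signal", "pcnm_axes", "selection", "varpart", "gradient")) {
      if (!is.null(res[[nm]])) {
        readr::write_csv(res[[nm]], file.path(out_dir, paste0(nm, ".csv")))
      }
    }
    manifest <- c(
      paste0("package_version: ", as.character(utils::packageVersion("elevdisp"))),
      paste0("r_version: ", R.version.string),
      paste0("seed: ", seed),
      paste0("n_null: ", n_null),
      paste0("n_perm: ", n_perm),
      paste0("alpha: ", alpha),
      paste0("n_sites: ", nrow(community$occupancy)),
      paste0("n_species: ", ncol(community$occupancy)),
      paste0("wall_time_s: ",
             round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)))
    writeLines(manifest, file.path(out_dir, "run_manifest.txt"))
  }
  info("done in ",
       round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1), " s")
  res
}
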