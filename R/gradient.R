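#' Simple linear regression of per-site values on elevation
#'
#' Ordinary least squares of a per-site quantity (an SES value, a
#' community-mean trait) on site elevation, with the two-sided F-test
#' p-value. Sites with undefined values are dropped (pairwise deletion).
#'
#' @param values_by_site named numeric vector (names = site ids) or a
#'   two-column data frame `site`, `value`.
#' @param sitetable site tibble with `site` and `elevation`.
#' @param response_name label carried into the result.
#' @return one-row tibble: `response`, `slope`, `intercept`, `r2`, `p`, `n`.
#' @export
regress_on_elevation <- function(values_by_site, sitetable,
                                 response_name = "value") {
  if (is.data.frame(values_by_site)) {
    v <- setNames(values_by_site$value, values_by_site$site)
  } else {
    v <- values_by_site
  }
  if (is.null(names(v))) stop("values must be named by site id")
  elev <- setNames(sitetable$elevation, sitetable$site)
  keep <- names(v)[!is.na(v) & names(v) %in% names(elev)]
  if (length(keep) < 3) stop("need at least 3 sites with defined values")
  x <- elev[keep]; y <- v[keep]
  if (var(x) == 0) stop("zero variance in elevation")
  fit <- lm(y ~ x)
  # degenerate perfect fits (r2 = 1, or constant response) are legal inputs;
  # summary.lm's "essentially perfect fit" warning adds nothing here
  sm <- suppressWarnings(summary(fit))
  p <- if (is.null(sm$fstatistic)) NA_real_ else
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
  tibble::tibble(response = response_name,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = sm$r.squared, p = p, n = length(keep))
}

#' Community-mean trait per site
#'
#' Per site, the unweighted mean of a (possibly transformed) continuous
#' trait over the present species, optionally restricted to a subset (a
#' family's species at the family level, all species at the order level).
#' Sites with no subset member present are excluded from the output.
#'
#' @param community community list.
#' @param traits trait tibble with a `species` column.
#' @param trait name of a continuous trait.
#' @param transform `"identity"` or `"log10"`.
#' @param subset character vector of species to restrict to (`NULL` = all).
#' @return named numeric vector of per-site means.
#' @export
community_mean_trait <- function(community, traits, trait,
                                 transform = c("identity", "log10"),
                                 subset = NULL) {
  transform <- match.arg(transform)
  occ <- community$occupancy
  x <- setNames(traits[[trait]], traits$species)
  sp <- intersect(colnames(occ), names(x))
  if (!is.null(subset)) sp <- intersect(sp, subset)
  if (!length(sp)) stop("no species left after subsetting")
  x <- x[sp]
  if (transform == "log10") {
    if (any(x <= 0)) stop("log10 transform requested on nonpositive trait values")
    x <- log10(x)
  }
  sub <- occ[, sp, drop = FALSE]
  k <- rowSums(sub)
  out <- as.vector(sub %*% x) / k
  out[k == 0] <- NA_real_
  out <- setNames(out, rownames(occ))
  out[!is.na(out)]
}

#' Ecogeographic (Bergmann / Allen) assessment along elevation
#'
#' Regresses community-mean log10 body size and community-mean relative
#' appendage length on elevation, at order level (all species) and for
#' each family holding at least `min_family_fraction` of the species pool
#' (rarer families are skipped, as are families occupying fewer than 3
#' sites). Verdicts read the slopes against Bergmann's rule (larger bodies
#' at higher, cooler elevations: positive size slope expected) and Allen's
#' rule (relatively shorter appendages when cooler: negative appendage
#' slope expected).
#'
#' @param community community list.
#' @param traits trait tibble.
#' @param sitetable site tibble.
#' @param family_map named character vector mapping species to family.
#' @param size_trait continuous trait for body size (log10-transformed).
#' @param appendage_trait continuous trait for relative appendage length.
#' @param min_family_fraction inclusion cutoff as a fraction of the pool
#'   (default 0.20).
#' @param alpha significance level for the verdicts.
#' @return tibble of regressions with `level`, `group`, `trait`, `rule`,
#'   `slope`, `intercept`, `r2`, `p`, `n`, `verdict`.
#' @export
ecogeographic_report <- function(community, traits, sitetable, family_map,
                                 size_trait = "HL", appendage_trait = "TR",
                                 min_family_fraction = 0.20, alpha = 0.05) {
  sp_all <- intersect(colnames(community$occupancy), traits$species)
  miss <- setdiff(sp_all, names(family_map))
  if (length(miss)) stop("family_map lacks species: ", paste(miss, collapse = ", "))
  fams <- table(family_map[sp_all])
  keep_fams <- names(fams)[fams / length(sp_all) >= min_family_fraction]
  groups <- c(list(order = sp_all),
              setNames(lapply(keep_fams, function(f) sp_all[family_map[sp_all] == f]),
                       keep_fams))
  specs <- list(
    list(trait = size_trait, transform = "log10", rule = "Bergmann",
         expected_sign = 1),
    list(trait = appendage_trait, transform = "identity", rule = "Allen",
         expected_sign = -1))
  out <- list()
  for (g in names(groups)) {
    for (spec in specs) {
      v <- tryCatch(
        community_mean_trait(community, traits, spec$trait,
                             transform = spec$transform, subset = groups[[g]]),
        error = function(e) NULL)
      if (is.null(v) || length(v) < 3) {
        warning("skipping ", g, " / ", spec$trait, ": fewer than 3 occupied sites")
        next
      }
      reg <- regress_on_elevation(v, sitetable, response_name = spec$trait)
      verdict <- if (is.na(reg$p) || reg$p > alpha) {
        "no significant pattern"
      } else if (sign(reg$slope) == spec$expected_sign) {
        paste0("consistent with ", spec$rule, "'s rule")
      } else {
        paste0("inconsistent with ", spec$rule, "'s rule")
      }
      out[[length(out) + 1]] <- dplyr::mutate(
        reg,
        level = if (g == "order") "order" else "family",
        group = g, trait = spec$trait, rule = spec$rule, verdict = verdict,
        .before = 1)
    }
  }
  if (!length(out)) {
    return(tibble::tibble(level = character(), group = character(),
                          trait = character(), rule = character(),
                          response = character(), slope = numeric(),
                          intercept = numeric(), r2 = numeric(),
                          p = numeric(), n = integer(), verdict = character()))
  }
  dplyr::bind_rows(out)
}
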