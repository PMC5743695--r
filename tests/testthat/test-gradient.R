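mk_sites <- function(elev) {
  tibble::tibble(site = names(elev), elevation = unname(elev), lat = 0, lon = 0)
}

test_that("elevational regression recovers exact linear relations", {
  elev <- setNames(seq(1000, 3000, length.out = 10), sprintf("s%02d", 1:10))
  v <- 0.002 * elev - 1
  reg <- regress_on_elevation(v, mk_sites(elev), "lin")
  expect_equal(reg$slope, 0.002, tolerance = 1e-10)
  expect_equal(reg$intercept, -1, tolerance = 1e-8)
  expect_equal(reg$r2, 1, tolerance = 1e-10)
  expect_equal(reg$n, 10)
})

test_that("regression matches the normal-equation oracle and ignores NA sites", {
  set.seed(121)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    elev <- setNames(runif(n, 500, 4000), sprintf("s%02d", 1:n))
    v <- rnorm(n, sd = 2)
    ref <- bf_ols(unname(elev), v)
    reg <- regress_on_elevation(setNames(v, names(elev)), mk_sites(elev))
    expect_lt(abs(reg$slope - ref[["slope"]]), 1e-10)
    expect_lt(abs(reg$intercept - ref[["intercept"]]), 1e-8)
  }
  elev <- setNames(c(1, 2, 3, 4), c("a", "b", "c", "d"))
  v <- setNames(c(1, 2, NA, 4), names(elev))
  expect_equal(regress_on_elevation(v, mk_sites(elev))$n, 3)
})

test_that("regression p-values are calibrated under the null", {
  set.seed(123)
  elev <- setNames(runif(40, 0, 1000), sprintf("s%02d", 1:40))
  ps <- replicate(200, regress_on_elevation(
    setNames(rnorm(40), names(elev)), mk_sites(elev))$p)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("regression is invariant to site ordering", {
  set.seed(125)
  elev <- setNames(runif(12, 0, 3000), sprintf("s%02d", 1:12))
  v <- setNames(rnorm(12), names(elev))
  r1 <- regress_on_elevation(v, mk_sites(elev))
  perm <- sample(names(elev))
  r2 <- regress_on_elevation(v[perm], mk_sites(elev[perm]))
  expect_equal(r1$slope, r2$slope, tolerance = 1e-12)
  expect_equal(r1$r2, r2$r2, tolerance = 1e-12)
})

mk_comm2 <- function(mat) list(occupancy = mat,
                               transect_of = setNames(rep("t1", nrow(mat)),
                                                      rownames(mat)))

test_that("community-mean traits average present species on the requested scale", {
  occ <- matrix(c(1L, 0L,
                  1L, 1L,
                  0L, 0L), 3, 2, byrow = TRUE,
                dimnames = list(c("s1", "s2", "s3"), c("a", "b")))
  traits <- tibble::tibble(species = c("a", "b"), HL = c(100, 1000))
  v <- community_mean_trait(mk_comm2(occ), traits, "HL", transform = "log10")
  expect_equal(unname(v["s1"]), 2)
  expect_equal(unname(v["s2"]), mean(c(2, 3)))
  expect_false("s3" %in% names(v))  # empty site excluded
  traits$HL[1] <- -5
  expect_error(community_mean_trait(mk_comm2(occ), traits, "HL", "log10"),
               "nonpositive")
})

test_that("subsetting then averaging equals masking then averaging", {
  set.seed(127)
  occ <- matrix(as.integer(runif(40) < 0.5), 5, 8,
                dimnames = list(sprintf("s%d", 1:5), sprintf("sp%d", 1:8)))
  traits <- tibble::tibble(species = sprintf("sp%d", 1:8), HL = runif(8, 10, 200))
  subset <- sprintf("sp%d", c(1, 3, 5, 7))
  v1 <- community_mean_trait(mk_comm2(occ), traits, "HL", subset = subset)
  occ_masked <- occ[, subset, drop = FALSE]
  v2 <- community_mean_trait(mk_comm2(occ_masked),
                             traits[traits$species %in% subset, ], "HL")
  expect_equal(v1, v2)
})

test_that("ecogeographic report reads slopes against Bergmann's and Allen's rules", {
  # construct: big-bodied species at high elevation, long tails at low
  n_site <- 12
  elev <- setNames(seq(500, 3800, length.out = n_site), sprintf("s%02d", 1:n_site))
  species <- sprintf("sp%02d", 1:10)
  occ <- matrix(0L, n_site, 10, dimnames = list(names(elev), species))
  opt <- seq(500, 3800, length.out = 10)
  for (j in 1:10) occ[abs(elev - opt[j]) < 1200, j] <- 1L
  traits <- tibble::tibble(species = species,
                           HL = 50 + 0.05 * opt,   # bigger higher: Bergmann-consistent
                           TR = 2 - 0.0003 * opt)  # shorter tails higher: Allen-consistent
  fam <- setNames(rep(c("FamA", "FamB"), each = 5), species)
  rep_tbl <- ecogeographic_report(mk_comm2(occ), traits, mk_sites(elev), fam,
                                  min_family_fraction = 0.2)
  ord <- rep_tbl[rep_tbl$level == "order", ]
  expect_equal(ord$verdict[ord$rule == "Bergmann"],
               "consistent with Bergmann's rule")
  expect_equal(ord$verdict[ord$rule == "Allen"],
               "consistent with Allen's rule")
  # both families hold 50% >= 20% of the pool, so both are reported
  expect_setequal(unique(rep_tbl$group), c("order", "FamA", "FamB"))
})

test_that("families below the species-fraction cutoff are excluded", {
  species <- sprintf("sp%02d", 1:10)
  fam <- setNames(c(rep("Big", 9), "Tiny"), species)
  elev <- setNames(seq(500, 3000, length.out = 8), sprintf("s%d", 1:8))
  occ <- matrix(1L, 8, 10, dimnames = list(names(elev), species))
  traits <- tibble::tibble(species = species, HL = runif(10, 50, 200),
                           TR = runif(10, 0.5, 2))
  rep_tbl <- ecogeographic_report(mk_comm2(occ), traits, mk_sites(elev), fam)
  expect_false("Tiny" %in% rep_tbl$group)
  expect_true("Big" %in% rep_tbl$group)
})

test_that("one family spanning the pool reproduces the order-level regression", {
  species <- sprintf("sp%02d", 1:6)
  fam <- setNames(rep("Only", 6), species)
  elev <- setNames(seq(500, 3000, length.out = 9), sprintf("s%d", 1:9))
  set.seed(129)
  occ <- matrix(as.integer(runif(54) < 0.6), 9, 6,
                dimnames = list(names(elev), species))
  traits <- tibble::tibble(species = species, HL = runif(6, 50, 200),
                           TR = runif(6, 0.5, 2))
  rep_tbl <- ecogeographic_report(mk_comm2(occ), traits, mk_sites(elev), fam)
  for (tr in c("HL", "TR")) {
    o <- rep_tbl[rep_tbl$level == "order" & rep_tbl$trait == tr, ]
    f <- rep_tbl[rep_tbl$group == "Only" & rep_tbl$trait == tr, ]
    expect_equal(o$slope, f$slope, tolerance = 1e-12)
    expect_equal(o$r2, f$r2, tolerance = 1e-12)
  }
})
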