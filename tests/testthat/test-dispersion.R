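test_that("cophenetic distances equal explicit path sums", {
  expect_equal(cophenetic_distance(tree_2tip())["A", "B"], 2)
  d3 <- cophenetic_distance(tree_3tip())
  expect_equal(d3["A", "C"], 4)
  expect_equal(d3["A", "B"], 2)
  tr <- simulate_tree(20, 1, seed = 13)
  d <- cophenetic_distance(tr)
  bf <- bf_cophenetic(tr)[rownames(d), colnames(d)]
  expect_lt(max(abs(d - bf)), 1e-12)
})

test_that("trait distances follow the standardized / mismatch / Gower definitions", {
  traits <- tibble::tibble(species = c("sp1", "sp2", "sp3"),
                           HL = c(10, 20, 30), TR = c(1, 1, 2),
                           ACD = c(0, 0, 1))
  kinds <- c(HL = "continuous", TR = "continuous", ACD = "binary")
  # single continuous trait: |z_i - z_j|
  d_hl <- trait_distance(traits, "HL", kinds)
  z <- (traits$HL - mean(traits$HL)) / sd(traits$HL)
  expect_equal(d_hl["sp1", "sp3"], abs(z[1] - z[3]))
  expect_equal(d_hl["sp1", "sp1"], 0)
  # binary mismatch
  d_acd <- trait_distance(traits, "ACD", kinds)
  expect_equal(d_acd["sp1", "sp3"], 1)
  expect_equal(d_acd["sp1", "sp2"], 0)
  # Gower hand computation: mean(|10-30|/20, |1-2|/1, 1) = 1
  d_all <- trait_distance(traits, "all", kinds)
  expect_equal(d_all["sp1", "sp3"], 1)
  expect_equal(d_all["sp1", "sp2"], mean(c(10 / 20, 0, 0)))
  # zero-variance continuous trait is an error
  traits0 <- tibble::tibble(species = c("a", "b"), HL = c(5, 5))
  expect_error(trait_distance(traits0, "HL", c(HL = "continuous")),
               "zero-variance")
})

test_that("Gower distances match the brute-force formula on random tables", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    traits <- tibble::tibble(species = sprintf("sp%02d", 1:n),
                             a = rnorm(n), b = runif(n, 10, 50),
                             c = as.numeric(runif(n) < 0.5))
    if (length(unique(traits$c)) == 1) next
    kinds <- c(a = "continuous", b = "continuous", c = "binary")
    d <- trait_distance(traits, "all", kinds)
    expect_lt(max(abs(d - bf_gower(traits, kinds))), 1e-12)
  }
})

test_that("mpd and mntd equal hand values and brute-force loops", {
  d2 <- cophenetic_distance(tree_2tip())
  expect_equal(mpd(c("A", "B"), d2), 2)
  expect_equal(mntd(c("A", "B"), d2), 2)
  d_star <- cophenetic_distance(star_tree(3))
  expect_equal(mpd(rownames(d_star), d_star), 2)
  # chain of trait values {0, 1, 3}: nearest distances {1, 1, 2}
  dm <- abs(outer(c(0, 1, 3), c(0, 1, 3), "-"))
  dimnames(dm) <- list(c("x", "y", "z"), c("x", "y", "z"))
  expect_equal(mntd(c("x", "y", "z"), dm), 4 / 3)
  expect_true(is.na(mpd("A", d2)))

  set.seed(51)
  tr <- simulate_tree(20, 1, seed = 15)
  d <- cophenetic_distance(tr)
  for (rep in 1:20) {
    sp <- sample(tr$tip.label, sample(2:12, 1))
    expect_lt(abs(mpd(sp, d) - bf_mpd(sp, d)), 1e-12)
    expect_lt(abs(mntd(sp, d) - bf_mntd(sp, d)), 1e-12)
    expect_lte(mntd(sp, d), mpd(sp, d) + 1e-12)
  }
})

test_that("independent swap preserves margins and handles degenerate matrices", {
  m <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
              dimnames = list(c("s1", "s2"), c("a", "b")))
  draws <- independent_swap(m, n_draws = 50, burn_in = 10, thin = 5, seed = 2)
  for (d in draws) {
    expect_equal(rowSums(d), rowSums(m))
    expect_equal(colSums(d), colSums(m))
  }
  # both checkerboard states are visited
  expect_equal(length(unique(vapply(draws, mat_key, character(1)))), 2)

  ones <- matrix(1L, 3, 3, dimnames = list(paste0("s", 1:3), paste0("p", 1:3)))
  expect_warning(dr <- independent_swap(ones, 5, 10, 5, seed = 1),
                 "no checkerboard")
  for (d in dr) expect_identical(unname(d), unname(ones))
})

test_that("the swap chain visits the whole fixed-margin set uniformly", {
  m <- matrix(c(1, 1, 0, 0,
                1, 0, 1, 0,
                0, 1, 0, 1,
                0, 0, 1, 1), 4, 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("p", 1:4)))
  storage.mode(m) <- "integer"
  universe <- enum_fixed_margin(m)
  draws <- independent_swap(m, n_draws = 20000, burn_in = 200, thin = 10,
                            seed = 77)
  keys <- vapply(draws, mat_key, character(1))
  expect_setequal(unique(keys), vapply(universe, mat_key, character(1)))
  tab <- table(keys)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("SES reproduces its defining formula and the exact enumeration null", {
  # 3x3 toy: enumerate the fixed-margin set for the exact null moments
  m <- matrix(c(1, 1, 0,
                1, 0, 1,
                0, 1, 1), 3, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), c("a", "b", "c")))
  storage.mode(m) <- "integer"
  dm <- matrix(c(0, 1, 3,
                 1, 0, 2,
                 3, 2, 0), 3, 3, dimnames = list(c("a", "b", "c"),
                                                 c("a", "b", "c")))
  universe <- enum_fixed_margin(m)
  exact_mean <- exact_sd <- numeric(3)
  for (i in 1:3) {
    vals <- vapply(universe, function(u)
      bf_mpd(colnames(u)[u[i, ] == 1L], dm), numeric(1))
    exact_mean[i] <- mean(vals)
    exact_sd[i] <- sd(vals)
  }
  res <- ses_dispersion(m, dm, "mpd", n_null = 999, burn_in = 500, thin = 20,
                        seed = 4)
  # formula identity
  ok <- !res$undefined_flag
  expect_lt(max(abs(res$ses[ok] - (res$obs[ok] - res$null_mean[ok]) /
                      res$null_sd[ok])), 1e-12)
  # swap-based null moments agree with enumeration within 3 standard errors
  se <- exact_sd / sqrt(res$n_null)
  expect_true(all(abs(res$null_mean - exact_mean) <= 3 * se + 1e-9))
})

test_that("undefined SES sites are flagged, not divided", {
  occ <- matrix(c(1L, 0L, 0L,
                  1L, 1L, 1L), 2, 3, byrow = TRUE,
                dimnames = list(c("poor", "rich"), c("a", "b", "c")))
  dm <- matrix(1, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(dm) <- 0
  res <- suppressWarnings(ses_dispersion(occ, dm, "mpd", n_null = 49, seed = 3))
  expect_true(res$undefined_flag[res$site == "poor"])
  expect_true(is.na(res$ses[res$site == "poor"]))
  # the rich site's null is degenerate too (all species always present)
  expect_true(res$undefined_flag[res$site == "rich"])
})

test_that("SES values track picante's independent-swap implementation", {
  set.seed(61)
  tr <- simulate_tree(25, 1, seed = 19)
  occ <- matrix(as.integer(runif(30 * 25) < 0.3), 30, 25,
                dimnames = list(sprintf("s%02d", 1:30), tr$tip.label))
  d <- cophenetic_distance(tr)
  mine <- ses_dispersion(occ, d, "mpd", n_null = 499, seed = 7)
  ref <- picante::ses.mpd(occ, d, null.model = "independentswap",
                          runs = 499, iterations = 1000)
  keep <- !mine$undefined_flag & !is.na(ref$mpd.obs.z)
  expect_gt(cor(mine$ses[keep], ref$mpd.obs.z[keep]), 0.95)
})
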