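#' Phylogenetic covariance matrix
#'
#' `V[i, j]` is the shared root-to-MRCA branch length of tips i and j (the
#' Brownian-motion covariance up to the rate); the diagonal holds
#' root-to-tip depths. Computed with [ape::vcv.phylo()].
#'
#' @param tree a rooted [ape::phylo] object.
#' @return labelled symmetric positive semidefinite matrix.
#' @export
phylo_covariance <- function(tree) {
  tree <- validate_phylogeny(tree)
  # a basal polytomy (e.g. a star tree) is a legitimate rooted shape here;
  # only genuinely rootless edge structures are rejected
  n_tip <- length(tree$tip.label)
  root_candidates <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(unique(root_candidates)) != 1) stop("tree must be rooted")
  ape::vcv.phylo(tree)
}

# K for one (or many) trait vectors given precomputed V machinery
k_statistic <- function(x, Vinv, trV, n, one_Vinv_one, expected) {
  # x: n x m matrix of trait columns (tip order matching V)
  ahat <- colSums(Vinv %*% x) / one_Vinv_one
  r <- sweep(x, 2, ahat)
  mse0 <- colSums(r * r) / (n - 1)
  mse <- colSums(r * (Vinv %*% r)) / (n - 1)
  (mse0 / mse) / expected
}

#' Blomberg's K for a continuous trait
#'
#' The ratio of observed phylogenetic signal to the Brownian-motion
#' expectation: `K = (MSE0/MSE) / E[MSE0/MSE]` where `MSE0` is the trait's
#' variance around the GLS ancestral estimate, `MSE` the
#' phylogenetically-corrected mean square, and the expectation
#' `(tr(V) - n / (1'V^-1 1)) / (n - 1)` follows from the tree alone.
#' K = 1 under Brownian motion, K < 1 for weaker, K > 1 for stronger
#' signal. Significance is by tip-label permutation of K itself:
#' `p = (1 + #{K_perm >= K_obs}) / (n_perm + 1)`.
#'
#' @param tree rooted [ape::phylo] covering the trait's species.
#' @param trait named numeric vector (names = tip labels).
#' @param n_perm number of permutations (>= 99).
#' @param seed optional integer seed.
#' @return one-row tibble: `trait`, `statistic = "K"`, `value`, `p_random`,
#'   `n_perm`, `seed`.
#' @export
blomberg_k <- function(tree, trait, n_perm = 999, seed = NULL) {
  tree <- validate_phylogeny(tree)
  if (is.null(names(trait))) stop("trait vector must be named by tip label")
  miss <- setdiff(tree$tip.label, names(trait))
  if (length(miss)) stop("trait missing for tips: ", paste(miss, collapse = ", "))
  x <- trait[tree$tip.label]
  if (var(x) == 0) stop("zero-variance trait")
  n <- length(x)
  V <- phylo_covariance(tree)
  Vinv <- tryCatch(solve(V), error = function(e) stop("singular phylogenetic covariance"))
  one_Vinv_one <- sum(Vinv)
  expected <- (sum(diag(V)) - n / one_Vinv_one) / (n - 1)
  k_obs <- k_statistic(matrix(x, ncol = 1), Vinv, sum(diag(V)), n,
                       one_Vinv_one, expected)
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) sample(x), numeric(n))
  k_perm <- k_statistic(perm, Vinv, sum(diag(V)), n, one_Vinv_one, expected)
  p <- (1 + sum(k_perm >= k_obs)) / (n_perm + 1)
  tibble::tibble(trait = deparse(substitute(trait)), statistic = "K",
                 value = unname(k_obs), p_random = p,
                 p_brownian = NA_real_, n_perm = as.integer(n_perm),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

# sum over edges of |value(child) - value(parent)| after post-order nodal
# averaging (node value = mean of its children's values, polytomy-safe).
# states: tips x m matrix in tree tip order. Returns length-m vector.
sum_state_changes <- function(tree, states) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  m <- ncol(states)
  po <- ape::reorder.phylo(tree, "postorder")
  val <- matrix(NA_real_, n_node, m)
  val[seq_len(n_tip), ] <- states
  parents <- po$edge[, 1]
  # postorder edge order guarantees all children of a parent precede it;
  # parents appear in contiguous runs in postorder edge lists
  for (p in unique(parents)) {
    ch <- po$edge[parents == p, 2]
    val[p, ] <- colMeans(val[ch, , drop = FALSE])
  }
  diffs <- abs(val[po$edge[, 2], , drop = FALSE] - val[po$edge[, 1], , drop = FALSE])
  colSums(diffs)
}

#' Fritz-Purvis D statistic for a binary trait
#'
#' Measures phylogenetic signal in a 0/1 trait by the total amount of
#' state change `sum(d)` implied by post-order nodal averaging, scaled
#' between two reference points: random tip shuffles (D = 1) and
#' Brownian-threshold arrangements at the observed prevalence (D = 0):
#' `D = (sumd_obs - mean(sumd_B)) / (mean(sumd_R) - mean(sumd_B))`.
#' D near 1 indicates a phylogenetically random trait, D near or below 0 a
#' clumped (conserved) one. Two p-values accompany it: `p_random`, the
#' permutation probability of observing as little change as the data under
#' random shuffles, and `p_brownian`, the probability of as much change
#' under the Brownian threshold model (both with the +1 correction so they
#' lie in (0, 1]).
#'
#' @param tree rooted [ape::phylo] with >= 4 tips.
#' @param binary_trait named 0/1 vector over tips, both states present.
#' @param n_perm permutation and simulation count (default 1000).
#' @param seed optional integer seed.
#' @return one-row tibble: `trait`, `statistic = "D"`, `value`, `p_random`,
#'   `p_brownian`, `n_perm`, `seed`.
#' @export
fritz_purvis_d <- function(tree, binary_trait, n_perm = 1000, seed = NULL) {
  tree <- validate_phylogeny(tree)
  if (length(tree$tip.label) < 4) stop("D requires at least 4 tips")
  if (is.null(names(binary_trait))) stop("trait vector must be named by tip label")
  miss <- setdiff(tree$tip.label, names(binary_trait))
  if (length(miss)) stop("trait missing for tips: ", paste(miss, collapse = ", "))
  x <- as.numeric(binary_trait[tree$tip.label])
  if (!all(x %in% c(0, 1))) stop("trait must be binary 0/1")
  k <- sum(x)
  n <- length(x)
  if (k == 0 || k == n) stop("both states must be present")
  if (!is.null(seed)) set.seed(seed)
  sumd_obs <- sum_state_changes(tree, matrix(x, ncol = 1))
  perm <- vapply(seq_len(n_perm), function(i) sample(x), numeric(n))
  sumd_r <- sum_state_changes(tree, perm)
  bm <- simulate_bm_trait(tree, sigma2 = 1, n = n_perm)
  thresh <- apply(bm, 2, function(z) {
    y <- numeric(n); y[order(z, decreasing = TRUE)[seq_len(k)]] <- 1; y
  })
  sumd_b <- sum_state_changes(tree, thresh)
  denom <- mean(sumd_r) - mean(sumd_b)
  if (abs(denom) < 1e-10) {
    stop("degenerate D denominator: random and Brownian references coincide")
  }
  d_val <- (sumd_obs - mean(sumd_b)) / denom
  p_random <- (1 + sum(sumd_r <= sumd_obs)) / (n_perm + 1)
  p_brownian <- (1 + sum(sumd_b >= sumd_obs)) / (n_perm + 1)
  tibble::tibble(trait = deparse(substitute(binary_trait)), statistic = "D",
                 value = unname(d_val), p_random = p_random,
                 p_brownian = p_brownian, n_perm = as.integer(n_perm),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Phylogenetic signal for every trait in a table
#'
#' Dispatches [blomberg_k()] to continuous traits and [fritz_purvis_d()] to
#' binary ones, producing a tidy table of statistics and p-values.
#'
#' @param tree rooted phylogeny.
#' @param traits trait tibble with a `species` column.
#' @param trait_kind named kind vector; inferred from \{0,1\} values if `NULL`.
#' @param n_perm permutations per trait.
#' @param seed master seed; per-trait seeds derive via [split_seed()].
#' @return tibble with one row per trait.
#' @export
phylo_signal_table <- function(tree, traits, trait_kind = NULL,
                               n_perm = 999, seed = 1L) {
  tr_names <- setdiff(names(traits), "species")
  if (is.null(trait_kind)) {
    trait_kind <- vapply(tr_names, function(tr)
      if (all(traits[[tr]] %in% c(0, 1))) "binary" else "continuous", character(1))
  }
  sp_in_tree <- traits$species %in% tree$tip.label
  res <- purrr::imap(setNames(tr_names, tr_names), function(tr, nm) {
    x <- setNames(traits[[tr]][sp_in_tree], traits$species[sp_in_tree])
    s <- split_seed(seed, match(tr, tr_names))
    out <- if (trait_kind[[tr]] == "binary") {
      fritz_purvis_d(tree, x, n_perm = max(n_perm, 1000), seed = s)
    } else {
      blomberg_k(tree, x, n_perm = n_perm, seed = s)
    }
    out$trait <- nm
    out
  })
  dplyr::bind_rows(res)
}
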