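# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and ape's cophenetic): path sums walk
# the edge matrix directly, means are explicit double loops.

# cophenetic distance by explicit root-path traversal of the edge matrix
bf_cophenetic <- function(tree) {
  n <- length(tree$tip.label)
  edge <- tree$edge
  len <- tree$edge.length
  parent_of <- function(node) {
    i <- which(edge[, 2] == node)
    if (!length(i)) NULL else list(parent = edge[i, 1], len = len[i])
  }
  # ancestor chain of a tip: named vector of cumulative distance to each
  # ancestor node (including itself at 0)
  chain <- function(tip) {
    d <- c(0); names(d) <- tip
    node <- tip; acc <- 0
    repeat {
      p <- parent_of(node)
      if (is.null(p)) break
      acc <- acc + p$len
      d <- c(d, setNames(acc, p$parent))
      node <- p$parent
    }
    d
  }
  chains <- lapply(seq_len(n), chain)
  out <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- intersect(names(chains[[i]]), names(chains[[j]]))
      mrca_d <- min(chains[[i]][shared] + chains[[j]][shared])
      out[i, j] <- out[j, i] <- mrca_d
    }
  }
  out
}

bf_mpd <- function(sp, d) {
  k <- length(sp)
  if (k < 2) return(NA_real_)
  s <- 0; cnt <- 0
  for (a in 1:(k - 1)) for (b in (a + 1):k) {
    s <- s + d[sp[a], sp[b]]; cnt <- cnt + 1
  }
  s / cnt
}

bf_mntd <- function(sp, d) {
  k <- length(sp)
  if (k < 2) return(NA_real_)
  tot <- 0
  for (a in seq_len(k)) {
    mn <- Inf
    for (b in seq_len(k)) if (a != b) mn <- min(mn, d[sp[a], sp[b]])
    tot <- tot + mn
  }
  tot / k
}

bf_gower <- function(traits, kinds) {
  sp <- traits$species
  tr <- setdiff(names(traits), "species")
  n <- length(sp)
  out <- matrix(0, n, n, dimnames = list(sp, sp))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    comp <- numeric(0)
    for (t in tr) {
      x <- traits[[t]]
      comp <- c(comp, if (kinds[[t]] == "binary") as.numeric(x[i] != x[j])
                else abs(x[i] - x[j]) / diff(range(x)))
    }
    out[i, j] <- mean(comp)
  }
  out
}

bf_ols <- function(x, y) {
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = sl, intercept = mean(y) - sl * mean(x))
}

# every 0/1 matrix with the same row and column sums as m (small m only)
enum_fixed_margin <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(nr * nc <= 16)
  rs <- rowSums(m); cs <- colSums(m)
  out <- list()
  for (i in 0:(2^(nr * nc) - 1)) {
    v <- as.integer(intToBits(i)[seq_len(nr * nc)])
    mm <- matrix(v, nr, nc)
    if (all(rowSums(mm) == rs) && all(colSums(mm) == cs)) {
      dimnames(mm) <- dimnames(m)
      out[[length(out) + 1]] <- mm
    }
  }
  out
}

mat_key <- function(m) paste(m, collapse = "")

# small fixed trees used in several files
tree_2tip <- function() ape::read.tree(text = "(A:1,B:1);")
tree_3tip <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")
star_tree <- function(n, bl = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(bl, nrow(tr$edge))
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}
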