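#' Ezekiel adjusted R-squared
#'
#' `1 - (1 - r2) * (n - 1) / (n - p - 1)`; with `p = 0` predictors the R2
#' passes through unchanged. The adjustment makes explained-variance
#' fractions comparable across predictor sets of different size, which is
#' what variance partitioning sums.
#'
#' @param r2 unadjusted R-squared.
#' @param n number of observations.
#' @param p number of predictors (excluding the intercept).
#' @return adjusted R-squared (can be negative).
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (n <= p + 1) stop("n must exceed p + 1 for the adjustment")
  if (p == 0) return(r2)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

# R^2 of y on columns of X (with intercept), via QR; X may be NULL/empty
r2_of <- function(y, X) {
  yc <- y - mean(y)
  tss <- sum(yc^2)
  if (is.null(X) || ncol(X) == 0) return(0)
  q <- qr(cbind(1, X))
  res <- qr.resid(q, y)
  1 - sum(res^2) / tss
}

# drop collinear (redundant) columns within a predictor matrix, warning
drop_collinear <- function(X, label = "predictor") {
  if (is.null(X) || ncol(X) <= 1) return(X)
  q <- qr(cbind(1, scale(X, scale = FALSE)))
  keep <- q$pivot[seq_len(q$rank)] - 1L
  keep <- sort(keep[keep > 0])
  if (length(keep) < ncol(X)) {
    dropped <- setdiff(colnames(X), colnames(X)[keep])
    warning("dropping collinear ", label, " column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  X
}

# permutation F-test that adding `X_add` to `X_base` improves the fit.
# Freedman-Lane: permute residuals of the base model. Returns list(F, p).
perm_partial_f <- function(y, X_base, X_add, n_perm = 999) {
  n <- length(y)
  q_base <- qr(cbind(rep(1, n), X_base))
  fit_base <- qr.fitted(q_base, y)
  res_base <- y - fit_base
  X_full <- cbind(rep(1, n), X_base, X_add)
  q_full <- qr(X_full)
  p_full <- q_full$rank - 1
  df_add <- q_full$rank - q_base$rank
  if (df_add <= 0 || n - p_full - 1 <= 0) return(list(stat = NA_real_, p = NA_real_))
  f_stat <- function(yy) {
    rss_b <- sum((yy - qr.fitted(q_base, yy))^2)
    rss_f <- sum(qr.resid(q_full, yy)^2)
    ((rss_b - rss_f) / df_add) / (rss_f / (n - p_full - 1))
  }
  f_obs <- f_stat(y)
  f_perm <- vapply(seq_len(n_perm), function(i) {
    f_stat(fit_base + res_base[sample.int(n)])
  }, numeric(1))
  list(stat = f_obs, p = (1 + sum(f_perm >= f_obs)) / (n_perm + 1))
}

#' Forward selection of predictors with the double stopping criterion
#'
#' First the global model (all candidates) is tested by permutation F-test;
#' if it is not significant at `alpha` the selection is empty. Otherwise
#' candidates enter one at a time, each step taking the variable giving the
#' largest R-squared improvement, and stopping when the entering
#' candidate's permutation p-value exceeds `alpha` or when the selected
#' model's adjusted R-squared would exceed the global model's — the
#' double stopping rule that curbs the classic forward-selection
#' inflation. Exactly collinear candidates are dropped with a warning.
#'
#' @param response numeric vector.
#' @param candidates data frame / matrix of candidate predictors (complete
#'   cases only).
#' @param alpha entry significance level.
#' @param n_perm permutations per test.
#' @param seed optional integer seed.
#' @return tibble of selected variables in entry order with `variable`,
#'   `r2_cum`, `adj_r2_cum`, `p_enter`; zero rows when nothing passes.
#'   Attributes `global_p` and `global_adj_r2` record the global test.
#' @export
forward_select <- function(response, candidates, alpha = 0.05,
                           n_perm = 999, seed = NULL) {
  X <- as.matrix(candidates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(length(response) == nrow(X), ncol(X) >= 1)
  if (anyNA(response) || anyNA(X)) stop("complete cases required")
  if (!is.null(seed)) set.seed(seed)
  X <- drop_collinear(X, "candidate")
  n <- length(response)
  empty <- tibble::tibble(variable = character(), r2_cum = numeric(),
                          adj_r2_cum = numeric(), p_enter = numeric())
  glob <- perm_partial_f(response, NULL, X, n_perm)
  glob_adj <- adjusted_r2(r2_of(response, X), n, qr(cbind(1, X))$rank - 1)
  decorate <- function(tb) {
    attr(tb, "global_p") <- glob$p
    attr(tb, "global_adj_r2") <- glob_adj
    tb
  }
  if (is.na(glob$p) || glob$p > alpha) return(decorate(empty))
  selected <- integer(0)
  rows <- list()
  remaining <- seq_len(ncol(X))
  repeat {
    if (!length(remaining)) break
    r2s <- vapply(remaining, function(j) {
      r2_of(response, X[, c(selected, j), drop = FALSE])
    }, numeric(1))
    j_best <- remaining[which.max(r2s)]
    r2_new <- max(r2s)
    adj_new <- adjusted_r2(r2_new, n, length(selected) + 1)
    test <- perm_partial_f(response, if (length(selected)) X[, selected, drop = FALSE] else NULL,
                           X[, j_best, drop = FALSE], n_perm)
    if (is.na(test$p) || test$p > alpha) break
    selected <- c(selected, j_best)
    remaining <- setdiff(remaining, j_best)
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = colnames(X)[j_best], r2_cum = r2_new,
      adj_r2_cum = adj_new, p_enter = test$p)
    # second stopping rule: no further entry once the selected model's
    # adjusted R2 reaches the global model's
    if (adj_new > glob_adj - 1e-12) break
  }
  decorate(if (length(rows)) dplyr::bind_rows(rows) else empty)
}

#' Three-set variance partitioning of a univariate response
#'
#' Decomposes the adjusted R-squared of `response` on the union of three
#' predictor sets (environment E, space S, phylogeny P) into pure and
#' shared fractions by inclusion-exclusion over the seven nested OLS fits:
#' pure E = adjR2(ESP) - adjR2(SP), cyclically; pairwise and triple
#' intersections follow from the singleton and pairwise unions. Shared
#' fractions are not variance components and may legitimately be negative;
#' they are reported as computed, never clipped. Each pure fraction's
#' significance is a Freedman-Lane permutation partial F-test of adding
#' that set given the other two.
#'
#' @param response numeric vector.
#' @param set_E,set_S,set_P data frames / matrices of predictors (any may
#'   be `NULL` or zero-column, then its fractions are 0).
#' @param n_perm permutations for pure-fraction tests.
#' @param seed optional integer seed.
#' @param response_name label carried into the result.
#' @return object of class `varpart3`; see [tidy.varpart3()] and
#'   [glance.varpart3()].
#' @export
variance_partition3 <- function(response, set_E, set_S, set_P,
                                n_perm = 999, seed = NULL,
                                response_name = "response") {
  sets <- list(E = set_E, S = set_S, P = set_P)
  sets <- lapply(sets, function(s) {
    if (is.null(s)) return(NULL)
    m <- as.matrix(s)
    if (ncol(m) == 0) return(NULL)
    if (is.null(colnames(m))) colnames(m) <- paste0("v", seq_len(ncol(m)))
    m
  })
  n <- length(response)
  if (anyNA(response) || any(vapply(sets, function(s) !is.null(s) && anyNA(s), logical(1)))) {
    stop("complete cases required across response and all predictor sets")
  }
  if (!is.null(seed)) set.seed(seed)
  combo <- function(keys) {
    mats <- Filter(Negate(is.null), sets[keys])
    if (!length(mats)) return(NULL)
    do.call(cbind, mats)
  }
  adj <- function(keys) {
    X <- combo(keys)
    if (is.null(X)) return(0)
    p <- qr(cbind(1, X))$rank - 1
    if (n <= p + 1) {
      stop("model on set {", paste(keys, collapse = ","),
           "} has n <= p + 1; reduce predictors (n = ", n, ", p = ", p, ")")
    }
    adjusted_r2(r2_of(response, X), n, p)
  }
  aE <- adj("E"); aS <- adj("S"); aP <- adj("P")
  aES <- adj(c("E", "S")); aEP <- adj(c("E", "P")); aSP <- adj(c("S", "P"))
  aESP <- adj(c("E", "S", "P"))
  g <- aE + aS + aP - aES - aEP - aSP + aESP
  fractions <- c(
    pure_E = aESP - aSP, pure_S = aESP - aEP, pure_P = aESP - aES,
    shared_ES = aE + aS - aES - g,
    shared_EP = aE + aP - aEP - g,
    shared_SP = aS + aP - aSP - g,
    shared_ESP = g,
    residual = 1 - aESP)
  p_pure <- c(E = NA_real_, S = NA_real_, P = NA_real_)
  others <- list(E = c("S", "P"), S = c("E", "P"), P = c("E", "S"))
  for (k in names(others)) {
    if (is.null(sets[[k]])) next
    t <- perm_partial_f(response, combo(others[[k]]), sets[[k]], n_perm)
    p_pure[k] <- t$p
  }
  structure(list(
    response = response_name,
    fractions = fractions,
    model_r2adj = c(E = aE, S = aS, P = aP, ES = aES, EP = aEP,
                    SP = aSP, ESP = aESP),
    p_pure = p_pure, n_perm = as.integer(n_perm), n_sites = n,
    set_sizes = vapply(sets, function(s) if (is.null(s)) 0L else ncol(s),
                       integer(1))),
    class = "varpart3")
}

#' @export
print.varpart3 <- function(x, ...) {
  cat("Three-set variance partitioning of", x$response,
      "(n =", x$n_sites, ")\n")
  fr <- format(round(x$fractions, 4))
  for (i in seq_along(fr)) cat(" ", names(fr)[i], "=", fr[i], "\n")
  cat("pure-fraction p-values:",
      paste(names(x$p_pure), format(x$p_pure, digits = 3), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Tidy the fractions of a variance partition
#'
#' @param x a `varpart3` object.
#' @param ... unused.
#' @return tibble with `response`, `fraction`, `adj_r2`, `p_value` (pure
#'   fractions only; shared fractions carry `NA` — they have no individual
#'   test).
#' @export
tidy.varpart3 <- function(x, ...) {
  p <- setNames(rep(NA_real_, length(x$fractions)), names(x$fractions))
  p[c("pure_E", "pure_S", "pure_P")] <- x$p_pure[c("E", "S", "P")]
  tibble::tibble(response = x$response, fraction = names(x$fractions),
                 adj_r2 = unname(x$fractions), p_value = unname(p))
}

#' One-row summary of a variance partition
#'
#' @param x a `varpart3` object.
#' @param ... unused.
#' @return tibble with the full-model adjusted R-squared, residual
#'   fraction, n and permutation count.
#' @export
glance.varpart3 <- function(x, ...) {
  tibble::tibble(response = x$response,
                 adj_r2_full = unname(x$model_r2adj["ESP"]),
                 residual = unname(x$fractions["residual"]),
                 n_sites = x$n_sites, n_perm = x$n_perm)
}
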