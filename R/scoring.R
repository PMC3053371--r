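# The statistical core: empirical-CDF calibration of threading Z-scores,
# hypergeometric over-representation of expected structures in the top
# window, combination into a single p-value, and the accept/reject call.

#' Build an empirical background CDF of threading Z-scores
#'
#' The background sample pools Z-scores from threading runs of random
#' (non-homologous) proteins; the synthetic generator supplies a model
#' sample. Upper-tail probabilities use the pseudocount convention
#' `p(z) = (# background >= z + 1) / (n + 1)` so p is never zero.
#'
#' @param background Numeric vector of background Z-scores (>= 10,000
#'   values).
#' @param source Provenance tag.
#' @return An `empirical_cdf` object.
#' @export
build_cdf <- function(background, source = NULL) {
  if (length(background) < 10000) {
    abort("need at least 10,000 background Z-scores")
  }
  if (anyNA(background)) abort("background contains NA")
  structure(list(sorted = sort(background), n = length(background),
                 source = source %||% attr(background, "source") %||% "unknown"),
            class = "empirical_cdf")
}

#' Upper-tail probability under an empirical background CDF
#'
#' @param cdf An `empirical_cdf` from [build_cdf()].
#' @param z Numeric vector of Z-scores.
#' @return `(# background >= z + 1) / (n + 1)`, in (0, 1].
#' @export
cdf_upper_tail <- function(cdf, z) {
  stopifnot(inherits(cdf, "empirical_cdf"))
  n_lt <- findInterval(z, cdf$sorted, left.open = TRUE)
  n_ge <- cdf$n - n_lt
  pmin(1, (n_ge + 1) / (cdf$n + 1))
}

#' @export
print.empirical_cdf <- function(x, ...) {
  cat("<empirical_cdf> n =", x$n, "source:", x$source, "\n")
  invisible(x)
}

#' Hypergeometric upper-tail probability for the top-window test
#'
#' `P(X >= k)` where `X ~ Hypergeometric(N, m, n)`: drawing the top `n`
#' ranked structures from a library of `N` in which `m` are mapped to the
#' expected domain, X counts expected structures in the window. Exact
#' (log-gamma based) computation via [stats::phyper()].
#'
#' @param k Expected structures observed in the top window.
#' @param m Structures mapped to the expected domain.
#' @param n Top-window size.
#' @param N Library size (all structures threaded).
#' @return `P(X >= k)`.
#' @export
hypergeom_upper <- function(k, m, n, N) {
  if (any(n > N) || any(m > N)) abort("n and m must not exceed N")
  if (any(k < 0) || any(k > pmin(n, m))) {
    abort("k must satisfy 0 <= k <= min(n, m)")
  }
  phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' Combine the CDF and hypergeometric p-values
#'
#' The default rule is the plain product `p_cdf * p_hyper`; Fisher's
#' method (chi-squared with 4 df on `-2 * sum(log p)`) is available as an
#' alternative strategy. Both are monotone in each argument.
#'
#' @param p_cdf,p_hyper Probabilities in (0, 1].
#' @param method `"product"` (default) or `"fisher"`.
#' @return Combined probability in (0, 1].
#' @export
combine_pvalues <- function(p_cdf, p_hyper,
                            method = c("product", "fisher")) {
  method <- match.arg(method)
  if (any(p_cdf <= 0 | p_cdf > 1) || any(p_hyper <= 0 | p_hyper > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  switch(method,
         product = p_cdf * p_hyper,
         fisher = pchisq(-2 * (log(p_cdf) + log(p_hyper)), df = 4,
                         lower.tail = FALSE))
}

#' Score a threading result against the expected structures
#'
#' Computes the combined fold-recognition statistic for one query region:
#' `k` expected structures among the top `n` ranked of `N` threaded, with
#' `m` structures mapped to the expected domain; `p_cdf` is the background
#' upper-tail probability of the best expected Z-score inside the window
#' (1 when no expected structure reaches the window, in which case the
#' domain cannot be accepted); `p_hyper` is the hypergeometric upper tail;
#' the call is accepted when the combined value is at or below `alpha`
#' and `k >= 1`.
#'
#' @param result A `threading_result`.
#' @param expected_structures Character vector of structure ids mapped to
#'   the expected domain (non-empty; structure gating happens upstream).
#' @param cdf An `empirical_cdf` background.
#' @param window Top-window size, default [top_window()] of the library.
#' @param alpha Acceptance threshold on the combined p-value.
#' @param method Combination rule, see [combine_pvalues()].
#' @return A `fold_score` object.
#' @export
score_threading <- function(result, expected_structures, cdf,
                            window = top_window(nrow(result)),
                            alpha = 0.001,
                            method = c("product", "fisher")) {
  method <- match.arg(method)
  if (length(expected_structures) == 0) {
    abort("expected structure set is empty (structure gating should have prevented scoring)")
  }
  missing <- setdiff(expected_structures, result$structure_id)
  if (length(missing) > 0) {
    abort(paste0("expected structure(s) not in threaded library: ",
                 paste(missing, collapse = ", ")))
  }
  N <- nrow(result)
  if (window > N) abort("window larger than library")
  top <- result$structure_id[result$rank <= window]
  inwin <- intersect(expected_structures, top)
  k <- length(inwin)
  m <- length(unique(expected_structures))
  if (k >= 1) {
    best_z <- max(result$zscore[result$structure_id %in% inwin])
    p_cdf <- cdf_upper_tail(cdf, best_z)
  } else {
    best_z <- NA_real_
    p_cdf <- 1
  }
  p_hyper <- hypergeom_upper(k, m, window, N)
  p_comb <- combine_pvalues(p_cdf, p_hyper, method)
  structure(list(p_cdf = p_cdf, p_hyper = p_hyper, p_combined = p_comb,
                 accepted = (p_comb <= alpha) && k >= 1,
                 params = list(N = N, n = window, m = m, k = k),
                 best_expected_z = best_z, alpha = alpha, method = method),
            class = "fold_score")
}

#' @export
print.fold_score <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<fold_score> %s  p_cdf=%.3g p_hyper=%.3g p_combined=%.3g  (N=%d n=%d m=%d k=%d)\n",
    if (x$accepted) "ACCEPTED" else "rejected",
    x$p_cdf, x$p_hyper, x$p_combined, p$N, p$n, p$m, p$k))
  invisible(x)
}

#' Tidy a fold score into a one-row tibble
#'
#' @param x A `fold_score`.
#' @param ... Unused.
#' @return One-row tibble with the p-values, decision and window counts.
#' @export
tidy.fold_score <- function(x, ...) {
  tibble(p_cdf = x$p_cdf, p_hyper = x$p_hyper, p_combined = x$p_combined,
         accepted = x$accepted, best_expected_z = x$best_expected_z,
         N = x$params$N, n_window = x$params$n, m = x$params$m,
         k = x$params$k)
}

#' @rdname tidy.fold_score
#' @export
glance.fold_score <- function(x, ...) {
  tidy(x)
}
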