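#' Average ranks with ties
#'
#' Midranks: tied values receive the mean of the positions they occupy, so
#' the ranks always sum to `n(n+1)/2`. Thin wrapper over
#' `rank(ties.method = "average")` that rejects non-finite input, since every
#' downstream tie-aware statistic assumes finite values.
#'
#' @param values Finite numeric vector.
#' @return Numeric vector of ranks.
#' @export
#' @examples
#' rank_with_ties(c(10, 20, 20, 30)) # 1, 2.5, 2.5, 4
rank_with_ties <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("domain error: values must be finite numerics", call. = FALSE)
  }
  rank(values, ties.method = "average")
}

test_result <- function(method, statistic, df, p_value, n,
                        alternative = "two.sided", notes = "") {
  structure(
    tibble::tibble(
      method = method, statistic = statistic, df = df, p_value = p_value,
      n = n, alternative = alternative, notes = notes
    ),
    class = c("ethno_test", class(tibble::tibble()))
  )
}

#' Spearman rank correlation
#'
#' Tie-aware Spearman correlation: rho is the Pearson correlation of the
#' midranks. The p-value is asymptotic by default (the `t`-approximation on
#' `n - 2` degrees of freedom used by `stats::cor.test`); for small samples
#' an exact permutation p-value is available, computed by full enumeration
#' of the `n!` orderings when `n <= exact_max` and by Monte Carlo (respecting
#' the session RNG) above that.
#'
#' @param x,y Equal-length finite numeric vectors, `n >= 3`.
#' @param p_method `"asymptotic"` (default) or `"permutation"`.
#' @param exact_max Largest `n` for exhaustive permutation enumeration
#'   (default 8; `8! = 40320` orderings).
#' @param n_perm Monte Carlo permutation count when `n > exact_max`.
#' @return A one-row `"ethno_test"` tibble: `method`, `statistic` (rho),
#'   `df`, `p_value`, `n`, `alternative`, `notes`.
#' @export
spearman_rho <- function(x, y, p_method = c("asymptotic", "permutation"),
                         exact_max = 8, n_perm = 10000) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("sample-size error: need n >= 3", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("domain error: values must be finite", call. = FALSE)
  }
  rx <- rank_with_ties(x)
  ry <- rank_with_ties(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    stop("undefined correlation: zero rank variance", call. = FALSE)
  }
  rho <- cor(rx, ry)
  if (p_method == "asymptotic") {
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE)
    )
    p <- ct$p.value
    notes <- "asymptotic t approximation, average ranks"
  } else {
    p <- spearman_perm_p(rx, ry, rho, exact_max, n_perm)
    notes <- if (n <= exact_max) {
      sprintf("exact permutation p over %d! orderings", n)
    } else {
      sprintf("Monte Carlo permutation p, %d draws", n_perm)
    }
  }
  test_result("Spearman rank correlation", rho, NA_real_, p, n,
              notes = notes)
}

spearman_perm_p <- function(rx, ry, rho_obs, exact_max, n_perm) {
  n <- length(rx)
  rho_of <- function(perm_ry) cor(rx, perm_ry)
  if (n <= exact_max) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(idx) rho_of(ry[idx]))
    mean(abs(rhos) >= abs(rho_obs) - 1e-12)
  } else {
    rhos <- vapply(seq_len(n_perm), function(i) rho_of(sample(ry)),
                   numeric(1))
    # add-one correction keeps Monte Carlo p strictly positive
    (sum(abs(rhos) >= abs(rho_obs) - 1e-12) + 1) / (n_perm + 1)
  }
}

# all n! permutations of 1..n as a matrix (rows); plumbing for exact tests
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    shifted <- sub + (sub >= i)
    out[rows, -1L] <- shifted
  }
  out
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with the chi-square approximation on
#' `k - 1` degrees of freedom (delegating to `stats::kruskal.test`). When
#' every observation is identical the statistic is defined as `H = 0` with
#' `p = 1` (the tie-correction denominator vanishes; no evidence against
#' homogeneity by convention).
#'
#' @param groups List of finite numeric vectors, one per group (>= 2 groups,
#'   each non-empty, total `n >= 3`).
#' @return A one-row `"ethno_test"` tibble with `statistic` = H.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))$statistic # 3.857
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("domain error: need >= 2 groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("domain error: empty group", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(values))) {
    stop("domain error: values must be finite", call. = FALSE)
  }
  if (length(values) < 3) {
    stop("sample-size error: need total n >= 3", call. = FALSE)
  }
  k <- length(groups)
  if (length(unique(values)) == 1) {
    return(test_result("Kruskal-Wallis rank sum test", 0, k - 1, 1,
                       length(values),
                       notes = "all observations equal; H = 0 by convention"))
  }
  g <- factor(rep(seq_len(k), sizes))
  kt <- stats::kruskal.test(values, g)
  test_result("Kruskal-Wallis rank sum test",
              unname(kt$statistic), unname(kt$parameter), kt$p.value,
              length(values), notes = "tie-corrected, chi-square approximation")
}

#' Paired t test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on `n - 1` degrees of freedom, for
#' paired differences `d = a - b`. Identical vectors return `t = 0` with
#' `p = 1` (documented convention); any other zero-variance difference is a
#' degenerate-input error.
#'
#' @param a,b Equal-length finite numeric vectors, `n >= 2`.
#' @return A one-row `"ethno_test"` tibble.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 2) stop("sample-size error: need n >= 2 pairs", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("domain error: values must be finite", call. = FALSE)
  }
  d <- a - b
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(test_result("Paired t test", 0, n - 1, 1, n,
                         notes = "identical vectors; t = 0, p = 1 by convention"))
    }
    stop("degenerate input: zero variance of paired differences", call. = FALSE)
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  test_result("Paired t test", unname(tt$statistic), unname(tt$parameter),
              tt$p.value, n)
}

#' Resource availability hypothesis (RAH) test
#'
#' The RAH predicts that locally more abundant species accrue higher use
#' values. At the ethnic-group pairing unit, group-level use values are
#' correlated (Spearman) against group-level densities; groups present in
#' only one of the two maps are dropped with a warning. The hypothesis is
#' directional, so support requires both `rho > 0` and `p < alpha`.
#'
#' @param uv_by_group Named numeric vector of use values per group.
#' @param density_by_group Named numeric vector of densities (tufts/ha) per
#'   group.
#' @param alpha Significance level, default 0.05.
#' @param species Optional species label carried into the result.
#' @param ... Passed to [spearman_rho()].
#' @return A list of class `"rah_result"`: `species`, `paired_groups`
#'   (tibble `group`, `UV`, `Ni`), `test` (`"ethno_test"`), `support`
#'   (`"supported"`/`"not supported"`), `alpha`, `dropped_groups`.
#' @export
rah_test <- function(uv_by_group, density_by_group, alpha = 0.05,
                     species = NA_character_, ...) {
  stopifnot(!is.null(names(uv_by_group)), !is.null(names(density_by_group)))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  common <- intersect(names(uv_by_group), names(density_by_group))
  dropped <- setdiff(union(names(uv_by_group), names(density_by_group)), common)
  keep <- common[!is.na(uv_by_group[common]) & !is.na(density_by_group[common])]
  dropped <- c(dropped, setdiff(common, keep))
  if (length(dropped)) {
    warning("dropped group(s) without both UV and density: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (length(keep) < 3) {
    stop("sample-size error: need >= 3 groups with both UV and density",
         call. = FALSE)
  }
  pairs <- tibble::tibble(group = keep, UV = unname(uv_by_group[keep]),
                          Ni = unname(density_by_group[keep]))
  test <- spearman_rho(pairs$UV, pairs$Ni, ...)
  support <- if (test$statistic > 0 && test$p_value < alpha) {
    "supported"
  } else {
    "not supported"
  }
  structure(
    list(species = species, paired_groups = pairs, test = test,
         support = support, alpha = alpha, dropped_groups = dropped),
    class = "rah_result"
  )
}

#' @export
print.rah_result <- function(x, ...) {
  cat("<rah_result>", if (!is.na(x$species)) x$species else "", "\n")
  cat("  n =", nrow(x$paired_groups), "groups; rho =",
      format(x$test$statistic, digits = 3), "; p =",
      format(x$test$p_value, digits = 3), "\n")
  cat("  resource availability hypothesis:", x$support, "at alpha =",
      x$alpha, "\n")
  invisible(x)
}

#' Cross-cultural test of use values
#'
#' Kruskal-Wallis on per-informant use values grouped by ethnic group: do
#' use values vary systematically across cultures? Requires at least two
#' groups each with at least one informant interviewed for the species, and
#' at least three informants overall.
#'
#' @param dataset An [interview_set()].
#' @param species Species label.
#' @return A one-row `"ethno_test"` tibble (see [kruskal_wallis()]).
#' @export
crosscultural_test <- function(dataset, species) {
  stopifnot(inherits(dataset, "interview_set"))
  groups <- sort(unique(dataset$informants$ethnic_group))
  uvis <- lapply(groups, function(g) uvis_vector(dataset, species, g))
  uvis <- uvis[lengths(uvis) > 0]
  if (length(uvis) < 2) {
    stop("domain error: need informants from >= 2 ethnic groups for '",
         species, "'", call. = FALSE)
  }
  kruskal_wallis(uvis)
}
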