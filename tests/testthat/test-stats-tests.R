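# independent O(n^2) midrank oracle: rank = (#smaller) + (#equal + 1) / 2
rank_oracle <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
}

# independent Spearman oracle: explicit Pearson formula on oracle ranks
spearman_oracle <- function(x, y) {
  rx <- rank_oracle(x)
  ry <- rank_oracle(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# independent tie-corrected H oracle from the textbook formula
kw_oracle <- function(groups) {
  values <- unlist(groups)
  n <- length(values)
  r <- rank_oracle(values)
  sizes <- lengths(groups)
  idx <- rep(seq_along(groups), sizes)
  rbar <- tapply(r, idx, mean)
  h <- 12 / (n * (n + 1)) * sum(sizes * rbar^2) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# independent recursive permutation enumerator (distinct code path from the
# package's matrix-based generator)
perm_recurse <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perm_recurse(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

test_that("average ranks agree with the comparison-counting oracle", {
  expect_equal(rank_with_ties(c(10, 20, 20, 30)), c(1, 2.5, 2.5, 4))
  expect_equal(rank_with_ties(rep(7, 5)), rep(3, 5))
  set.seed(42)
  for (i in 1:20) {
    x <- sample(1:6, 12, replace = TRUE)
    r <- rank_with_ties(x)
    expect_equal(r, rank_oracle(x))
    expect_equal(sum(r), 12 * 13 / 2)
  }
  expect_error(rank_with_ties(c(1, NA)), "finite")
  expect_error(rank_with_ties(c(1, Inf)), "finite")
})

test_that("Spearman rho matches the rank-Pearson oracle, ties included", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    x <- sample(1:5, n, replace = TRUE)
    y <- sample(1:5, n, replace = TRUE)
    if (sd(rank(x)) == 0 || sd(rank(y)) == 0) next
    expect_equal(spearman_rho(x, y)$statistic, spearman_oracle(x, y))
  }
  # perfectly monotone data
  expect_equal(spearman_rho(1:8, (1:8)^3)$statistic, 1)
  expect_equal(spearman_rho(1:8, -(1:8))$statistic, -1)
  expect_error(spearman_rho(1:2, 2:1), "n >= 3")
  expect_error(spearman_rho(c(1, 1, 1), 1:3), "zero rank variance")
})

test_that("Spearman is invariant under increasing transforms, antisymmetric under reversal", {
  set.seed(8)
  x <- rnorm(15)
  y <- rnorm(15)
  base <- spearman_rho(x, y)$statistic
  expect_equal(spearman_rho(exp(x), y)$statistic, base)
  expect_equal(spearman_rho(x, y^3 + 5 * y)$statistic, base)
  expect_equal(spearman_rho(x, -y)$statistic, -base)
})

test_that("exact permutation p equals full-enumeration oracle on tied 6-point data", {
  set.seed(9)
  x <- c(3, 1, 4, 1, 5, 2)
  y <- c(2, 7, 1, 8, 2, 8)
  res <- spearman_rho(x, y, p_method = "permutation", exact_max = 6)
  rho_obs <- spearman_oracle(x, y)
  rhos <- vapply(perm_recurse(seq_along(y)),
                 function(idx) spearman_oracle(x, y[idx]), numeric(1))
  p_oracle <- mean(abs(rhos) >= abs(rho_obs) - 1e-12)
  expect_equal(res$p_value, p_oracle)
  expect_equal(res$statistic, rho_obs)
})

test_that("asymptotic p is close to the permutation p on small samples", {
  set.seed(10)
  for (i in 1:5) {
    x <- rnorm(8)
    y <- 0.5 * x + rnorm(8)
    pa <- spearman_rho(x, y)$p_value
    pp <- spearman_rho(x, y, p_method = "permutation")$p_value
    expect_lt(abs(pa - pp), 0.12)
  }
})

test_that("Kruskal-Wallis reproduces the hand-computed H and handles ties", {
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  # rank sums 6 and 15: H = 12/(6*7) * (36/3 + 225/3) - 3*7 = 27/7
  expect_equal(res$statistic, 27 / 7)
  expect_equal(round_display(res$statistic, 2), 3.86)
  expect_equal(res$df, 1)
  set.seed(11)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j) sample(1:4, sample(3:6, 1),
                                                    replace = TRUE))
    if (length(unique(unlist(groups))) == 1) next
    expect_equal(kruskal_wallis(groups)$statistic, kw_oracle(groups))
  }
})

test_that("Kruskal-Wallis degenerate and error cases", {
  res <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric())), "empty group")
  expect_error(kruskal_wallis(list(1, 2)), "total n >= 3")
})

test_that("two-group Kruskal-Wallis equals the tie-corrected Mann-Whitney chi-square", {
  set.seed(12)
  for (i in 1:10) {
    a <- sample(1:5, 7, replace = TRUE)
    b <- sample(2:6, 9, replace = TRUE)
    n1 <- length(a); n2 <- length(b); n <- n1 + n2
    r <- rank_oracle(c(a, b))
    u <- sum(r[1:n1]) - n1 * (n1 + 1) / 2
    ties <- table(c(a, b))
    var_u <- n1 * n2 / (n * (n - 1)) * ((n^3 - n - sum(ties^3 - ties)) / 12)
    z2 <- (u - n1 * n2 / 2)^2 / var_u
    expect_equal(kruskal_wallis(list(a, b))$statistic, z2)
  }
})

test_that("chi-square p is within Monte-Carlo error of a permutation p", {
  set.seed(13)
  groups <- list(c(1, 3, 2, 5), c(4, 6, 2), c(7, 3, 5))
  res <- kruskal_wallis(groups)
  values <- unlist(groups)
  sizes <- lengths(groups)
  n_perm <- 4000
  h_perm <- replicate(n_perm, {
    v <- sample(values)
    kw_oracle(split(v, rep(seq_along(sizes), sizes)))
  })
  p_perm <- mean(h_perm >= res$statistic - 1e-12)
  expect_lt(abs(res$p_value - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / n_perm) + 0.05)
})

test_that("paired t matches its closed form", {
  a <- c(2, 3, 4, 6)
  b <- c(1, 2, 3, 3) # d = 1, 1, 1, 3: mean 1.5, sd 1
  res <- paired_t(a, b)
  expect_equal(res$statistic, 1.5 / (1 / sqrt(4)))
  expect_equal(res$statistic, 3)
  expect_equal(res$df, 3)
  expect_equal(res$p_value, 2 * pt(-3, df = 3))
  same <- paired_t(1:5, 1:5)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(paired_t(c(1, 2), c(0, 1)), "zero variance")
  expect_error(paired_t(1, 2), "n >= 2")
})

test_that("all reported p-values lie in [0, 1]", {
  set.seed(14)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(6)
    expect_true(dplyr::between(spearman_rho(x, y)$p_value, 0, 1))
    expect_true(dplyr::between(
      spearman_rho(x, y, p_method = "permutation")$p_value, 0, 1))
    g <- list(rnorm(4), rnorm(5))
    expect_true(dplyr::between(kruskal_wallis(g)$p_value, 0, 1))
  }
})

test_that("RAH test joins on group labels and applies the directional rule", {
  uv <- c(A = 0.1, B = 0.2, C = 0.3, D = 0.15, E = 0.25)
  ni <- c(A = 50, B = 90, C = 120, D = 70, E = 100, F = 999)
  expect_warning(res <- rah_test(uv, ni), "dropped group.*F")
  expect_equal(nrow(res$paired_groups), 5)
  expect_equal(res$test$n, 5)
  expect_equal(res$support, "supported") # perfectly concordant, rho = 1
  expect_equal(res$test$statistic, 1)
  # negative association is never "support", however significant
  neg <- suppressWarnings(rah_test(uv, -ni[names(uv)]))
  expect_equal(neg$test$statistic, -1)
  expect_equal(neg$support, "not supported")
  expect_error(rah_test(uv[1:2], ni[1:2]), ">= 3 groups")
  expect_error(rah_test(uv, ni, alpha = 1.5), "alpha")
  # NA on either side drops the group
  uv_na <- uv; uv_na["C"] <- NA
  expect_warning(res2 <- rah_test(uv_na, ni), "dropped group")
  expect_equal(res2$test$n, 4)
})

test_that("cross-cultural test runs KW on per-informant use values by group", {
  sim <- generate_survey(synthetic_config(n_groups = 3,
                                          informants_per_group = 15,
                                          seed = 21))
  d <- sim$interviews
  res <- crosscultural_test(d, d$species_list)
  expect_equal(res$method, "Kruskal-Wallis rank sum test")
  expect_equal(res$df, 2)
  expect_equal(res$n, 45)
  # single group is a domain error
  one <- subset_interviews(d, ethnic_group = "group_01")
  expect_error(crosscultural_test(one, d$species_list), ">= 2 ethnic groups")
  # two informants total (one per group) is a sample-size error
  two <- d
  two$informants <- d$informants[c(1, 16), ]
  two$use_reports <- d$use_reports[d$use_reports$informant_id %in%
                                     two$informants$informant_id, ]
  two$responses <- d$responses[d$responses$informant_id %in%
                                 two$informants$informant_id, ]
  expect_error(crosscultural_test(two, d$species_list), "total n >= 3")
})

test_that("cross-cultural test detects a strongly shifted group", {
  cfg <- synthetic_config(
    n_groups = 3, informants_per_group = 25, coupling_beta = 0,
    baseline_alpha = log(2), seed = 22
  )
  sim <- generate_survey(cfg)
  d <- sim$interviews
  # shift group_03 upward by tripling its citations' presence: append extra
  # reports for each of its informants
  extra <- d$use_reports[0, ]
  ids <- d$informants$informant_id[d$informants$ethnic_group == "group_03"]
  for (i in ids) {
    extra <- dplyr::bind_rows(extra, tibble::tibble(
      informant_id = i, species = d$species_list, organ = "rootstock",
      category = "medicinal",
      specific_use = paste0("shift_", i, "_", 1:6),
      affection_category = NA_character_
    ))
  }
  d$use_reports <- dplyr::bind_rows(d$use_reports, extra)
  validate_interviews(d)
  expect_lt(crosscultural_test(d, d$species_list)$p_value, 0.01)
})
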