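#' Configuration for the synthetic survey generator
#'
#' Bundles and validates every parameter of [generate_survey()]. The
#' defaults emulate the scale and structure of the countrywide Benin
#' *Cochlospermum* survey: 27 ethnic groups of 28 informants (756 Dialog
#' Partners), one sampled site per group with 4 one-hectare plots
#' (~100 plots over 27 areas), site abundances spanning the printed
#' per-group densities (about 40-215 tufts/ha), a lexicon of 83 distinct
#' specific uses, and category/organ weights dominated by medicinal uses of
#' the rootstock.
#'
#' Abundance enters citation behaviour through a log link: informants of
#' group `g` cite `K_i ~ Poisson(mu_g)` distinct uses with
#' `log(mu_g) = baseline_alpha + coupling_beta * z(lambda_g)`, where
#' `z` standardizes the group abundances. `coupling_beta = 0` decouples use
#' from abundance (the null of the resource availability hypothesis);
#' positive values make more abundant sites more-cited, with recoverable
#' strength.
#'
#' @param n_groups Number of ethnic groups.
#' @param informants_per_group Scalar or per-group integer vector.
#' @param lambda_range `(min, max)` tufts/ha for the uniform site-abundance
#'   draw.
#' @param plots_per_site Plots censused per site.
#' @param plot_area Plot area in hectares.
#' @param coupling_beta Log-linear effect of standardized abundance on
#'   citation intensity.
#' @param baseline_alpha Log mean citation count at average abundance.
#' @param category_weights Named simplex over the use categories (default:
#'   medicinal-dominated), or a per-group list of such vectors.
#' @param organ_weights Named simplex over the organs (default:
#'   rootstock-dominated).
#' @param seller_prob Scalar or per-group probability of answering "yes" to
#'   selling.
#' @param use_lexicon_size Number of distinct specific uses in the synthetic
#'   lexicon.
#' @param species Species label stamped on the synthetic records.
#' @param seed Integer seed; the generator uses one RNG stream with a fixed
#'   draw order, so a seed fully determines the output.
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_groups = 27,
                             informants_per_group = 28,
                             lambda_range = c(40, 215),
                             plots_per_site = 4,
                             plot_area = 1,
                             coupling_beta = 0.5,
                             baseline_alpha = log(2),
                             category_weights = NULL,
                             organ_weights = NULL,
                             seller_prob = 0.5,
                             use_lexicon_size = 83,
                             species = "Cochlospermum synth",
                             seed = 1L) {
  voc <- default_vocabulary()
  if (is.null(category_weights)) {
    category_weights <- c(
      medicinal = 0.40, food = 0.18, handicraft = 0.10, construction = 0.06,
      fodder = 0.06, dye = 0.08, magic = 0.03, fuel = 0.02,
      veterinary = 0.04, cosmetic = 0.03
    )
  }
  if (is.null(organ_weights)) {
    organ_weights <- c(
      "rootstock" = 0.50, "root bark" = 0.07, "leaf" = 0.12, "stem" = 0.05,
      "stem bark" = 0.06, "fruit" = 0.06, "fiber" = 0.03, "flower" = 0.04,
      "seed" = 0.07
    )
  }
  cfg <- structure(
    list(
      n_groups = as.integer(n_groups),
      informants_per_group = rep_len(as.integer(informants_per_group), n_groups),
      lambda_range = as.numeric(lambda_range),
      plots_per_site = as.integer(plots_per_site),
      plot_area = as.numeric(plot_area),
      coupling_beta = as.numeric(coupling_beta),
      baseline_alpha = as.numeric(baseline_alpha),
      category_weights = category_weights,
      organ_weights = organ_weights,
      seller_prob = rep_len(as.numeric(seller_prob), n_groups),
      use_lexicon_size = as.integer(use_lexicon_size),
      species = species,
      seed = as.integer(seed),
      vocabulary = voc
    ),
    class = "synthetic_config"
  )
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  voc <- cfg$vocabulary
  if (cfg$n_groups < 1) stop("config error: n_groups >= 1", call. = FALSE)
  if (any(cfg$informants_per_group < 1)) {
    stop("config error: informants_per_group >= 1", call. = FALSE)
  }
  if (length(cfg$lambda_range) != 2 || cfg$lambda_range[1] > cfg$lambda_range[2] ||
      any(cfg$lambda_range < 0)) {
    stop("config error: lambda_range must be 0 <= min <= max", call. = FALSE)
  }
  if (cfg$plots_per_site < 1 || cfg$plot_area <= 0) {
    stop("config error: need plots_per_site >= 1 and plot_area > 0",
         call. = FALSE)
  }
  check_simplex <- function(w, labels, what) {
    if (!setequal(names(w), labels)) {
      stop("config error: ", what, " must be named over the full vocabulary",
           call. = FALSE)
    }
    if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
      stop("config error: ", what, " must be a simplex (sum to 1)",
           call. = FALSE)
    }
  }
  cw <- cfg$category_weights
  if (is.list(cw)) {
    lapply(cw, check_simplex, labels = voc$categories,
           what = "category_weights")
  } else {
    check_simplex(cw, voc$categories, "category_weights")
  }
  check_simplex(cfg$organ_weights, voc$organs, "organ_weights")
  if (any(cfg$seller_prob < 0 | cfg$seller_prob > 1)) {
    stop("config error: seller_prob in [0, 1]", call. = FALSE)
  }
  # Poisson support is unbounded; require that the upper tail of the
  # citation-count distribution fits the lexicon (uses are sampled without
  # replacement)
  z_max <- if (cfg$n_groups > 1) 2 else 0 # |z| rarely exceeds 2 across groups
  mu_max <- exp(cfg$baseline_alpha + abs(cfg$coupling_beta) * z_max)
  if (stats::qpois(1 - 1e-9, mu_max) > cfg$use_lexicon_size) {
    stop("config error: citation-count support exceeds use_lexicon_size; ",
         "raise use_lexicon_size or lower baseline_alpha/coupling_beta",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Generate a synthetic interview survey and plot census
#'
#' Draws a full survey under the model described in [synthetic_config()].
#' One RNG stream with a fixed, documented draw order (group abundances;
#' plot counts; then per group: informant covariates, citation counts, each
#' informant's uses, the organ and category assignments for the group's
#' reports, the seller flags and the remaining response answers), so a seed
#' plus a config determines the output exactly — there is no way to
#' regenerate one part in isolation.
#'
#' @param config A [synthetic_config()].
#' @return A list: `interviews` (a validated [interview_set()]), `census`
#'   (plot-census tibble, see [read_census()]), `truth` (tibble `group`,
#'   `lambda` true site abundance, `mu` true mean citation count).
#' @export
#' @examples
#' sim <- generate_survey(synthetic_config(n_groups = 4,
#'                                         informants_per_group = 5,
#'                                         seed = 42))
#' sim$truth
generate_survey <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  voc <- cfg$vocabulary
  set.seed(cfg$seed)

  groups <- sprintf("group_%02d", seq_len(cfg$n_groups))
  zones <- c("Sudanian", "Sudano-Guinean", "Guineo-Congolian")
  group_zone <- zones[((seq_len(cfg$n_groups) - 1) %% 3) + 1]
  sites <- sprintf("site_%02d", seq_len(cfg$n_groups))
  lexicon <- sprintf("use_%03d", seq_len(cfg$use_lexicon_size))

  # 1) site abundances
  lambda <- stats::runif(cfg$n_groups, cfg$lambda_range[1], cfg$lambda_range[2])
  z <- if (cfg$n_groups > 1 && sd(lambda) > 0) {
    (lambda - mean(lambda)) / sd(lambda)
  } else {
    rep(0, cfg$n_groups)
  }
  mu <- exp(cfg$baseline_alpha + cfg$coupling_beta * z)

  # 2) plot census
  counts <- stats::rpois(cfg$n_groups * cfg$plots_per_site,
                         rep(lambda, each = cfg$plots_per_site) * cfg$plot_area)
  census <- tibble::tibble(
    plot_id = sprintf("%s_p%02d", rep(sites, each = cfg$plots_per_site),
                      rep(seq_len(cfg$plots_per_site), cfg$n_groups)),
    site = rep(sites, each = cfg$plots_per_site),
    zone = rep(group_zone, each = cfg$plots_per_site),
    species = cfg$species,
    n_individuals = as.integer(counts),
    area_ha = cfg$plot_area
  )

  # 3) interviews, group by group
  cat_w <- cfg$category_weights
  informants <- vector("list", cfg$n_groups)
  reports <- vector("list", cfg$n_groups)
  responses <- vector("list", cfg$n_groups)
  for (g in seq_len(cfg$n_groups)) {
    n_i <- cfg$informants_per_group[g]
    ids <- sprintf("%s_i%03d", groups[g], seq_len(n_i))
    informants[[g]] <- tibble::tibble(
      informant_id = ids,
      ethnic_group = groups[g],
      municipality = sites[g],
      zone = group_zone[g],
      sex = sample(c("m", "f"), n_i, replace = TRUE),
      age = sample(17:92, n_i, replace = TRUE),
      occupation = sample(
        c("farmer", "healer", "powder seller", "elder", "local leader"),
        n_i, replace = TRUE, prob = c(0.34, 0.29, 0.25, 0.08, 0.04)
      )
    )
    k <- pmin(stats::rpois(n_i, mu[g]), cfg$use_lexicon_size)
    w <- if (is.list(cat_w)) cat_w[[g]] else cat_w
    n_rep <- sum(k)
    uses <- unlist(lapply(k[k > 0], function(ki) sample(lexicon, ki)),
                   use.names = FALSE)
    reports[[g]] <- tibble::tibble(
      informant_id = rep(ids, k),
      species = cfg$species,
      organ = sample(names(cfg$organ_weights), n_rep, replace = TRUE,
                     prob = cfg$organ_weights),
      category = sample(names(w), n_rep, replace = TRUE, prob = w),
      specific_use = uses %||% character(),
      affection_category = NA_character_
    )
    responses[[g]] <- tibble::tibble(
      informant_id = ids,
      species = cfg$species,
      sells = stats::runif(n_i) < cfg$seller_prob[g],
      perceived_dynamic = sample(c("decrease", "stable"), n_i,
                                 replace = TRUE, prob = c(0.8, 0.2)),
      harvest_tool = sample(c("axe", "hoe", "machete"), n_i, replace = TRUE,
                            prob = c(0.51, 0.38, 0.11)),
      conservation_practice = sample(
        c("none", "partial harvest", "fallowing areas"), n_i,
        replace = TRUE, prob = c(0.85, 0.10, 0.05)
      ),
      knows_species = TRUE
    )
  }

  interviews <- interview_set(
    informants = dplyr::bind_rows(informants),
    use_reports = dplyr::bind_rows(reports),
    responses = dplyr::bind_rows(responses),
    species_list = cfg$species,
    vocabulary = voc
  )
  list(
    interviews = interviews,
    census = census,
    truth = tibble::tibble(group = groups, lambda = lambda, mu = mu)
  )
}

#' Recover group-level parameters from a (synthetic) survey
#'
#' Validation harness for the generator: computes the empirical per-group
#' use values and plot densities, their Spearman correlation (the RAH
#' estimate), and the empirical seller fractions, for comparison against the
#' generating truth.
#'
#' @param dataset An [interview_set()] with a single species.
#' @param census Plot-census tibble whose sites map 1:1 to the dataset's
#'   municipalities (as produced by [generate_survey()]).
#' @return A list: `uv_by_group`, `density_by_group`, `seller_frac` (named
#'   vectors), `rho_test` (an `"ethno_test"`, Spearman UV vs density).
#' @export
recover_parameters <- function(dataset, census) {
  stopifnot(inherits(dataset, "interview_set"),
            length(dataset$species_list) == 1)
  sp <- dataset$species_list
  inf <- dataset$informants
  groups <- sort(unique(inf$ethnic_group))
  uv <- vapply(groups, function(g) {
    species_use_value(dataset, sp, group = g)$uvs
  }, numeric(1))
  site_map <- dplyr::distinct(inf, site = .data$municipality,
                              group = .data$ethnic_group)
  dens_tab <- density_by_group(census, sp, site_to_group = site_map)
  dens <- setNames(dens_tab$Ni, dens_tab$group)[groups]
  sellers <- vapply(groups, function(g) {
    r <- subset_interviews(dataset, ethnic_group = g)$responses
    mean(r$sells %in% TRUE)
  }, numeric(1))
  list(
    uv_by_group = uv,
    density_by_group = dens,
    seller_frac = sellers,
    rho_test = spearman_rho(unname(uv), unname(dens[names(uv)]))
  )
}
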