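#' Per-plot density
#'
#' `Ni = ni / S`: tufts (individuals) per hectare from a fixed-area plot
#' count.
#'
#' @param n_individuals Tuft count(s), integer >= 0.
#' @param area Plot area(s) in hectares, > 0; default 1 (a 100 m x 100 m
#'   plot).
#' @return Density in tufts per hectare.
#' @export
#' @examples
#' plot_density(50, 0.5) # 100 tufts per hectare
plot_density <- function(n_individuals, area = 1) {
  if (any(area <= 0)) stop("domain error: plot area must be > 0", call. = FALSE)
  if (any(n_individuals < 0)) {
    stop("domain error: tuft count must be >= 0", call. = FALSE)
  }
  n_individuals / area
}

#' Site- or group-level density estimate
#'
#' Averages per-plot densities for one species over the plots in scope, and
#' also reports the pooled estimate (total tufts / total area). With
#' equal-area plots the two coincide; with unequal areas the pooled
#' estimator weights plots by area.
#'
#' @param census A plot-census data frame (see [read_census()]) with columns
#'   `plot_id`, `site`, `zone`, `species`, `n_individuals`, `area_ha`.
#' @param species Species label.
#' @param site,zone Optional scope filters.
#' @return A list of class `"density_estimate"`: `scope`, `species`,
#'   `Ni` (mean of per-plot densities), `Ni_pooled`, `n_plots`.
#' @export
site_density <- function(census, species, site = NULL, zone = NULL) {
  cen <- census[census$species == species, ]
  scope <- "all"
  if (!is.null(site)) {
    cen <- cen[cen$site %in% site, ]
    scope <- paste(site, collapse = "+")
  }
  if (!is.null(zone)) {
    cen <- cen[cen$zone %in% zone, ]
    scope <- paste(c(scope[scope != "all"], zone), collapse = "+")
  }
  if (nrow(cen) == 0) {
    stop("undefined density: no plot for '", species, "' in scope ", scope,
         call. = FALSE)
  }
  structure(
    list(
      scope = scope, species = species,
      Ni = mean(plot_density(cen$n_individuals, cen$area_ha)),
      Ni_pooled = sum(cen$n_individuals) / sum(cen$area_ha),
      n_plots = nrow(cen)
    ),
    class = "density_estimate"
  )
}

#' @export
print.density_estimate <- function(x, ...) {
  cat("<density_estimate> ", x$species, " [", x$scope, "]: ",
      format(x$Ni, digits = 4), " tufts/ha over ", x$n_plots, " plot(s)",
      " (pooled ", format(x$Ni_pooled, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Density per site (or per site-mapped ethnic group)
#'
#' @param census Plot-census data frame.
#' @param species Species label.
#' @param site_to_group Optional data frame `site`, `group` mapping sampled
#'   areas to ethnic groups (the mapping is survey metadata, supplied
#'   explicitly, never inferred).
#' @return Tibble with columns `group` (site label or mapped group), `Ni`
#'   (mean of per-plot densities), `Ni_pooled`, `n_plots`.
#' @export
density_by_group <- function(census, species, site_to_group = NULL) {
  cen <- census[census$species == species, ]
  if (nrow(cen) == 0) {
    stop("undefined density: no plot for '", species, "'", call. = FALSE)
  }
  if (!is.null(site_to_group)) {
    stopifnot(all(c("site", "group") %in% names(site_to_group)))
    cen <- dplyr::inner_join(cen, site_to_group, by = "site")
  } else {
    cen$group <- cen$site
  }
  cen$dens <- plot_density(cen$n_individuals, cen$area_ha)
  dplyr::summarise(
    dplyr::group_by(cen, .data$group),
    Ni = mean(.data$dens),
    Ni_pooled = sum(.data$n_individuals) / sum(.data$area_ha),
    n_plots = dplyr::n(),
    .groups = "drop"
  )
}

#' Read / write a plot census
#'
#' CSV schema: `plot_id`, `site`, `zone`, `species`, `n_individuals`,
#' `area_ha`. Counts must be non-negative integers and areas strictly
#' positive; violations are validation errors. `write_census()` emits the
#' canonical column order, sorted, `NA` spelled out, so equal censuses
#' serialize identically and round-trip through `read_census()`.
#'
#' @param path CSV path.
#' @return `read_census()`: a validated tibble; `write_census()`: `path`,
#'   invisibly.
#' @export
read_census <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cen <- readr::read_csv(
    path,
    col_types = readr::cols(
      plot_id = readr::col_character(), site = readr::col_character(),
      zone = readr::col_character(), species = readr::col_character(),
      n_individuals = readr::col_integer(), area_ha = readr::col_double()
    ),
    na = "NA", locale = readr::locale(encoding = "UTF-8"),
    progress = FALSE, show_col_types = FALSE
  )
  validate_census(cen)
  cen
}

#' @rdname read_census
#' @param census Census data frame.
#' @export
write_census <- function(census, path) {
  validate_census(census)
  cols <- c("plot_id", "site", "zone", "species", "n_individuals", "area_ha")
  cen <- dplyr::arrange(census[, cols], .data$plot_id, .data$species)
  readr::write_csv(cen, path, na = "NA", progress = FALSE)
  invisible(path)
}

validate_census <- function(census) {
  need <- c("plot_id", "site", "zone", "species", "n_individuals", "area_ha")
  miss <- setdiff(need, names(census))
  if (length(miss)) {
    stop("schema error: census is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(census$n_individuals) | census$n_individuals < 0)) {
    stop("validation error: n_individuals must be a non-negative count",
         call. = FALSE)
  }
  if (any(is.na(census$area_ha) | census$area_ha <= 0)) {
    stop("validation error: area_ha must be > 0", call. = FALSE)
  }
  key <- paste(census$plot_id, census$species, sep = "\r")
  if (anyDuplicated(key)) {
    stop("validation error: duplicated plot_id x species row(s)", call. = FALSE)
  }
  invisible(census)
}
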