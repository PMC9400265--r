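#' Per-ethnic-group index table
#'
#' Assembles, for one species, the table of indices reported per ethnic
#' group in quantitative-ethnobotany surveys: use value with its standard
#' deviation, per-category use values, index of commercial value, and local
#' density joined from a plot census. A final means row holds the
#' *unweighted* mean over the group rows (each ethnic group counts once,
#' regardless of its sample size), which is how published survey tables
#' summarize their body rows.
#'
#' @param dataset An [interview_set()].
#' @param species Species label.
#' @param densities Named numeric vector (or two-column data frame
#'   `group`, `Ni`) of tufts per hectare per ethnic group. Groups without a
#'   density get `NA` with a warning.
#' @param uv_normalizer,sd_type Passed to [species_use_value()].
#' @param uvc_scale Passed to [category_use_value()].
#' @return A tibble of class `"group_index_table"` with columns `species`,
#'   `ethnic_group`, `row_type` (`"group"`/`"means"`), `n_informants`, `UV`,
#'   `UV_sd`, one `UVc_<category>` column per vocabulary category, `ICV`,
#'   `Ni`.
#' @export
build_group_index_table <- function(dataset, species, densities = NULL,
                                    uv_normalizer = c("none", "lexicon"),
                                    sd_type = c("sample", "population"),
                                    uvc_scale = 1) {
  stopifnot(inherits(dataset, "interview_set"))
  uv_normalizer <- match.arg(uv_normalizer)
  sd_type <- match.arg(sd_type)
  dens <- normalize_density_map(densities)

  groups <- sort(unique(dataset$informants$ethnic_group))
  groups <- groups[vapply(groups, function(g) {
    r <- dataset$responses
    ids <- dataset$informants$informant_id[dataset$informants$ethnic_group == g]
    any(r$informant_id %in% ids & r$species == species &
          r$knows_species %in% TRUE)
  }, logical(1))]
  if (length(groups) == 0) {
    return(empty_group_table(dataset$vocabulary))
  }

  rows <- purrr::map(groups, function(g) {
    uv <- species_use_value(dataset, species, group = g,
                            sd_type = sd_type, uv_normalizer = uv_normalizer)
    uvc <- category_use_value(dataset, species, group = g, scale = uvc_scale)
    icv <- commercial_value(dataset, species, group = g)
    ni <- if (g %in% names(dens)) dens[[g]] else NA_real_
    tibble::tibble(
      species = species, ethnic_group = g, row_type = "group",
      n_informants = uv$ns, UV = uv$uvs, UV_sd = uv$sd,
      !!!setNames(as.list(uvc), paste0("UVc_", names(uvc))),
      ICV = icv, Ni = ni
    )
  })
  tab <- dplyr::bind_rows(rows)
  missing_dens <- tab$ethnic_group[is.na(tab$Ni)]
  if (!is.null(densities) && length(missing_dens)) {
    warning("no density supplied for group(s): ",
            paste(missing_dens, collapse = ", "), call. = FALSE)
  }
  tab <- add_means_row(tab)
  class(tab) <- c("group_index_table", class(tab))
  tab
}

normalize_density_map <- function(densities) {
  if (is.null(densities)) return(numeric())
  if (is.data.frame(densities)) {
    stopifnot(all(c("group", "Ni") %in% names(densities)))
    return(setNames(densities$Ni, densities$group))
  }
  stopifnot(!is.null(names(densities)))
  densities
}

empty_group_table <- function(vocabulary) {
  tab <- tibble::tibble(
    species = character(), ethnic_group = character(), row_type = character(),
    n_informants = integer(), UV = numeric(), UV_sd = numeric(),
    !!!setNames(rep(list(numeric()), length(vocabulary$categories)),
                paste0("UVc_", vocabulary$categories)),
    ICV = numeric(), Ni = numeric()
  )
  class(tab) <- c("group_index_table", class(tab))
  tab
}

add_means_row <- function(tab) {
  body <- tab[tab$row_type == "group", ]
  if (nrow(body) == 0) return(tab)
  num_cols <- setdiff(names(tab)[vapply(tab, is.numeric, logical(1))],
                      "n_informants")
  means <- tibble::tibble(
    species = body$species[[1]], ethnic_group = "Means", row_type = "means",
    n_informants = NA_integer_
  )
  for (col in num_cols) {
    v <- body[[col]]
    means[[col]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  dplyr::bind_rows(body, means)
}

#' Unweighted column mean over the group rows of an index table
#'
#' The published tables' "Means ± sd" row is the unweighted arithmetic mean
#' over the ethnic-group rows (missing entries dropped); rounding to the
#' printed precision (2 dp for UV and ICV, whole tufts for Ni) is applied at
#' display only.
#'
#' @param table A `"group_index_table"` (or any data frame with a
#'   `row_type` column).
#' @param column Column name to summarize.
#' @return The unrounded mean over non-missing group-row entries.
#' @export
summarize_column <- function(table, column) {
  if (!column %in% names(table)) {
    stop("schema error: no column '", column, "'", call. = FALSE)
  }
  body <- table[table$row_type == "group", ]
  v <- body[[column]]
  if (!is.numeric(v)) stop("column '", column, "' is not numeric", call. = FALSE)
  if (all(is.na(v))) stop("column '", column, "' is all-missing", call. = FALSE)
  mean(v, na.rm = TRUE)
}

#' Read a pre-aggregated group index table
#'
#' Loads a table of per-ethnic-group summary values (columns
#' `ethnic_group`, `UV`, `UV_sd`, `Ni`, `ICV`, optional `UVc_*`) such as the
#' packaged transcriptions of the published *Cochlospermum* survey tables,
#' and appends the unweighted means row. Lines starting with `#` are
#' comments.
#'
#' @param path CSV path.
#' @param species Species label to stamp on the rows; defaults to the file's
#'   `species` column if present.
#' @return A `"group_index_table"` tibble.
#' @export
#' @examples
#' t5 <- read_group_table(
#'   system.file("extdata", "table5_tinctorium.csv", package = "usevalue")
#' )
#' round(summarize_column(t5, "Ni")) # 97 tufts per hectare
read_group_table <- function(path, species = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, comment = "#", na = "NA",
                         locale = readr::locale(encoding = "UTF-8"),
                         progress = FALSE, show_col_types = FALSE)
  if (!"ethnic_group" %in% names(raw)) {
    stop("schema error: missing mandatory column: ethnic_group", call. = FALSE)
  }
  if (is.null(species)) {
    species <- if ("species" %in% names(raw)) raw$species[[1]] else NA_character_
  }
  raw$species <- species
  raw$row_type <- "group"
  if (!"n_informants" %in% names(raw)) raw$n_informants <- NA_integer_
  front <- c("species", "ethnic_group", "row_type", "n_informants")
  raw <- raw[, c(front, setdiff(names(raw), front))]
  tab <- add_means_row(raw)
  class(tab) <- c("group_index_table", class(tab))
  tab
}

#' Write a group index table to TSV
#'
#' @param table A `"group_index_table"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_group_table <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path, na = "NA", progress = FALSE)
  invisible(path)
}
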