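#' @importFrom rlang %||% .data
#' @importFrom stats sd setNames cor
#' @importFrom utils head
NULL

# canonical on-disk column order for the long interview CSV
INTERVIEW_COLUMNS <- c(
  "informant_id", "ethnic_group", "municipality", "zone", "sex", "age",
  "occupation", "species", "organ", "category", "specific_use",
  "affection_category", "sells", "perceived_dynamic", "harvest_tool",
  "conservation_practice", "knows_species"
)

DYNAMIC_LEVELS <- c("increase", "decrease", "stable")
TOOL_LEVELS <- c("axe", "hoe", "machete")
PRACTICE_LEVELS <- c(
  "seeding", "assisted natural regeneration", "partial harvest",
  "fallowing areas", "weeding protection", "none"
)

#' Construct a validated interview record set
#'
#' The central container of the package: a long-format ethnobotanical survey
#' split into three linked tables. `informants` carries one row per Dialog
#' Partner with sociodemographic covariates; `use_reports` one row per
#' informant x species x organ x category x specific-use citation;
#' `responses` one row per informant x species with the closed-ended answers
#' (selling, perceived abundance dynamic, harvesting tool, conservation
#' practice, and whether the informant knows the species at all).
#'
#' Validation enforces referential integrity (every use report and response
#' resolves to an informant), controlled vocabularies for `organ` and
#' `category`, uniqueness of informant ids and of use reports (duplicate
#' citations are rejected, not deduplicated, so that index denominators stay
#' auditable), and that every cited species appears in `species_list`.
#'
#' @param informants Data frame with columns `informant_id`, `ethnic_group`,
#'   `municipality`, `zone`, `sex`, `age`, `occupation`.
#' @param use_reports Data frame with columns `informant_id`, `species`,
#'   `organ`, `category`, `specific_use`, `affection_category`.
#' @param responses Data frame with columns `informant_id`, `species`,
#'   `sells`, `perceived_dynamic`, `harvest_tool`, `conservation_practice`,
#'   `knows_species`.
#' @param species_list Character vector of species labels covered by the
#'   survey; defaults to the species present in `use_reports`/`responses`.
#' @param vocabulary An `"ethno_vocabulary"`, see [default_vocabulary()].
#' @return An object of class `"interview_set"`: a list with elements
#'   `informants`, `use_reports`, `responses` (tibbles), `species_list` and
#'   `vocabulary`.
#' @export
#' @examples
#' d <- interview_set(
#'   informants = data.frame(
#'     informant_id = c("i1", "i2"), ethnic_group = "Mokolé",
#'     municipality = "Kandi", zone = "Sudanian", sex = "f", age = 40L,
#'     occupation = "farmer"
#'   ),
#'   use_reports = data.frame(
#'     informant_id = "i1", species = "C. tinctorium", organ = "rootstock",
#'     category = "medicinal", specific_use = "jaundice remedy",
#'     affection_category = "liver"
#'   ),
#'   responses = data.frame(
#'     informant_id = c("i1", "i2"), species = "C. tinctorium",
#'     sells = c(TRUE, FALSE), perceived_dynamic = c("decrease", NA),
#'     harvest_tool = c("axe", NA), conservation_practice = NA_character_,
#'     knows_species = TRUE
#'   )
#' )
#' n_informants(d)
interview_set <- function(informants, use_reports = NULL, responses = NULL,
                          species_list = NULL, vocabulary = default_vocabulary()) {
  informants <- tibble::as_tibble(informants)
  use_reports <- tibble::as_tibble(use_reports %||% empty_use_reports())
  responses <- tibble::as_tibble(responses %||% empty_responses())
  if (is.null(species_list)) {
    species_list <- sort(unique(c(use_reports$species, responses$species)))
  }
  out <- structure(
    list(
      informants = informants,
      use_reports = use_reports,
      responses = responses,
      species_list = as.character(species_list),
      vocabulary = vocabulary
    ),
    class = "interview_set"
  )
  validate_interviews(out)
  out
}

empty_use_reports <- function() {
  tibble::tibble(
    informant_id = character(), species = character(), organ = character(),
    category = character(), specific_use = character(),
    affection_category = character()
  )
}

empty_responses <- function() {
  tibble::tibble(
    informant_id = character(), species = character(), sells = logical(),
    perceived_dynamic = character(), harvest_tool = character(),
    conservation_practice = character(), knows_species = logical()
  )
}

#' Validate an interview record set
#'
#' Checks schema, uniqueness, referential integrity and vocabulary
#' membership; called by [interview_set()] and [read_interviews()]. Errors
#' name the offending column or list the offending rows.
#'
#' @param x An `"interview_set"`.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_interviews <- function(x) {
  stopifnot(inherits(x, "interview_set"))
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop("schema error: ", what, " is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  need(x$informants, setdiff(INTERVIEW_COLUMNS[1:7], NULL), "informants")
  need(x$use_reports, names(empty_use_reports()), "use_reports")
  need(x$responses, names(empty_responses()), "responses")

  inf <- x$informants
  if (anyDuplicated(inf$informant_id)) {
    stop("validation error: duplicated informant_id: ",
         paste(unique(inf$informant_id[duplicated(inf$informant_id)]),
               collapse = ", "), call. = FALSE)
  }
  for (col in c("ethnic_group", "zone")) {
    bad <- which(is.na(inf[[col]]) | !nzchar(inf[[col]]))
    if (length(bad)) {
      stop("validation error: empty ", col, " for informant(s): ",
           paste(inf$informant_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  if (any(!is.na(inf$age) & inf$age < 0)) {
    stop("validation error: negative age", call. = FALSE)
  }

  # referential integrity
  for (tab in c("use_reports", "responses")) {
    dangling <- setdiff(x[[tab]]$informant_id, inf$informant_id)
    if (length(dangling)) {
      stop("referential error: ", tab, " reference unknown informant_id: ",
           paste(dangling, collapse = ", "), call. = FALSE)
    }
  }
  unknown_sp <- setdiff(
    c(x$use_reports$species, x$responses$species), x$species_list
  )
  if (length(unknown_sp)) {
    stop("validation error: species not in species_list: ",
         paste(unknown_sp, collapse = ", "), call. = FALSE)
  }

  # vocabulary membership
  voc <- x$vocabulary
  bad_organ <- which(!x$use_reports$organ %in% voc$organs)
  if (length(bad_organ)) {
    stop("validation error: unknown organ label(s) at use-report row(s) ",
         paste(head(bad_organ, 10), collapse = ", "), ": ",
         paste(unique(x$use_reports$organ[bad_organ]), collapse = ", "),
         call. = FALSE)
  }
  bad_cat <- which(!x$use_reports$category %in% voc$categories)
  if (length(bad_cat)) {
    stop("validation error: unknown category label(s) at use-report row(s) ",
         paste(head(bad_cat, 10), collapse = ", "), ": ",
         paste(unique(x$use_reports$category[bad_cat]), collapse = ", "),
         call. = FALSE)
  }

  # duplicate citations are rejected so FC/UV denominators stay auditable
  key <- with(x$use_reports,
              paste(informant_id, species, organ, category, specific_use,
                    sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("validation error: duplicate use-report(s) at row(s): ",
         paste(head(dup, 10), collapse = ", "), call. = FALSE)
  }
  rkey <- with(x$responses, paste(informant_id, species, sep = "\r"))
  if (anyDuplicated(rkey)) {
    stop("validation error: more than one response record per ",
         "informant x species", call. = FALSE)
  }

  check_levels <- function(v, levels, what) {
    bad <- setdiff(v[!is.na(v)], levels)
    if (length(bad)) {
      stop("validation error: unknown ", what, " value(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  check_levels(x$responses$perceived_dynamic, DYNAMIC_LEVELS, "perceived_dynamic")
  check_levels(x$responses$harvest_tool, TOOL_LEVELS, "harvest_tool")
  check_levels(x$responses$conservation_practice, PRACTICE_LEVELS,
               "conservation_practice")

  # a use report implies the informant was interviewed for (and knows) the species
  ur_key <- unique(paste(x$use_reports$informant_id, x$use_reports$species,
                         sep = "\r"))
  known <- rkey[x$responses$knows_species %in% TRUE]
  orphans <- setdiff(ur_key, known)
  if (length(orphans)) {
    stop("validation error: use-report(s) without a knows_species = TRUE ",
         "response record: ",
         paste(head(gsub("\r", " / ", orphans), 5), collapse = "; "),
         call. = FALSE)
  }
  invisible(x)
}

#' @export
print.interview_set <- function(x, ...) {
  cat("<interview_set> ", nrow(x$informants), " informants, ",
      nrow(x$use_reports), " use-reports, ",
      length(x$species_list), " species\n", sep = "")
  grp <- table(x$informants$ethnic_group)
  cat("  ethnic groups (", length(grp), "): ",
      paste(head(names(grp), 8), collapse = ", "),
      if (length(grp) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Total number of informants (Nt)
#'
#' @param dataset An `"interview_set"`.
#' @return Integer count of informants in the dataset.
#' @export
n_informants <- function(dataset) {
  stopifnot(inherits(dataset, "interview_set"))
  nrow(dataset$informants)
}

#' Informants interviewed for a species (Ns)
#'
#' Counts informants with a response record for `species` and
#' `knows_species = TRUE`. Informants who do not know the species (it is
#' absent from their locality) are excluded from the denominator of that
#' species' use value but remain part of the dataset total.
#'
#' @param dataset An `"interview_set"`.
#' @param species Species label.
#' @return Integer count.
#' @export
n_interviewed <- function(dataset, species) {
  stopifnot(inherits(dataset, "interview_set"))
  r <- dataset$responses
  sum(r$species == species & r$knows_species %in% TRUE)
}

#' Read an interview survey from a long-format CSV
#'
#' Expects one row per use-report (citation), with informant covariates and
#' the closed-ended response fields repeated on every row for the same
#' informant x species; rows whose use fields (`organ`, `category`,
#' `specific_use`) are all missing carry a response (or a bare informant)
#' without citations. Files are read as UTF-8 — vernacular and ethnic-group
#' labels carry diacritics.
#'
#' @param path Path to a CSV file with the columns listed under
#'   [write_interviews()].
#' @param vocabulary Controlled vocabulary, see [default_vocabulary()].
#' @param delim Field delimiter, default `","`.
#' @return A validated [interview_set()].
#' @export
read_interviews <- function(path, vocabulary = default_vocabulary(),
                            delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- withCallingHandlers(
    readr::read_delim(
      path, delim = delim, col_types = interview_col_types(),
      na = "NA", locale = readr::locale(encoding = "UTF-8"),
      progress = FALSE, show_col_types = FALSE
    ),
    warning = function(w) {
      # a missing column becomes our own schema error below, not a readr
      # parser warning
      if (grepl("parsers don't match", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  miss <- setdiff(INTERVIEW_COLUMNS, names(raw))
  if (length(miss)) {
    stop("schema error: missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  informants <- dplyr::distinct(
    raw, .data$informant_id, .data$ethnic_group, .data$municipality,
    .data$zone, .data$sex, .data$age, .data$occupation
  )
  if (anyDuplicated(informants$informant_id)) {
    stop("validation error: inconsistent covariates across rows for ",
         "informant_id: ",
         paste(unique(informants$informant_id[
           duplicated(informants$informant_id)]), collapse = ", "),
         call. = FALSE)
  }
  has_sp <- !is.na(raw$species)
  responses <- dplyr::distinct(
    raw[has_sp, ], .data$informant_id, .data$species, .data$sells,
    .data$perceived_dynamic, .data$harvest_tool,
    .data$conservation_practice, .data$knows_species
  )
  rkey <- paste(responses$informant_id, responses$species, sep = "\r")
  if (anyDuplicated(rkey)) {
    stop("validation error: inconsistent response fields across rows for ",
         "informant x species: ",
         paste(unique(gsub("\r", " / ", rkey[duplicated(rkey)])),
               collapse = "; "), call. = FALSE)
  }
  is_report <- has_sp & !(is.na(raw$organ) & is.na(raw$category) &
                            is.na(raw$specific_use))
  use_reports <- raw[is_report, c("informant_id", "species", "organ",
                                  "category", "specific_use",
                                  "affection_category")]
  interview_set(
    informants = informants,
    use_reports = use_reports,
    responses = responses,
    vocabulary = vocabulary
  )
}

interview_col_types <- function() {
  readr::cols(
    informant_id = readr::col_character(),
    ethnic_group = readr::col_character(),
    municipality = readr::col_character(),
    zone = readr::col_character(),
    sex = readr::col_character(),
    age = readr::col_integer(),
    occupation = readr::col_character(),
    species = readr::col_character(),
    organ = readr::col_character(),
    category = readr::col_character(),
    specific_use = readr::col_character(),
    affection_category = readr::col_character(),
    sells = readr::col_logical(),
    perceived_dynamic = readr::col_character(),
    harvest_tool = readr::col_character(),
    conservation_practice = readr::col_character(),
    knows_species = readr::col_logical()
  )
}

#' Write an interview survey to its canonical long-format CSV
#'
#' Emits one row per use-report, one row per citation-free response, and one
#' row per informant without any response, in a canonical sort order so that
#' identical datasets serialize byte-identically. Missing values are written
#' as the literal `NA`, never as empty strings. The written file round-trips
#' through [read_interviews()] to an identical dataset.
#'
#' @param dataset A validated [interview_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interviews <- function(dataset, path) {
  stopifnot(inherits(dataset, "interview_set"))
  validate_interviews(dataset)
  ur <- dataset$use_reports
  resp <- dataset$responses
  # responses with no citation become use-field-NA rows
  ur_key <- paste(ur$informant_id, ur$species, sep = "\r")
  r_key <- paste(resp$informant_id, resp$species, sep = "\r")
  bare_resp <- resp[!(r_key %in% ur_key), c("informant_id", "species")]
  bare_resp$organ <- NA_character_
  bare_resp$category <- NA_character_
  bare_resp$specific_use <- NA_character_
  bare_resp$affection_category <- NA_character_
  long <- dplyr::bind_rows(ur, bare_resp)
  # informants with no responses at all still get one covariate row
  bare_inf <- setdiff(dataset$informants$informant_id, long$informant_id)
  if (length(bare_inf)) {
    long <- dplyr::bind_rows(
      long,
      tibble::tibble(informant_id = bare_inf, species = NA_character_,
                     organ = NA_character_, category = NA_character_,
                     specific_use = NA_character_,
                     affection_category = NA_character_)
    )
  }
  wide <- dplyr::left_join(long, dataset$informants, by = "informant_id")
  wide <- dplyr::left_join(wide, resp, by = c("informant_id", "species"))
  wide <- wide[, INTERVIEW_COLUMNS]
  wide <- dplyr::arrange(
    wide, .data$informant_id, .data$species, .data$organ, .data$category,
    .data$specific_use
  )
  readr::write_csv(wide, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Distinct-use and vernacular-name inventory for a two-species survey
#'
#' Counts distinct specific-use labels per species, the number shared by
#' both species, and the overall union; the union satisfies the two-set
#' inclusion-exclusion identity `union = a + b - common` by construction.
#' The same accounting applies to vernacular names when a name table is
#' supplied. For the Benin *Cochlospermum* survey this reproduces 83
#' distinct specific uses (57 + 61 - 35) and 36 vernacular names
#' (14 + 28 - 6).
#'
#' @param dataset An [interview_set()] with (for the shared counts) exactly
#'   two species.
#' @param names Optional data frame with columns `species` and `name`
#'   (vernacular names, one row per species x name).
#' @return A list of class `"use_inventory"`: `per_species_use_count`
#'   (named integer), `common_use_count`, `union_use_count`, and — when
#'   `names` is given — `per_species_name_count`, `common_name_count`,
#'   `union_name_count`.
#' @export
use_inventory <- function(dataset, names = NULL) {
  stopifnot(inherits(dataset, "interview_set"))
  ur <- dataset$use_reports
  sets <- split(ur$specific_use, factor(ur$species, levels = dataset$species_list))
  sets <- lapply(sets, unique)
  out <- inventory_counts(sets)
  names(out) <- paste0(sub("_count$", "_use_count", names(out)))
  if (!is.null(names)) {
    nsets <- split(names$name, factor(names$species,
                                      levels = unique(names$species)))
    nsets <- lapply(nsets, unique)
    nout <- inventory_counts(nsets)
    out$per_species_name_count <- nout$per_species_count
    out$common_name_count <- nout$common_count
    out$union_name_count <- nout$union_count
  }
  structure(out, class = "use_inventory")
}

inventory_counts <- function(sets) {
  per <- vapply(sets, length, integer(1))
  all_labels <- unique(unlist(sets, use.names = FALSE))
  union_n <- length(all_labels)
  common_n <- if (length(sets) == 2) {
    length(intersect(sets[[1]], sets[[2]]))
  } else {
    NA_integer_
  }
  list(per_species_count = per, common_count = common_n,
       union_count = union_n)
}

#' Inventory from printed per-species totals
#'
#' When only the published totals are available (per-species distinct counts
#' and the shared count), the union follows from inclusion-exclusion for two
#' sets: `union = a + b - common`.
#'
#' @param per_species Named or unnamed numeric vector of length 2: distinct
#'   labels recorded for each species.
#' @param common Number of labels shared by both species.
#' @return A `"use_inventory"` list with the same fields as
#'   [use_inventory()].
#' @export
#' @examples
#' inventory_from_counts(c(57, 61), 35)$union_use_count  # 83
#' inventory_from_counts(c(14, 28), 6)$union_use_count   # 36
inventory_from_counts <- function(per_species, common) {
  stopifnot(length(per_species) == 2, common >= 0,
            common <= min(per_species))
  structure(
    list(per_species_use_count = per_species,
         common_use_count = common,
         union_use_count = sum(per_species) - common),
    class = "use_inventory"
  )
}

#' @export
print.use_inventory <- function(x, ...) {
  cat("<use_inventory>\n")
  cat("  uses: per-species",
      paste(x$per_species_use_count, collapse = " / "),
      "| common", x$common_use_count, "| union", x$union_use_count, "\n")
  if (!is.null(x$union_name_count)) {
    cat("  names: per-species",
        paste(x$per_species_name_count, collapse = " / "),
        "| common", x$common_name_count, "| union", x$union_name_count, "\n")
  }
  invisible(x)
}

#' Referentially closed subset of a survey
#'
#' Subsets by ethnic group, zone and/or species; informants outside the
#' selection are dropped together with their reports and responses, so the
#' result validates on its own. Subsetting by every level of a partitioning
#' covariate (e.g. the three phytogeographic zones) yields subsets whose
#' informant counts sum to the parent's.
#'
#' @param dataset An [interview_set()].
#' @param ethnic_group,zone Optional labels to keep (informant filter).
#' @param species Optional species label to keep (report/response filter;
#'   informants are retained).
#' @return A validated [interview_set()].
#' @export
subset_interviews <- function(dataset, ethnic_group = NULL, zone = NULL,
                              species = NULL) {
  stopifnot(inherits(dataset, "interview_set"))
  inf <- dataset$informants
  for (arg in c("ethnic_group", "zone")) {
    val <- get(arg)
    if (!is.null(val)) {
      known <- unique(inf[[arg]])
      if (!all(val %in% known)) {
        stop("lookup error: unknown ", arg, ": ",
             paste(setdiff(val, known), collapse = ", "), call. = FALSE)
      }
      inf <- inf[inf[[arg]] %in% val, ]
    }
  }
  sp_list <- dataset$species_list
  if (!is.null(species)) {
    if (!all(species %in% sp_list)) {
      stop("lookup error: unknown species: ",
           paste(setdiff(species, sp_list), collapse = ", "), call. = FALSE)
    }
    sp_list <- species
  }
  keep_inf <- inf$informant_id
  ur <- dataset$use_reports
  ur <- ur[ur$informant_id %in% keep_inf & ur$species %in% sp_list, ]
  resp <- dataset$responses
  resp <- resp[resp$informant_id %in% keep_inf & resp$species %in% sp_list, ]
  interview_set(inf, ur, resp, species_list = sp_list,
                vocabulary = dataset$vocabulary)
}

#' Pivot use-reports to an informant x specific-use incidence matrix
#'
#' Convenience view for consensus-style analyses: one row per informant in
#' scope, one column per distinct (species, organ, category, specific-use)
#' combination, entries 0/1.
#'
#' @param dataset An [interview_set()].
#' @param species Optional species filter.
#' @return An integer matrix with informant ids as row names.
#' @export
incidence_matrix <- function(dataset, species = NULL) {
  stopifnot(inherits(dataset, "interview_set"))
  ur <- dataset$use_reports
  if (!is.null(species)) ur <- ur[ur$species %in% species, ]
  use_key <- paste(ur$species, ur$organ, ur$category, ur$specific_use,
                   sep = " | ")
  ids <- dataset$informants$informant_id
  mat <- matrix(0L, nrow = length(ids), ncol = length(unique(use_key)),
                dimnames = list(ids, sort(unique(use_key))))
  if (nrow(ur)) mat[cbind(ur$informant_id, use_key)] <- 1L
  mat
}
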