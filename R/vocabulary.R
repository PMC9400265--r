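#' Controlled vocabularies for interview surveys
#'
#' Ethnobotanical use-reports are coded against controlled vocabularies: a
#' set of use categories (medicinal, food, ...), a set of exploited plant
#' organs, and a set of affection (ailment) groups for medicinal citations.
#' `default_vocabulary()` returns the vocabulary used in the Benin
#' *Cochlospermum* survey this package was built around: 10 use categories,
#' 9 organs and 13 affection groups. Unknown labels in loaded data are
#' validation errors, never silently passed through.
#'
#' @return A list with class `"ethno_vocabulary"` and character elements
#'   `categories`, `organs`, `affections`.
#' @seealso [read_vocabulary()] to load a custom vocabulary from a YAML file.
#' @export
#' @examples
#' default_vocabulary()$organs
default_vocabulary <- function() {
  new_vocabulary(
    categories = c(
      "medicinal", "food", "handicraft", "construction", "fodder",
      "dye", "magic", "fuel", "veterinary", "cosmetic"
    ),
    organs = c(
      "rootstock", "root bark", "leaf", "stem", "stem bark",
      "fruit", "fiber", "flower", "seed"
    ),
    affections = c(
      "dermatology", "eye", "gynecology/andrology", "general health",
      "gastrointestinal", "infectious", "liver", "neurological",
      "respiratory", "skeleto-muscular", "urological", "unspecific",
      "vascular/blood"
    )
  )
}

new_vocabulary <- function(categories, organs, affections = character()) {
  for (v in list(categories, organs)) {
    if (!is.character(v) || length(v) == 0 || anyDuplicated(v) || any(!nzchar(v))) {
      stop("vocabulary lists must be non-empty character vectors without duplicates",
           call. = FALSE)
    }
  }
  structure(
    list(categories = categories, organs = organs,
         affections = as.character(affections)),
    class = "ethno_vocabulary"
  )
}

#' Read a controlled vocabulary from a YAML file
#'
#' The file must define `categories` and `organs` lists; an `affections`
#' list is optional. See `system.file("extdata", "vocabulary.yml",
#' package = "usevalue")` for the packaged default.
#'
#' @param path Path to a YAML file.
#' @return An `"ethno_vocabulary"` list, as [default_vocabulary()].
#' @export
read_vocabulary <- function(path) {
  if (!file.exists(path)) stop("vocabulary file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  for (field in c("categories", "organs")) {
    if (is.null(raw[[field]])) {
      stop("vocabulary file is missing the '", field, "' list: ", path, call. = FALSE)
    }
  }
  new_vocabulary(
    categories = unlist(raw$categories),
    organs = unlist(raw$organs),
    affections = unlist(raw$affections %||% character())
  )
}

#' @export
print.ethno_vocabulary <- function(x, ...) {
  cat("<ethno_vocabulary>\n")
  cat("  categories (", length(x$categories), "): ",
      paste(x$categories, collapse = ", "), "\n", sep = "")
  cat("  organs     (", length(x$organs), "): ",
      paste(x$organs, collapse = ", "), "\n", sep = "")
  if (length(x$affections)) {
    cat("  affections (", length(x$affections), "): ",
        paste(x$affections, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
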