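#' Citation frequency (FC)
#'
#' Percentage of informants giving a particular response:
#' `FC = 100 * Np / Nt`, with `Np` the number of informants citing the
#' response and `Nt` the total number of informants questioned. Returned
#' unrounded; presentation rounding is a display concern
#' (see [round_display()]).
#'
#' @param np Number of informants giving the response (0 <= np <= nt).
#' @param nt Total number of informants questioned (> 0).
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' citation_frequency(358, 756) # 47.35% of informants aged 36-50
citation_frequency <- function(np, nt) {
  if (any(nt <= 0)) stop("undefined denominator: Nt must be > 0", call. = FALSE)
  if (any(np < 0 | np > nt)) stop("Np must satisfy 0 <= Np <= Nt", call. = FALSE)
  100 * np / nt
}

#' Index of commercial value (ICV)
#'
#' `ICV = 100 * Ip / I`: the percentage of informants answering positively
#' to selling the species' products, out of all informants questioned.
#'
#' @param ip Number of informants selling (0 <= ip <= i).
#' @param i Total informants questioned (> 0).
#' @return Percentage in `[0, 100]`.
#' @export
commercial_value_index <- function(ip, i) {
  if (any(i <= 0)) stop("undefined denominator: I must be > 0", call. = FALSE)
  if (any(ip < 0 | ip > i)) stop("Ip must satisfy 0 <= Ip <= I", call. = FALSE)
  100 * ip / i
}

#' Commercial-importance classification
#'
#' A species is classed as commercially important for a group when its ICV
#' reaches the threshold (default 75%). The comparison is `>=` by default —
#' groups sitting exactly on, or within rounding of, the threshold (e.g. an
#' ICV of 75.97) are flagged; set `strict = TRUE` for a strict `>`.
#'
#' @param icv ICV percentage(s) in `[0, 100]`.
#' @param threshold Classification threshold in percent, default 75.
#' @param strict Use strict `>` instead of `>=`.
#' @return Logical vector.
#' @export
flag_commercially_important <- function(icv, threshold = 75, strict = FALSE) {
  if (any(icv < 0 | icv > 100, na.rm = TRUE)) {
    stop("icv must lie in [0, 100]", call. = FALSE)
  }
  if (strict) icv > threshold else icv >= threshold
}

#' Per-informant use value (UVis)
#'
#' The number of distinct uses an informant cited for a species, divided by
#' the number of interview events for that informant (a single survey round
#' here, so the default divisor is 1 and UVis is simply the citation count).
#' Two citations of the same specific use on different organs are distinct
#' use-reports.
#'
#' @param dataset An [interview_set()].
#' @param informant Informant id.
#' @param species Species label.
#' @param events Number of interview events for the informant, default 1.
#' @return Non-negative numeric.
#' @export
informant_use_value <- function(dataset, informant, species, events = 1) {
  stopifnot(inherits(dataset, "interview_set"), events > 0)
  if (!informant %in% dataset$informants$informant_id) {
    stop("lookup error: unknown informant: ", informant, call. = FALSE)
  }
  ur <- dataset$use_reports
  n <- sum(ur$informant_id == informant & ur$species == species)
  n / events
}

# per-informant citation counts over the informants in scope who know the
# species; informants citing nothing contribute 0
uvis_vector <- function(dataset, species, group = NULL) {
  d <- if (is.null(group)) dataset else {
    subset_interviews(dataset, ethnic_group = group)
  }
  r <- d$responses
  scope_ids <- r$informant_id[r$species == species & r$knows_species %in% TRUE]
  ur <- d$use_reports
  ur <- ur[ur$species == species & ur$informant_id %in% scope_ids, ]
  counts <- table(factor(ur$informant_id, levels = scope_ids))
  setNames(as.numeric(counts), scope_ids)
}

#' Species use value (UVs)
#'
#' The mean per-informant use value over the `Ns` informants interviewed for
#' the species within the scope (whole dataset or one ethnic group):
#' `UVs = sum(UVis) / Ns`. Informants who know the species but cited no use
#' contribute zero; informants who do not know the species are excluded from
#' `Ns`. Optionally the per-informant counts are divided by a global
#' normalizer (`uv_normalizer = "lexicon"` divides by the number of distinct
#' specific uses recorded for the species study-wide), which rescales UV
#' without affecting group rankings.
#'
#' @param dataset An [interview_set()].
#' @param species Species label.
#' @param group Optional ethnic-group scope.
#' @param sd_type `"sample"` (n-1, default) or `"population"` standard
#'   deviation of UVis over informants.
#' @param uv_normalizer `"none"` (default) or `"lexicon"`.
#' @return A list of class `"use_value_record"`: `uvs`, `sd`, `ns`, `uvis`
#'   (named per-informant values), `species`, `group`.
#' @export
species_use_value <- function(dataset, species, group = NULL,
                              sd_type = c("sample", "population"),
                              uv_normalizer = c("none", "lexicon")) {
  sd_type <- match.arg(sd_type)
  uv_normalizer <- match.arg(uv_normalizer)
  uvis <- uvis_vector(dataset, species, group)
  ns <- length(uvis)
  if (ns == 0) {
    stop("undefined use value: no informant interviewed for '", species,
         "' in scope ", if (is.null(group)) "<all>" else group, call. = FALSE)
  }
  if (uv_normalizer == "lexicon") {
    ur <- dataset$use_reports
    lex <- length(unique(ur$specific_use[ur$species == species]))
    if (lex > 0) uvis <- uvis / lex
  }
  s <- if (ns == 1) 0 else if (sd_type == "sample") {
    sd(uvis)
  } else {
    sqrt(mean((uvis - mean(uvis))^2))
  }
  structure(
    list(uvs = mean(uvis), sd = s, ns = ns, uvis = uvis,
         species = species, group = group),
    class = "use_value_record"
  )
}

#' @export
print.use_value_record <- function(x, ...) {
  cat("<use_value_record> ", x$species,
      if (!is.null(x$group)) paste0(" [", x$group, "]"), ": UV = ",
      format(x$uvs, digits = 4), " ± ", format(x$sd, digits = 4),
      " (Ns = ", x$ns, ")\n", sep = "")
  invisible(x)
}

#' Per-category use value (UVc)
#'
#' Total use-reports per use category for the species within the scope,
#' multiplied by a configurable scale (default 1, i.e. raw citation totals).
#' Every vocabulary category is present in the result, zero-filled when
#' uncited; the between-category ranking is the stable contract, the
#' absolute scale is presentation.
#'
#' @param dataset An [interview_set()].
#' @param species Species label.
#' @param group Optional ethnic-group scope.
#' @param scale Multiplicative scale, default 1.
#' @return Named numeric vector over the category vocabulary.
#' @export
category_use_value <- function(dataset, species, group = NULL, scale = 1) {
  stopifnot(inherits(dataset, "interview_set"))
  d <- if (is.null(group)) dataset else {
    subset_interviews(dataset, ethnic_group = group)
  }
  ur <- d$use_reports
  ur <- ur[ur$species == species, ]
  counts <- table(factor(ur$category, levels = dataset$vocabulary$categories))
  setNames(as.numeric(counts) * scale, names(counts))
}

#' Index value of organ (IVO)
#'
#' Share of all use-reports attributable to each plant organ:
#' `IVO(o) = Nui(o) / Ntu`, where `Nui(o)` is the number of use-reports
#' citing organ `o` and `Ntu` the total over all organs. The shares sum to 1
#' exactly.
#'
#' @param dataset An [interview_set()].
#' @param species Species label.
#' @param group Optional ethnic-group scope.
#' @return Named numeric vector over the organ vocabulary, summing to 1.
#' @export
organ_index <- function(dataset, species, group = NULL) {
  stopifnot(inherits(dataset, "interview_set"))
  d <- if (is.null(group)) dataset else {
    subset_interviews(dataset, ethnic_group = group)
  }
  ur <- d$use_reports
  ur <- ur[ur$species == species, ]
  if (nrow(ur) == 0) {
    stop("undefined organ index: no use-report for '", species,
         "' in scope", call. = FALSE)
  }
  counts <- table(factor(ur$organ, levels = dataset$vocabulary$organs))
  setNames(as.numeric(counts) / sum(counts), names(counts))
}

#' ICV computed from survey responses
#'
#' @param dataset An [interview_set()].
#' @param species Species label.
#' @param group Optional ethnic-group scope.
#' @return Percentage in `[0, 100]`. The denominator is the number of
#'   informants interviewed for the species in scope; a missing `sells`
#'   answer counts as a non-seller.
#' @export
commercial_value <- function(dataset, species, group = NULL) {
  stopifnot(inherits(dataset, "interview_set"))
  d <- if (is.null(group)) dataset else {
    subset_interviews(dataset, ethnic_group = group)
  }
  r <- d$responses
  r <- r[r$species == species & r$knows_species %in% TRUE, ]
  if (nrow(r) == 0) {
    stop("undefined denominator: no informant interviewed for '", species,
         "' in scope", call. = FALSE)
  }
  commercial_value_index(sum(r$sells %in% TRUE), nrow(r))
}

#' Half-away-from-zero display rounding
#'
#' All internal arithmetic in this package is unrounded; printed tables use
#' conventional half-away-from-zero rounding (0.5 rounds up), not R's
#' banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_display <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
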