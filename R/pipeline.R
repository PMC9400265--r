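#' Run the full survey-analysis pipeline
#'
#' Orchestrates validate -> indices -> density -> hypothesis tests ->
#' ordination -> report for one or more species, writing all artifacts under
#' `out_dir`. Two input modes:
#'
#' * **raw mode** — `interviews` (an [interview_set()] or CSV path) plus
#'   `census` (tibble or CSV path): group index tables are computed from the
#'   raw records, the RAH test pairs computed group use values with group
#'   densities, and the cross-cultural Kruskal-Wallis runs on per-informant
#'   use values.
#' * **table mode** — `tables`, a named list (species -> path or
#'   `"group_index_table"`) of pre-aggregated per-group tables (as the
#'   packaged transcriptions of the published survey tables): index
#'   computation is bypassed and the tests run on the table columns. The
#'   cross-cultural test needs per-informant data and is skipped in this
#'   mode.
#'
#' Re-running with identical inputs and config rewrites identical artifacts.
#'
#' @param interviews Raw mode: [interview_set()] or CSV path.
#' @param census Raw mode: census tibble or CSV path.
#' @param tables Table mode: named list of per-species group tables.
#' @param site_to_group Optional `site`,`group` mapping for the census
#'   (defaults to mapping municipalities to ethnic groups via the
#'   informants table).
#' @param out_dir Output directory (created).
#' @param alpha Significance level in `(0, 1)`.
#' @param icv_threshold Commercial-importance threshold (percent).
#' @param uv_normalizer Passed to [species_use_value()].
#' @param pca_scale Unit-variance scaling for the ordination.
#' @param quiet Suppress progress messages.
#' @return A list of class `"run_report"`: per-species results (`table`,
#'   `rah`, `crosscultural`, `ordination`), artifact paths, warnings, and
#'   the settings in force.
#' @export
run_pipeline <- function(interviews = NULL, census = NULL, tables = NULL,
                         site_to_group = NULL, out_dir,
                         alpha = 0.05, icv_threshold = 75,
                         uv_normalizer = "none", pca_scale = FALSE,
                         quiet = FALSE) {
  if (alpha <= 0 || alpha >= 1) {
    stop("config validation error: alpha must lie in (0, 1)", call. = FALSE)
  }
  if (icv_threshold < 0 || icv_threshold > 100) {
    stop("config validation error: icv_threshold must lie in [0, 100]",
         call. = FALSE)
  }
  table_mode <- !is.null(tables)
  if (!table_mode && is.null(interviews)) {
    stop("config validation error: supply either raw interviews or tables",
         call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message("[usevalue] ", ...)
  warnings_log <- character()
  note <- function(w) warnings_log <<- c(warnings_log, w)

  species_tables <- list()
  dataset <- NULL
  if (table_mode) {
    stopifnot(!is.null(names(tables)), all(nzchar(names(tables))))
    for (sp in names(tables)) {
      t <- tables[[sp]]
      species_tables[[sp]] <- if (is.character(t)) {
        read_group_table(t, species = sp)
      } else {
        t
      }
      say("loaded table for ", sp, ": ",
          sum(species_tables[[sp]]$row_type == "group"), " group rows")
    }
  } else {
    dataset <- if (is.character(interviews)) {
      say("reading interviews from ", interviews)
      read_interviews(interviews)
    } else {
      interviews
    }
    validate_interviews(dataset)
    say("validated ", n_informants(dataset), " informants, ",
        nrow(dataset$use_reports), " use-reports")
    if (is.character(census)) census <- read_census(census)
    if (is.null(site_to_group) && !is.null(census)) {
      site_to_group <- dplyr::distinct(
        dataset$informants, site = .data$municipality,
        group = .data$ethnic_group
      )
    }
    for (sp in dataset$species_list) {
      dens <- if (!is.null(census)) {
        d <- density_by_group(census, sp, site_to_group = site_to_group)
        setNames(d$Ni, d$group)
      } else {
        NULL
      }
      species_tables[[sp]] <- withCallingHandlers(
        build_group_index_table(dataset, sp, densities = dens,
                                uv_normalizer = uv_normalizer),
        warning = function(w) {
          note(conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      )
    }
  }

  results <- list()
  for (sp in names(species_tables)) {
    tab <- species_tables[[sp]]
    body <- tab[tab$row_type == "group", ]
    tab_path <- file.path(out_dir, paste0("group_index_table_",
                                          sanitize_label(sp), ".tsv"))
    write_group_table(tab, tab_path)

    rah <- tryCatch(
      withCallingHandlers(
        rah_test(setNames(body$UV, body$ethnic_group),
                 setNames(body$Ni, body$ethnic_group),
                 alpha = alpha, species = sp),
        warning = function(w) {
          note(conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      ),
      error = function(e) {
        note(paste0("RAH test skipped for ", sp, ": ", conditionMessage(e)))
        NULL
      }
    )
    cc <- if (!table_mode) {
      tryCatch(crosscultural_test(dataset, sp), error = function(e) {
        note(paste0("cross-cultural test skipped for ", sp, ": ",
                    conditionMessage(e)))
        NULL
      })
    } else {
      NULL
    }
    ord <- tryCatch({
      mat <- project_groups(tab)
      keep <- colSums(mat != 0) > 0
      dropped <- colnames(mat)[!keep]
      if (length(dropped)) {
        note(paste0("zero-filled/uncited categories dropped from PCA for ",
                    sp, ": ", paste(dropped, collapse = ", ")))
      }
      o <- pca_ordination(mat[, keep, drop = FALSE], scale = pca_scale)
      write_ordination(o, file.path(out_dir,
                                    paste0("ordination_", sanitize_label(sp))))
      o
    }, error = function(e) {
      note(paste0("ordination skipped for ", sp, ": ", conditionMessage(e)))
      NULL
    })

    results[[sp]] <- list(
      table = tab, table_path = tab_path, rah = rah, crosscultural = cc,
      ordination = ord,
      icv_flagged = body$ethnic_group[
        !is.na(body$ICV) &
          flag_commercially_important(body$ICV, icv_threshold)]
    )
    if (!is.null(rah)) {
      say(sp, ": RAH rho = ", round_display(rah$test$statistic, 2),
          " (p = ", signif(rah$test$p_value, 3), "), ", rah$support)
    }
  }

  report <- structure(
    list(
      species = results,
      settings = list(alpha = alpha, icv_threshold = icv_threshold,
                      uv_normalizer = uv_normalizer, pca_scale = pca_scale,
                      table_mode = table_mode),
      warnings = unique(warnings_log),
      out_dir = out_dir
    ),
    class = "run_report"
  )
  json_path <- file.path(out_dir, "results.json")
  jsonlite::write_json(report_as_json(report), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  report$results_json <- json_path
  report_md <- make_report(report)
  md_path <- file.path(out_dir, "report.md")
  writeLines(report_md, md_path, useBytes = TRUE)
  report$report_md <- md_path
  for (w in report$warnings) say("warning: ", w)
  report
}

sanitize_label <- function(x) gsub("[^A-Za-z0-9_.-]+", "_", x)

report_as_json <- function(report) {
  lapply(report$species, function(res) {
    body <- res$table[res$table$row_type == "group", ]
    out <- list(
      n_groups = nrow(body),
      uv_mean = summarize_column(res$table, "UV"),
      icv_flagged = as.list(res$icv_flagged)
    )
    if (!all(is.na(body$Ni))) out$ni_mean <- summarize_column(res$table, "Ni")
    if (!all(is.na(body$ICV))) out$icv_mean <- summarize_column(res$table, "ICV")
    if (!is.null(res$rah)) {
      out$rah <- list(
        method = res$rah$test$method, rho = res$rah$test$statistic,
        p = res$rah$test$p_value, n = res$rah$test$n,
        alpha = res$rah$alpha, support = res$rah$support,
        dropped_groups = as.list(res$rah$dropped_groups)
      )
    }
    if (!is.null(res$crosscultural)) {
      cc <- res$crosscultural
      out$crosscultural <- list(
        method = cc$method, H = cc$statistic, df = cc$df, p = cc$p_value,
        n = cc$n
      )
    }
    if (!is.null(res$ordination)) {
      out$pca_explained_variance <- res$ordination$explained_variance_ratio
    }
    out
  })
}

#' Render a pipeline run as a markdown report
#'
#' Summarizes, per species: the index-table means row, commercially
#' important groups at the configured ICV threshold, the RAH and
#' cross-cultural test outcomes with their statistics and p-values, the
#' ordination variance profile, and every warning and setting in force.
#'
#' @param report A `"run_report"` from [run_pipeline()].
#' @return Character vector of markdown lines, invisibly usable with
#'   `writeLines()`.
#' @export
make_report <- function(report) {
  stopifnot(inherits(report, "run_report"))
  if (length(report$species) == 0) {
    stop("error: empty artifact set — no species results to report",
         call. = FALSE)
  }
  s <- report$settings
  lines <- c(
    "# Survey analysis report", "",
    sprintf("Settings: alpha = %s; ICV threshold = %s%%; uv_normalizer = %s; PCA scaling = %s; table mode = %s",
            s$alpha, s$icv_threshold, s$uv_normalizer, s$pca_scale,
            s$table_mode), ""
  )
  for (sp in names(report$species)) {
    res <- report$species[[sp]]
    if (is.null(res$table) || !file.exists(res$table_path)) {
      stop("error: missing artifact for species '", sp, "': ",
           res$table_path %||% "<no table>", call. = FALSE)
    }
    body <- res$table[res$table$row_type == "group", ]
    lines <- c(lines, sprintf("## %s", sp), "",
               sprintf("- groups: %d", nrow(body)),
               sprintf("- mean use value (unweighted over groups): %.2f",
                       round_display(summarize_column(res$table, "UV"), 2)))
    if (!all(is.na(body$Ni))) {
      lines <- c(lines, sprintf("- mean density: %.0f tufts/ha",
                                round_display(summarize_column(res$table, "Ni"), 0)))
    }
    if (!all(is.na(body$ICV))) {
      lines <- c(lines, sprintf("- mean ICV: %.2f%%",
                                round_display(summarize_column(res$table, "ICV"), 2)))
    }
    lines <- c(lines, sprintf(
      "- commercially important groups (ICV >= %s%%): %s", s$icv_threshold,
      if (length(res$icv_flagged)) paste(res$icv_flagged, collapse = ", ")
      else "none"
    ))
    if (!is.null(res$rah)) {
      lines <- c(lines, sprintf(
        "- RAH (Spearman UV~Ni, n = %d groups): rho = %.2f, p = %.4g -> %s",
        res$rah$test$n, round_display(res$rah$test$statistic, 2),
        res$rah$test$p_value, res$rah$support
      ))
    }
    if (!is.null(res$crosscultural)) {
      cc <- res$crosscultural
      lines <- c(lines, sprintf(
        "- cross-cultural (Kruskal-Wallis, n = %d): H = %.2f, df = %d, p = %.4g",
        cc$n, round_display(cc$statistic, 2), cc$df, cc$p_value
      ))
    }
    if (!is.null(res$ordination)) {
      lines <- c(lines, sprintf(
        "- PCA variance explained: %s",
        paste0(round_display(100 * res$ordination$explained_variance_ratio, 1),
               "%", collapse = ", ")
      ))
    }
    lines <- c(lines, "")
  }
  if (length(report$warnings)) {
    lines <- c(lines, "## Warnings", "",
               paste0("- ", report$warnings), "")
  }
  lines
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", length(x$species), " species -> ", x$out_dir, "\n",
      sep = "")
  for (sp in names(x$species)) {
    res <- x$species[[sp]]
    cat("  ", sp, ": ",
        sum(res$table$row_type == "group"), " groups",
        if (!is.null(res$rah)) {
          paste0("; RAH rho = ", round_display(res$rah$test$statistic, 2),
                 " (", res$rah$support, ")")
        }, "\n", sep = "")
  }
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
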