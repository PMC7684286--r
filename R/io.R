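#' Read and write rendition tables
#'
#' Rendition tables are stored as delimited text (TSV by default) with
#' header `bird_id, group, target_side, day, rendition, pitch_hz, stimulus`
#' and optionally `phase`. Reading validates the required columns and types,
#' reports offending line numbers, and restores day ordering within birds if
#' needed (with a warning).
#'
#' @param path File path.
#' @param sep Field separator (default tab; use `","` for CSV).
#' @return `read_renditions()`: a validated rendition table data.frame.
#' @export
read_renditions <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  required <- c("bird_id", "day", "pitch_hz", "stimulus")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  if (!is.numeric(tab$pitch_hz)) {
    bad <- which(is.na(suppressWarnings(as.numeric(tab$pitch_hz))))
    stop("non-numeric pitch_hz in ", path, " at data line(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  bad_pitch <- which(tab$pitch_hz <= 0 | is.na(tab$pitch_hz))
  if (length(bad_pitch) > 0L) {
    stop("nonpositive or missing pitch_hz at data line(s): ",
         paste(utils::head(bad_pitch, 5L), collapse = ", "))
  }
  if (is.character(tab$stimulus)) {
    tab$stimulus <- toupper(tab$stimulus) %in% c("TRUE", "T", "1")
  }
  tab$stimulus <- as.logical(tab$stimulus)
  tab$day <- as.integer(tab$day)
  ord <- order(tab$bird_id, tab$day)
  if (any(ord != seq_along(ord))) {
    warning("days not grouped by bird in ", path, "; auto-sorting")
    tab <- tab[ord, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' @rdname read_renditions
#' @param table A rendition table.
#' @return `write_renditions()`: the path, invisibly.
#' @export
write_renditions <- function(table, path, sep = "\t") {
  stopifnot(is.data.frame(table))
  utils::write.table(table, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write cohort designs as YAML
#'
#' A cohort design file is a YAML list of bird entries, each holding the
#' [bird_params()] fields (missing fields take the defaults).
#'
#' @param path File path.
#' @return `read_cohort_design()`: a list of [bird_params()].
#' @export
read_cohort_design <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$birds)) raw <- raw$birds
  lapply(raw, function(entry) do.call(bird_params, entry))
}

#' @rdname read_cohort_design
#' @param design A list of [bird_params()].
#' @return `write_cohort_design()`: the path, invisibly.
#' @export
write_cohort_design <- function(design, path) {
  entries <- lapply(design, function(p) {
    p <- unclass(p)
    p[!vapply(p, is.null, logical(1L))]
  })
  yaml::write_yaml(list(birds = entries), path)
  invisible(path)
}

#' Export a mixed-model fit report as JSON
#'
#' Writes the per-term table of a [fit_pitch_lmm()] or [fit_singing_lmm()]
#' fit (estimate, SE, t, df, p, 95% CI) plus the random-intercept standard
#' deviation to a JSON file.
#'
#' @param fit A `pitch_lmm_fit` or `singing_lmm_fit`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, c("pitch_lmm_fit", "singing_lmm_fit")))
  terms <- lapply(seq_len(nrow(fit$coef)), function(i) as.list(fit$coef[i, -1L]))
  names(terms) <- fit$coef$term
  jsonlite::write_json(
    list(terms = terms, random_sd = fit$random_sd, n_obs = fit$n_obs),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read and write syllable-world configurations as YAML
#'
#' A world config file holds the [syllable_world()] arguments (`n_notes`,
#' `n_variants`, `lo_states`, `kernel`, `lo_mode`); missing fields take the
#' defaults.
#'
#' @param path File path.
#' @return `read_world_config()`: a [syllable_world()].
#' @export
read_world_config <- function(path) {
  raw <- yaml::read_yaml(path)
  keep <- intersect(names(raw), c("n_notes", "n_variants", "lo_states",
                                  "kernel", "lo_mode"))
  do.call(syllable_world, raw[keep])
}

#' @rdname read_world_config
#' @param world A [syllable_world()].
#' @return `write_world_config()`: the path, invisibly.
#' @export
write_world_config <- function(world, path) {
  stopifnot(inherits(world, "syllable_world"))
  yaml::write_yaml(list(
    n_notes = world$n_notes, n_variants = world$n_variants,
    lo_states = world$lo_states,
    kernel = as.numeric(world$emission[2, 1:3]),
    lo_mode = world$lo_mode
  ), path)
  invisible(path)
}
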