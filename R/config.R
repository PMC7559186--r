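#' Load and validate a project configuration
#'
#' Reads a YAML (or JSON) configuration holding the hierarchy block, the
#' expert judgment matrices, the hazard catalog and the stage options, fills
#' defaults, and validates everything at once — the error report lists every
#' violation, not just the first.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `project_config` list with components `hierarchy`
#'   (a [risk_hierarchy()]), `experts` (named list of [judgment_matrix()]
#'   lists), `hazards` (named list of [hazard_definition()]s) and `options`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  project_config(raw)
}

#' Build a project configuration from a raw list
#'
#' @param raw nested list as produced by parsing the config file.
#' @return validated `project_config`.
#' @export
project_config <- function(raw) {
  errs <- character(0)
  note <- function(...) errs <<- c(errs, paste0(...))
  allowed <- c("hierarchy", "experts", "hazards", "options")
  extra <- setdiff(names(raw), allowed)
  if (length(extra)) note("unknown top-level key(s): ", paste(extra, collapse = ", "))

  hier <- tryCatch({
    if (is.null(raw$hierarchy)) default_hierarchy()
    else {
      nodes <- raw$hierarchy$nodes
      if (is.data.frame(nodes) && is.list(nodes$parent))  # json list column
        nodes$parent <- vapply(nodes$parent, function(p)
          if (length(p)) as.character(p) else NA_character_, character(1))
      if (is.data.frame(nodes)) risk_hierarchy(nodes)
      else risk_hierarchy(do.call(rbind, lapply(nodes, function(nd)
        data.frame(id = nd$id,
                   parent = if (is.null(nd$parent)) NA_character_ else nd$parent,
                   label = if (is.null(nd$label)) nd$id else nd$label,
                   stringsAsFactors = FALSE))))
    }
  }, error = function(e) { note("hierarchy: ", conditionMessage(e)); NULL })

  experts <- list()
  for (nd in names(raw$experts)) {
    mats <- raw$experts[[nd]]
    if (is.array(mats) && length(dim(mats)) == 3)  # json: list of matrices
      mats <- lapply(seq_len(dim(mats)[1]), function(i) mats[i, , ])
    if (!is.null(hier) && !(nd %in% names(hier$children)))
      note("experts: node '", nd, "' is not an internal hierarchy node")
    experts[[nd]] <- lapply(seq_along(mats), function(k) {
      m <- mats[[k]]
      if (is.list(m)) m <- do.call(rbind, lapply(m, unlist))
      # text serialization rounds reciprocals; accept 1e-6 and re-symmetrize
      tryCatch({
        jm <- judgment_matrix(m, node = nd, expert = paste0("E", k), tol = 1e-6)
        jm$m[lower.tri(jm$m)] <- (1 / t(jm$m))[lower.tri(jm$m)]
        jm
      }, error = function(e) {
        note("experts[", nd, "][", k, "]: ", conditionMessage(e))
        NULL
      })
    })
  }

  raw_hazards <- raw$hazards
  if (is.data.frame(raw_hazards))   # json simplification flattens to a df
    raw_hazards <- lapply(seq_len(nrow(raw_hazards)), function(i)
      lapply(raw_hazards, function(col) {
        v <- if (is.list(col)) col[[i]] else col[i]
        if (is.list(v)) unlist(v) else v
      }))
  hazards <- list()
  for (hz in raw_hazards) {
    h <- tryCatch(
      hazard_definition(hz$id, hz$cutoffs,
                        T = if (is.null(hz$T)) c(10, 30, 50, 70, 90) else hz$T,
                        unit = if (is.null(hz$unit)) "" else hz$unit,
                        higher_is_worse = !isFALSE(hz$higher_is_worse)),
      error = function(e) { note("hazards: ", conditionMessage(e)); NULL })
    if (!is.null(h)) hazards[[h$id]] <- h
  }

  opts <- utils::modifyList(default_options(),
                            if (is.null(raw$options)) list() else raw$options)
  if (!is.null(opts$fit$families)) {
    bad <- setdiff(tolower(opts$fit$families), names(distribution_families()))
    if (length(bad)) note("options$fit$families: unknown family ",
                          paste(bad, collapse = ", "))
  }
  if (opts$simulate$n < 1) note("options$simulate$n must be >= 1")

  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  structure(list(hierarchy = hier, experts = experts, hazards = hazards,
                 options = opts),
            class = "project_config")
}

default_options <- function() {
  list(questionnaire_scale_factor = 10,
       cr_threshold = 0.1,
       detection_leaves = "u7",
       fit = list(families = names(distribution_families()),
                  bins = 33, alpha = 0.05, min_expected = 5),
       simulate = list(n = 10000, seed = 42, mode = "latin_hypercube",
                       bins = c(0, 10, 20, 30, 40, 50, 60, 70, 100),
                       thresholds = c(40, 70)),
       sensitivity = list(method = "rank", scenario_threshold = 40,
                          shift_cutoff = 0.5))
}

#' Serialize a project configuration back to a raw list / file
#'
#' Round-trips with [load_config()]: `project_config(config_to_list(cfg))`
#' reproduces the same object.
#'
#' @param config a `project_config`.
#' @param path optional file path (`.yaml` or `.json`); written if given.
#' @return the raw list, invisibly if written to file.
#' @export
config_to_list <- function(config, path = NULL) {
  raw <- list(
    hierarchy = list(nodes = lapply(seq_len(nrow(config$hierarchy$edges)),
      function(i) {
        e <- config$hierarchy$edges[i, ]
        list(id = e$id,
             parent = if (is.na(e$parent)) NULL else e$parent,
             label = if ("label" %in% names(e)) e$label else e$id)
      })),
    experts = lapply(config$experts, function(mats)
      lapply(mats, function(jm) {
        m <- unclass(jm$m)
        lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
      })),
    hazards = lapply(unname(config$hazards), function(h)
      list(id = h$id, unit = h$unit, cutoffs = h$cutoffs, T = h$T,
           higher_is_worse = h$higher_is_worse)),
    options = config$options)
  if (length(raw$experts) == 0L) raw$experts <- NULL
  if (!is.null(path)) {
    if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
    else yaml::write_yaml(raw, path, precision = 15)
    return(invisible(raw))
  }
  raw
}

#' The shipped default configuration
#'
#' The three-level default hierarchy, a twelve-hazard catalog with
#' placeholder warning ladders (the regulatory cut-off values behind each
#' real ladder are jurisdiction-specific and must be edited in by the user),
#' and default stage options.
#'
#' @return a `project_config`.
#' @export
default_config <- function() {
  load_config(system.file("extdata", "default_config.yaml",
                          package = "riskwarn", mustWork = TRUE))
}
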