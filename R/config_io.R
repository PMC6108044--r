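#' Read a YAML configuration document
#'
#' @param path Path to a YAML file.
#' @return Parsed document (list). A parse failure signals a configuration
#'   error carrying the parser's position message.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop("configuration error: file not found: ", path, call. = FALSE)
  tryCatch(yaml::read_yaml(path),
           error = function(e)
             stop("configuration error in ", path, ": ",
                  conditionMessage(e), call. = FALSE))
}

#' Validate a configuration document against a named schema
#'
#' Lightweight structural validation: required fields, types and ranges,
#' with precise error paths. All violations are collected and reported
#' together. Unknown extra keys produce a warning, not an error (forward
#' compatibility).
#'
#' @param document Parsed configuration (list) or, for `"registry"`, an
#'   `hd_registry` data frame.
#' @param schema_name One of `"registry"`, `"design"`, `"uncertainty"`,
#'   `"scenario"`, `"labor"`.
#' @return The validated structure, converted to the package's native
#'   object where one exists (`hd_registry`, `hd_design`, `hd_scenario`,
#'   uncertainty data frame, labor data frame).
#' @export
validate_config <- function(document,
                            schema_name = c("registry", "design",
                                            "uncertainty", "scenario",
                                            "labor")) {
  schema_name <- match.arg(schema_name)
  errs <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)

  known_keys <- switch(schema_name,
    registry = c("parameters"),
    design = c("n_reactors", "n_fibers_A", "n_fibers_B", "fiber_A",
               "fiber_B", "reactor_radius", "reactor_length",
               "flow_per_fiber", "feeds", "seeding_density", "horizon",
               "gamma_pack"),
    uncertainty = c("parameters"),
    scenario = c("price", "market_size", "share", "success_prob",
                 "discount_rate", "dev_cost_per_year", "dev_years",
                 "horizon"),
    labor = c("activities"))
  if (is.list(document) && !is.data.frame(document)) {
    extra <- setdiff(names(document), known_keys)
    if (length(extra))
      warning("ignoring unknown key(s): ", paste(extra, collapse = ", "),
              call. = FALSE)
  }

  out <- switch(schema_name,
    registry = {
      reg <- if (is.data.frame(document)) document else {
        need(!is.null(document$parameters), "registry: missing 'parameters'")
        if (length(errs)) NULL else {
          tf <- tempfile(fileext = ".yaml")
          on.exit(unlink(tf), add = TRUE)
          yaml::write_yaml(document, tf); read_registry(tf)
        }
      }
      if (!is.null(reg)) {
        need(all(c("id", "nominal", "unit", "group", "uncertainty_class")
                 %in% names(reg)), "registry: missing required columns")
        if (!length(errs)) {
          for (i in seq_len(nrow(reg))) {
            if (!is.finite(reg$nominal[i]) || reg$nominal[i] <= 0)
              need(FALSE, sprintf(
                "registry: parameters[%d] (%s): nominal must be > 0",
                i, reg$id[i]))
            if (!reg$uncertainty_class[i] %in%
                c("measured_box", "level_set"))
              need(FALSE, sprintf(
                "registry: parameters[%d] (%s): bad uncertainty_class",
                i, reg$id[i]))
          }
          need(!anyDuplicated(reg$id), "registry: duplicate parameter ids")
        }
      }
      reg
    },
    design = {
      args <- document
      for (f in c("reactor_radius", "reactor_length", "flow_per_fiber")) {
        if (!is.null(args[[f]]))
          need(is.numeric(args[[f]]) && args[[f]] > 0,
               paste0("design: '", f, "' must be a positive number"))
      }
      if (!is.null(args$feeds)) {
        args$feeds <- unlist(args$feeds)
        need(all(args$feeds >= 0), "design: 'feeds' must be nonnegative")
      }
      if (length(errs)) NULL else
        tryCatch(do.call(hd_design, args),
                 error = function(e) { need(FALSE, paste0("design: ",
                   conditionMessage(e))); NULL })
    },
    uncertainty = {
      need(!is.null(document$parameters), "uncertainty: missing 'parameters'")
      if (length(errs)) NULL else {
        rows <- do.call(rbind, lapply(seq_along(document$parameters),
          function(i) {
            p <- document$parameters[[i]]
            need(!is.null(p$id), sprintf("uncertainty: parameters[%d]: missing id", i))
            need(!is.null(p$lo) && !is.null(p$hi),
                 sprintf("uncertainty: parameters[%d]: missing lo/hi", i))
            if (!is.null(p$lo) && !is.null(p$hi))
              need(p$lo <= 1 && 1 <= p$hi, sprintf(
                "uncertainty: parameters[%d] (%s): need lo <= 1 <= hi",
                i, p$id))
            data.frame(id = p$id %||% NA_character_,
                       lo = p$lo %||% NA_real_, hi = p$hi %||% NA_real_,
                       stringsAsFactors = FALSE)
          }))
        if (length(errs)) NULL else rows
      }
    },
    scenario = {
      for (f in c("price", "market_size")) {
        need(!is.null(document[[f]]), paste0("scenario: missing '", f, "'"))
        if (!is.null(document[[f]]))
          need(is.numeric(document[[f]]) && document[[f]] >= 0,
               paste0("scenario: '", f, "' must be >= 0"))
      }
      for (f in c("share", "success_prob")) {
        if (!is.null(document[[f]]))
          need(document[[f]] >= 0 && document[[f]] <= 1,
               paste0("scenario: '", f, "' must be in [0, 1]"))
      }
      if (length(errs)) NULL else
        do.call(market_scenario,
                document[intersect(names(document), known_keys)])
    },
    labor = {
      need(!is.null(document$activities), "labor: missing 'activities'")
      if (length(errs)) NULL else {
        tb <- do.call(rbind, lapply(seq_along(document$activities),
          function(i) {
            a <- document$activities[[i]]
            need(!is.null(a$days) && a$days >= 0, sprintf(
              "labor: activities[%d]: 'days' must be >= 0", i))
            need(!is.null(a$hours_per_day) && a$hours_per_day >= 0,
                 sprintf("labor: activities[%d]: 'hours_per_day' must be >= 0", i))
            data.frame(stage = a$stage %||% "unspecified",
                       activity = a$activity %||% sprintf("activity_%d", i),
                       days = a$days %||% NA_real_,
                       hours_per_day = a$hours_per_day %||% NA_real_,
                       stringsAsFactors = FALSE)
          }))
        if (length(errs)) NULL else tb
      }
    })
  if (length(errs))
    stop("configuration error:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write machine-readable results as JSON
#'
#' Numbers are serialized at full precision; nested lists map to JSON
#' objects.
#'
#' @param x Result list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a run manifest
#'
#' Records what a run did: subcommand, input-file MD5 hashes, seed, tool
#' version, timestamp and output paths. Deterministic subcommands rerun
#' with an identical manifest reproduce identical outputs.
#'
#' @param subcommand Subcommand name.
#' @param inputs Character vector of input file paths (hashed if they
#'   exist).
#' @param seed Integer seed or `NA`.
#' @param outputs Character vector of output paths.
#' @param path Manifest output path.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(subcommand, inputs = character(0), seed = NA,
                           outputs = character(0), path) {
  hashes <- if (length(inputs)) {
    ex <- file.exists(inputs)
    h <- rep(NA_character_, length(inputs))
    h[ex] <- unname(tools::md5sum(inputs[ex]))
    stats::setNames(as.list(h), inputs)
  } else list()
  man <- list(subcommand = subcommand, config_hashes = hashes,
              seed = seed,
              tool_version = as.character(utils::packageVersion("hemodesign")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              outputs = as.list(outputs))
  write_results(man, path)
  invisible(man)
}
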