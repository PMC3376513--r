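ADVICE_SECTIONS <- c("introduction", "normative_feedback",
                     "progress_feedback", "schedule", "tips", "info_blocks")

TIP_DOMAINS <- c("work", "household", "gardening", "leisure", "transport")

INFO_BLOCKS <- c("walking_buddy", "step_vs_activity_guidelines",
                 "pedometer_use", "benefits_10000", "barriers",
                 "self_efficacy", "environment")

#' Read a message library
#'
#' A message library is a YAML list of entries, each with an `id`, a
#' `section` (one of introduction, normative_feedback, progress_feedback,
#' schedule, tips, info_blocks), a `stage` (a stage name, a list of stage
#' names, or `any`), an optional `domain` (for tips) or `block` (for info
#' blocks), an optional `when` predicate -- an R expression over the
#' tailoring fields (e.g. `below_goal`, `high_barriers`,
#' `evolution == "positive"`) -- and a `template` whose `{placeholders}`
#' are filled at composition time. Entries marked `canonical: true` carry
#' published wording; the rest are editable seed texts.
#'
#' @param path YAML file; `NULL` loads the library shipped with the
#'   package.
#' @return A `message_library` object.
#' @export
read_message_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "message_library.yaml",
                        package = "steptailor", mustWork = TRUE)
  }
  entries <- yaml::read_yaml(path)
  if (!length(entries)) stop("empty message library: ", path, call. = FALSE)
  ids <- vapply(entries, function(e) e$id %||% NA_character_, character(1))
  if (anyNA(ids) || anyDuplicated(ids)) {
    stop("every message-library entry needs a unique id: ", path,
         call. = FALSE)
  }
  for (e in entries) {
    if (is.null(e$section) || !e$section %in% ADVICE_SECTIONS) {
      stop("entry '", e$id, "': section must be one of ",
           paste(ADVICE_SECTIONS, collapse = ", "), call. = FALSE)
    }
    if (is.null(e$stage)) {
      stop("entry '", e$id, "': stage is required (may be 'any')",
           call. = FALSE)
    }
    bad <- setdiff(unlist(e$stage), c(STAGES, "any"))
    if (length(bad)) {
      stop("entry '", e$id, "': unknown stage(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (is.null(e$template) || !nzchar(e$template)) {
      stop("entry '", e$id, "': template is required", call. = FALSE)
    }
  }
  structure(list(entries = entries, path = path),
            class = "message_library")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.message_library <- function(x, ...) {
  sections <- vapply(x$entries, `[[`, character(1), "section")
  cat(sprintf("Message library (%d entries): %s\n", length(x$entries),
              paste(sprintf("%s=%d", names(table(sections)),
                            table(sections)), collapse = ", ")))
  invisible(x)
}

eval_predicate <- function(expr_string, data, id = "?") {
  expr <- tryCatch(parse(text = expr_string)[[1]],
                   error = function(e) {
                     stop("entry '", id, "': unparseable predicate: ",
                          expr_string, call. = FALSE)
                   })
  value <- eval(expr, envir = data, enclos = baseenv())
  if (!is.logical(value) || length(value) != 1L || is.na(value)) {
    stop("entry '", id, "': predicate did not yield TRUE/FALSE: ",
         expr_string, call. = FALSE)
  }
  value
}

render_template <- function(template, data, id = "?") {
  matches <- gregexpr("\\{[a-z0-9_]+\\}", template)[[1]]
  if (matches[1] == -1L) return(template)
  names <- unique(substring(
    regmatches(template, gregexpr("\\{[a-z0-9_]+\\}", template))[[1]], 2,
    nchar(regmatches(template,
                     gregexpr("\\{[a-z0-9_]+\\}", template))[[1]]) - 1L))
  out <- template
  for (nm in names) {
    if (is.null(data[[nm]])) {
      stop("unresolved template placeholder '{", nm, "}' in message '",
           id, "'", call. = FALSE)
    }
    out <- gsub(paste0("{", nm, "}"), as.character(data[[nm]]), out,
                fixed = TRUE)
  }
  out
}

stage_matches <- function(entry, stage) {
  s <- unlist(entry$stage)
  "any" %in% s || stage %in% s
}

#' Select and render matching messages from a library
#'
#' Filters entries by section (and optionally tip domain / info block),
#' stage, and predicate, then renders each surviving template against the
#' tailoring data. Every returned message keeps its provenance (entry id,
#' predicate) so a composed document is auditable.
#'
#' @param library A [read_message_library()] result.
#' @param section Section name.
#' @param data Named list of tailoring fields for predicates and
#'   placeholders; must contain `stage`.
#' @param domain Optional tip domain filter.
#' @param block Optional info-block filter.
#' @return List of messages: `list(id, section, text, when)` each.
#' @export
select_messages <- function(library, section, data, domain = NULL,
                            block = NULL) {
  stopifnot(inherits(library, "message_library"))
  out <- list()
  for (e in library$entries) {
    if (!identical(e$section, section)) next
    if (!is.null(domain) && !identical(e$domain, domain)) next
    if (!is.null(block) && !identical(e$block, block)) next
    if (!stage_matches(e, data$stage)) next
    if (!is.null(e$when) && !eval_predicate(e$when, data, e$id)) next
    out[[length(out) + 1L]] <- list(
      id = e$id, section = section,
      domain = e$domain %||% NA_character_,
      block = e$block %||% NA_character_,
      when = e$when %||% NA_character_,
      canonical = isTRUE(e$canonical),
      text = render_template(e$template, data, e$id))
  }
  out
}

fmt_steps <- function(x) formatC(round(x), big.mark = ",", format = "d")
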