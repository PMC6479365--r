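#' Write an ENPS model description
#'
#' Serializes a system to a JSON document with top-level keys `membranes`
#' (label, parent, variables with initial values, enzymes), `programs`
#' (membrane, production expression string, enzyme, repartition terms,
#' comparison, name, group) and optionally `policy`. The format round-trips:
#' `read_enps_model(write_enps_model(s))` is structurally equal to `s`.
#'
#' @param system an [enps_system()].
#' @param path optional file path; when `NULL` the JSON text is returned.
#' @param policy optional [enps_policy()] stored as defaults in the file.
#' @return the JSON text, invisibly when written to a file.
#' @export
write_enps_model <- function(system, path = NULL, policy = NULL) {
  stopifnot(inherits(system, "enps_system"))
  membranes <- lapply(system$membranes, function(m) {
    v <- m$variables
    if (is.null(v)) v <- numeric(0)
    list(label = as.character(m$label),
         parent = if (is.null(m$parent) || is.na(m$parent)) NULL
                  else as.character(m$parent),
         variables = as.list(v),
         enzymes = if (is.null(m$enzymes)) character(0)
                   else as.character(m$enzymes))
  })
  programs <- lapply(system$programs, function(p) {
    out <- list(membrane = p$membrane,
                production = deparse1(p$production),
                repartition = lapply(seq_along(p$targets), function(i)
                  list(coefficient = p$coefficients[i],
                       target = p$targets[i])),
                comparison = p$comparison)
    if (!is.na(p$enzyme)) out$enzyme <- p$enzyme
    if (!is.na(p$name)) out$name <- p$name
    if (!is.na(p$group)) out$group <- p$group
    out
  })
  doc <- list(membranes = membranes, programs = programs)
  if (!is.null(policy)) {
    stopifnot(inherits(policy, "enps_policy"))
    doc$policy <- list(mode = policy$mode, consumption = policy$consumption,
                       max_steps = policy$max_steps,
                       halt_variable = policy$halt_variable,
                       halt_threshold = policy$halt_threshold,
                       halt_on_fixpoint = policy$halt_on_fixpoint)
  }
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                          pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(as.character(txt))
}

#' Read an ENPS model description
#'
#' Parses the JSON dialect written by [write_enps_model()] and validates all
#' structural invariants (single-rooted membrane tree, unique variable names,
#' resolvable references). Integer initial values are parsed as doubles.
#'
#' @param path a file path, or a JSON string.
#' @return a list with elements `system` (an [enps_system()]) and `policy`
#'   (an [enps_policy()], or `NULL` when the file declares none).
#' @export
read_enps_model <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("cannot parse model file: ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(doc$membranes))
    stop("model file lacks a 'membranes' key", call. = FALSE)
  membranes <- lapply(doc$membranes, function(m) {
    if (is.null(m$label)) stop("membrane without a label", call. = FALSE)
    v <- m$variables
    vals <- if (is.null(v) || length(v) == 0L) numeric(0)
            else vapply(v, as.numeric, numeric(1))
    list(label = as.character(m$label),
         parent = if (is.null(m$parent)) NA_character_
                  else as.character(m$parent),
         variables = vals,
         enzymes = if (is.null(m$enzymes)) character(0)
                   else vapply(m$enzymes, as.character, character(1)))
  })
  programs <- lapply(doc$programs, function(p) {
    if (is.null(p$production) || is.null(p$repartition) ||
        is.null(p$membrane))
      stop("program entries need 'membrane', 'production' and 'repartition'",
           call. = FALSE)
    coefs <- vapply(p$repartition, function(t) as.numeric(t$coefficient),
                    numeric(1))
    targets <- vapply(p$repartition, function(t) as.character(t$target),
                      character(1))
    enps_program(production = p$production,
                 repartition = stats::setNames(coefs, targets),
                 membrane = as.character(p$membrane),
                 enzyme = p$enzyme,
                 comparison = if (is.null(p$comparison)) "ge"
                              else p$comparison,
                 name = p$name, group = p$group)
  })
  system <- enps_system(membranes, programs)
  policy <- NULL
  if (!is.null(doc$policy)) {
    pl <- doc$policy
    policy <- enps_policy(
      mode = if (is.null(pl$mode)) "staged" else pl$mode,
      consumption = if (is.null(pl$consumption)) "non-consuming"
                    else pl$consumption,
      max_steps = if (is.null(pl$max_steps)) 1000L else pl$max_steps,
      halt_variable = pl$halt_variable,
      halt_threshold = if (is.null(pl$halt_threshold)) 1
                       else pl$halt_threshold,
      halt_on_fixpoint = isTRUE(pl$halt_on_fixpoint))
  }
  list(system = system, policy = policy)
}
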