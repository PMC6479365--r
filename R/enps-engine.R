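#' Enzyme applicability of a program
#'
#' A program with no enzyme is unconditionally applicable. With an enzyme
#' `e`, it is applicable iff `e > min(operands)` (strict comparison) or
#' `e >= min(operands)` (non-strict). For an operand-free (constant)
#' production the operand minimum is taken to be 0.
#'
#' @param program an [enps_program()].
#' @param config an `enps_config` (see [enps_init()]), or a named numeric
#'   vector of current variable values.
#' @return logical scalar.
#' @export
enps_applicable <- function(program, config) {
  values <- config_values(config)
  if (is.na(program$enzyme)) return(TRUE)
  ev <- lookup_values(values, program$enzyme)
  m <- if (length(program$operands) == 0L) 0 else
    min(lookup_values(values, program$operands))
  if (program$comparison == "gt") ev > m else ev >= m
}

#' Evaluate a program's production function
#'
#' Pure evaluation of the production expression on the current variable
#' values; no state is changed. Applicability is the caller's concern.
#'
#' @inheritParams enps_applicable
#' @param envir optionally, a pre-built environment holding the variable
#'   values (used internally to avoid rebuilding it per rule).
#' @return the numeric production value.
#' @export
enps_production_value <- function(program, config, envir = NULL) {
  if (is.null(envir)) {
    values <- config_values(config)
    miss <- setdiff(program$operands, names(values))
    if (length(miss))
      stop("unresolved variable(s) in production: ",
           paste(miss, collapse = ", "), call. = FALSE)
    envir <- list2env(as.list(values), parent = baseenv())
  }
  v <- suppressWarnings(eval(program$production, envir))
  if (is.na(v) || is.nan(v))
    stop("production of rule '", program$name,
         "' evaluated to a non-finite value (square root of a negative ",
         "intermediate?)", call. = FALSE)
  v
}

#' Repartition of a production value
#'
#' Distributes `amount` among targets proportionally to the repartition
#' coefficients: target `k` receives `amount * c_k / sum(c)`. The increments
#' sum to `amount` exactly up to floating tolerance. A zero coefficient sum
#' is legal only for a zero amount (all increments 0), which is how
#' border-zeroing rules with an empty right-hand share are expressed.
#'
#' @param amount numeric production value.
#' @param repartition named numeric vector of non-negative coefficients
#'   (names are target variables), or an [enps_program()] whose repartition
#'   protocol is used.
#' @return named numeric vector of increments, one per target.
#' @export
enps_distribute <- function(amount, repartition) {
  if (inherits(repartition, "enps_program")) {
    coefs <- repartition$coefficients
    targets <- repartition$targets
  } else {
    coefs <- unname(repartition)
    targets <- names(repartition)
  }
  if (length(coefs) < 1L)
    stop("repartition protocol must have at least one term", call. = FALSE)
  if (any(coefs < 0))
    stop("repartition coefficients must be non-negative", call. = FALSE)
  cs <- sum(coefs)
  if (cs == 0) {
    if (amount != 0)
      stop("repartition error: zero coefficient sum with non-zero amount ",
           amount, call. = FALSE)
    return(stats::setNames(numeric(length(coefs)), targets))
  }
  stats::setNames(amount * (coefs / cs), targets)
}

#' One synchronous parallel step of an ENPS
#'
#' All applicable programs of the active membranes (optionally narrowed to
#' named scheduling groups) evaluate their productions against the pre-step
#' configuration simultaneously. Then, in this order: under a consuming
#' policy every production operand of a fired program is reset to 0; every
#' repartition target of a fired program is reset to 0; finally the summed
#' increments of all fired programs are added, in program declaration order.
#'
#' @param system an [enps_system()].
#' @param config an `enps_config`.
#' @param policy an [enps_policy()]; only `consumption` is consulted here.
#' @param membranes character vector of active membrane labels (default:
#'   all membranes).
#' @param groups optional character vector of program group tags; when given,
#'   only programs carrying one of these tags (in the active membranes) are
#'   eligible.
#' @return a list with elements `config` (the post-step `enps_config`,
#'   `step_index` incremented), `fired` (number of programs that fired) and
#'   `fired_programs` (their names).
#' @export
enps_step <- function(system, config, policy = enps_policy(),
                      membranes = NULL, groups = NULL) {
  stopifnot(inherits(system, "enps_system"), inherits(config, "enps_config"))
  values <- config$values
  progs <- system$programs

  eligible <- rep(TRUE, length(progs))
  if (!is.null(membranes)) {
    unknown <- setdiff(membranes, system$labels)
    if (length(unknown))
      stop("unknown membrane label(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    eligible <- system$program_membranes %in% membranes
  }
  if (!is.null(groups))
    eligible <- eligible & (system$program_groups %in% groups)
  idx <- which(eligible)

  if (length(idx) == 0L) {
    config$step_index <- config$step_index + 1L
    return(list(config = config, fired = 0L, fired_programs = character(0)))
  }

  envir <- list2env(as.list(values), parent = baseenv())

  fired <- integer(length(idx))
  amounts <- numeric(length(idx))
  nf <- 0L
  for (i in idx) {
    p <- progs[[i]]
    # applicability, via the hashed environment (fast path of
    # enps_applicable(); see that function for the semantics)
    if (is.na(p$enzyme)) {
      app <- TRUE
    } else {
      ev <- get(p$enzyme, envir = envir)
      m <- if (length(p$operands) == 0L) 0 else
        min(unlist(mget(p$operands, envir = envir), use.names = FALSE))
      app <- if (p$comparison == "gt") ev > m else ev >= m
    }
    if (!app) next
    a <- tryCatch(enps_production_value(p, envir = envir),
                  error = function(e)
      stop("membrane ", p$membrane, ", rule '", p$name, "': ",
           conditionMessage(e), call. = FALSE))
    nf <- nf + 1L
    fired[nf] <- i
    amounts[nf] <- a
  }
  fired <- fired[seq_len(nf)]
  amounts <- amounts[seq_len(nf)]

  new_values <- values
  if (length(fired)) {
    if (policy$consumption == "consuming") {
      ops <- unique(unlist(lapply(progs[fired], `[[`, "operand_idx"),
                           use.names = FALSE))
      if (length(ops)) new_values[ops] <- 0
    }
    tgts <- unique(unlist(lapply(progs[fired], `[[`, "target_idx"),
                          use.names = FALSE))
    new_values[tgts] <- 0
    for (k in seq_along(fired)) {
      p <- progs[[fired[k]]]
      inc <- tryCatch(enps_distribute(amounts[k], p), error = function(e)
        stop("membrane ", p$membrane, ", rule '", p$name, "': ",
             conditionMessage(e), call. = FALSE))
      new_values[p$target_idx] <- new_values[p$target_idx] + unname(inc)
    }
  }

  config$values <- new_values
  config$step_index <- config$step_index + 1L
  nm <- vapply(progs[fired], `[[`, character(1), "name")
  list(config = config, fired = length(fired), fired_programs = nm)
}

#' Run an ENPS to its halting configuration
#'
#' In staged mode the schedule is executed entry by entry, one synchronous
#' step per entry; each entry is either a character vector of membrane
#' labels, or a list with elements `membranes` and/or `groups` (either may be
#' omitted). If a halt variable is configured and reaches its threshold the
#' run stops after that entry.
#'
#' In all-parallel mode every membrane is active at every step; the run stops
#' when the halt variable reaches its threshold, when no program fires, or
#' (if enabled) at a fixed point. Exhausting `max_steps` raises a classed
#' error (`enps_nonhalting_error`) rather than silently truncating.
#'
#' @param system an [enps_system()].
#' @param policy an [enps_policy()].
#' @param schedule staged mode only: non-empty list of schedule entries.
#' @param config starting configuration (default [enps_init()]).
#' @param trace logical; record every variable's value after every step.
#' @return a list of class `enps_run`: `config` (final configuration),
#'   `steps` (steps executed), `fired` (integer vector, programs fired per
#'   step), `halted` (logical) and, if requested, `trace` (a data.frame with
#'   columns `step`, `variable`, `value`; step 0 is the initial state).
#' @export
enps_run <- function(system, policy = enps_policy(), schedule = NULL,
                     config = NULL, trace = FALSE) {
  stopifnot(inherits(system, "enps_system"), inherits(policy, "enps_policy"))
  if (is.null(config)) config <- enps_init(system)
  if (!is.null(policy$halt_variable) &&
      !policy$halt_variable %in% names(config$values))
    stop("halt variable '", policy$halt_variable, "' is not declared",
         call. = FALSE)

  snapshots <- if (trace) list(config$values) else NULL
  fired_per_step <- integer(0)

  halted <- FALSE
  if (policy$mode == "staged") {
    if (is.null(schedule) || length(schedule) == 0L)
      stop("staged mode requires a non-empty schedule", call. = FALSE)
    for (entry in schedule) {
      if (is.list(entry)) {
        mem <- entry$membranes; grp <- entry$groups
      } else { mem <- entry; grp <- NULL }
      st <- enps_step(system, config, policy, membranes = mem, groups = grp)
      config <- st$config
      fired_per_step <- c(fired_per_step, st$fired)
      if (trace) snapshots[[length(snapshots) + 1L]] <- config$values
      if (halt_reached(config, policy)) { halted <- TRUE; break }
    }
    if (!halted) halted <- is.null(policy$halt_variable)
  } else {
    prev <- config$values
    repeat {
      if (length(fired_per_step) >= policy$max_steps)
        stop_nonhalting(policy$max_steps)
      st <- enps_step(system, config, policy)
      config <- st$config
      fired_per_step <- c(fired_per_step, st$fired)
      if (trace) snapshots[[length(snapshots) + 1L]] <- config$values
      if (halt_reached(config, policy)) { halted <- TRUE; break }
      if (st$fired == 0L) { halted <- TRUE; break }
      if (policy$halt_on_fixpoint && identical(config$values, prev)) {
        halted <- TRUE; break
      }
      prev <- config$values
    }
  }

  out <- list(config = config, steps = length(fired_per_step),
              fired = fired_per_step, halted = halted)
  if (trace) {
    vars <- names(config$values)
    out$trace <- data.frame(
      step = rep(seq_along(snapshots) - 1L, each = length(vars)),
      variable = rep(vars, times = length(snapshots)),
      value = unlist(snapshots, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  class(out) <- "enps_run"
  out
}

halt_reached <- function(config, policy) {
  !is.null(policy$halt_variable) &&
    config$values[[policy$halt_variable]] >= policy$halt_threshold
}

stop_nonhalting <- function(max_steps) {
  stop(structure(class = c("enps_nonhalting_error", "error", "condition"),
                 list(message = sprintf(
                   "system did not halt within max_steps = %d", max_steps),
                   call = NULL)))
}

#' @export
print.enps_run <- function(x, ...) {
  cat(sprintf("<enps_run> %d step(s), %s; programs fired per step: %s\n",
              x$steps, if (x$halted) "halted" else "not halted",
              paste(x$fired, collapse = ", ")))
  invisible(x)
}

config_values <- function(config) {
  if (inherits(config, "enps_config")) config$values
  else if (is.numeric(config) && !is.null(names(config))) config
  else stop("expected an enps_config or a named numeric vector",
            call. = FALSE)
}

lookup_values <- function(values, nm) {
  i <- match(nm, names(values))
  if (anyNA(i))
    stop("unresolved variable reference: ",
         paste(nm[is.na(i)], collapse = ", "), call. = FALSE)
  values[i]
}
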