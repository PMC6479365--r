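#' Construct an ENPS program (rule)
#'
#' A program in an enzymatic numerical P system consists of a *production
#' function* (an arithmetic expression over variables; polynomials plus
#' `sqrt()` and `sum()`) and a *repartition protocol* that distributes the
#' production value among target variables proportionally to non-negative
#' coefficients. An optional *enzyme* variable gates execution: the rule may
#' fire only if the enzyme's value exceeds (strict) or equals-or-exceeds
#' (non-strict) the minimum of the production operands.
#'
#' For an operand-free (constant) production the operand minimum is taken to
#' be 0, so e.g. a zeroing rule `0 |e -> 1|v` fires whenever the enzyme is
#' non-negative (non-strict) or positive (strict).
#'
#' @param production the production function: a character string (parsed), a
#'   language object, or a plain number.
#' @param repartition named numeric vector: names are target variables,
#'   values are non-negative repartition coefficients. At least one term.
#' @param membrane label of the membrane the program belongs to.
#' @param enzyme optional name of the gating enzyme variable.
#' @param comparison `"ge"` (non-strict, the default) or `"gt"` (strict):
#'   how the enzyme value is compared with the operand minimum.
#' @param name optional rule name used in traces and error messages.
#' @param group optional scheduling group tag (see [enps_run()]'s staged mode).
#' @return an object of class `enps_program`.
#' @examples
#' enps_program("2 * (g - theta)", c(g = 1, E = 1), membrane = "3",
#'              name = "Pr31")
#' @seealso [enps_system()], [enps_step()]
#' @export
enps_program <- function(production, repartition, membrane,
                         enzyme = NULL, comparison = c("ge", "gt"),
                         name = NULL, group = NULL) {
  comparison <- match.arg(comparison)
  if (is.character(production)) {
    production <- tryCatch(str2lang(production), error = function(e)
      stop("cannot parse production expression: ", conditionMessage(e),
           call. = FALSE))
  }
  check_production_expr(production)
  if (length(repartition) < 1L)
    stop("repartition protocol must have at least one term", call. = FALSE)
  if (is.null(names(repartition)) || any(!nzchar(names(repartition))))
    stop("repartition terms must be named by their target variables",
         call. = FALSE)
  repartition <- vapply(repartition, as.numeric, numeric(1))
  if (any(repartition < 0) || anyNA(repartition))
    stop("repartition coefficients must be non-negative numbers",
         call. = FALSE)
  operands <- all.vars(production)
  if (!is.null(enzyme)) {
    if (enzyme %in% operands)
      stop("enzyme '", enzyme, "' may not appear among production operands",
           call. = FALSE)
    if (enzyme %in% names(repartition))
      stop("enzyme '", enzyme, "' may not be a repartition target",
           call. = FALSE)
  }
  structure(list(
    name = if (is.null(name)) NA_character_ else as.character(name),
    membrane = as.character(membrane),
    production = production,
    operands = operands,
    enzyme = if (is.null(enzyme)) NA_character_ else as.character(enzyme),
    comparison = comparison,
    targets = names(repartition),
    coefficients = unname(repartition),
    coef_sum = sum(repartition),
    group = if (is.null(group)) NA_character_ else as.character(group)
  ), class = "enps_program")
}

# fast internal constructor: callers guarantee validity by construction
new_program <- function(production, operands, targets, coefficients,
                        membrane, enzyme = NULL, comparison = "ge",
                        name = NA_character_, group = NA_character_) {
  structure(list(
    name = name, membrane = membrane, production = production,
    operands = operands,
    enzyme = if (is.null(enzyme)) NA_character_ else enzyme,
    comparison = comparison, targets = targets,
    coefficients = coefficients, coef_sum = sum(coefficients),
    group = group
  ), class = "enps_program")
}

# Productions are polynomials plus sqrt; sum() is admitted as flat n-ary
# addition so very wide productions do not nest thousands of binary calls.
check_production_expr <- function(e) {
  allowed <- c("+", "-", "*", "/", "^", "sqrt", "sum", "(")
  walk <- function(x) {
    if (is.numeric(x) || is.symbol(x)) return(invisible())
    if (is.call(x)) {
      op <- as.character(x[[1L]])
      if (!op %in% allowed)
        stop("operator or function '", op,
             "' is not allowed in a production expression", call. = FALSE)
      for (i in seq_along(x)[-1L]) walk(x[[i]])
      return(invisible())
    }
    stop("invalid element in production expression: ",
         deparse(x), call. = FALSE)
  }
  walk(e)
  invisible(e)
}

#' Construct an enzymatic numerical P system
#'
#' Assembles and validates a cell-like membrane system: a rooted tree of
#' membranes (the root is the skin), per-membrane numerical variables with
#' initial values, per-membrane enzyme subsets, and the programs (rules).
#'
#' Validation enforces the structural invariants of the model: the membrane
#' graph is a tree with a single root; variable names are unique system-wide;
#' every enzyme is declared as a variable of its own membrane; and every name
#' a program references (operand, enzyme, repartition target) resolves to a
#' declared variable somewhere in the system.
#'
#' @param membranes list of membrane descriptions, each a list with elements
#'   `label` (character scalar), `parent` (label of the enclosing membrane, or
#'   `NA` for the skin), `variables` (named numeric vector of initial values;
#'   may be empty), and optionally `enzymes` (character vector naming which of
#'   this membrane's variables are enzymes).
#' @param programs list of [enps_program()] objects; each carries the label of
#'   its membrane.
#' @return an object of class `enps_system`.
#' @examples
#' sys <- enps_system(
#'   membranes = list(
#'     list(label = "skin", parent = NA, variables = c(a = 3, b = 0))),
#'   programs = list(
#'     enps_program("2 * a", c(b = 1), membrane = "skin", name = "double")))
#' enps_run(sys, enps_policy(mode = "parallel", max_steps = 1))$config
#' @export
enps_system <- function(membranes, programs = list()) {
  if (length(membranes) < 1L) stop("at least one membrane is required",
                                   call. = FALSE)
  labels <- vapply(membranes, function(m) as.character(m$label), character(1))
  if (anyDuplicated(labels))
    stop("duplicate membrane label: ",
         labels[duplicated(labels)][1L], call. = FALSE)
  parents <- vapply(membranes, function(m) {
    p <- m$parent
    if (is.null(p) || length(p) == 0L || is.na(p)) NA_character_
    else as.character(p)
  }, character(1))
  roots <- which(is.na(parents))
  if (length(roots) != 1L)
    stop("membrane structure must have exactly one root (the skin), found ",
         length(roots), call. = FALSE)
  bad <- !is.na(parents) & !(parents %in% labels)
  if (any(bad))
    stop("membrane '", labels[bad][1L], "' names unknown parent '",
         parents[bad][1L], "'", call. = FALSE)
  # acyclicity: walk to the root from every node
  for (i in seq_along(labels)) {
    seen <- character(0); l <- labels[i]
    while (!is.na(parents[match(l, labels)])) {
      if (l %in% seen) stop("membrane structure contains a cycle through '",
                            l, "'", call. = FALSE)
      seen <- c(seen, l)
      l <- parents[match(l, labels)]
    }
  }

  var_names <- character(0); var_values <- numeric(0)
  var_membrane <- character(0); enzyme_names <- character(0)
  for (m in membranes) {
    v <- m$variables
    if (is.null(v)) v <- numeric(0)
    if (length(v) && (is.null(names(v)) || any(!nzchar(names(v)))))
      stop("variables of membrane '", m$label, "' must be named",
           call. = FALSE)
    ez <- m$enzymes
    if (is.null(ez)) ez <- character(0)
    if (length(ez) && !all(ez %in% names(v)))
      stop("enzyme(s) ", paste(setdiff(ez, names(v)), collapse = ", "),
           " not declared as variables of membrane '", m$label, "'",
           call. = FALSE)
    var_names <- c(var_names, names(v))
    var_values <- c(var_values, as.numeric(v))
    var_membrane <- c(var_membrane, rep(as.character(m$label), length(v)))
    enzyme_names <- c(enzyme_names, ez)
  }
  if (anyDuplicated(var_names))
    stop("variable name '", var_names[duplicated(var_names)][1L],
         "' declared in more than one membrane", call. = FALSE)
  names(var_values) <- var_names

  if (length(programs)) {
    ok <- vapply(programs, inherits, logical(1), what = "enps_program")
    if (!all(ok)) stop("programs must be enps_program objects", call. = FALSE)
    pm <- vapply(programs, `[[`, character(1), "membrane")
    if (!all(pm %in% labels))
      stop("program assigned to unknown membrane '",
           setdiff(pm, labels)[1L], "'", call. = FALSE)
    refs <- unique(c(
      unlist(lapply(programs, `[[`, "operands"), use.names = FALSE),
      unlist(lapply(programs, `[[`, "targets"), use.names = FALSE),
      stats::na.omit(vapply(programs, `[[`, character(1), "enzyme"))))
    missing <- setdiff(refs, var_names)
    if (length(missing))
      stop("program references undeclared variable(s): ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    # pre-resolve target/operand positions so the engine never matches
    # names against the (possibly very large) variable vector per rule
    tl <- lengths(lapply(programs, `[[`, "targets"))
    ti <- match(unlist(lapply(programs, `[[`, "targets"), use.names = FALSE),
                var_names)
    ol <- lengths(lapply(programs, `[[`, "operands"))
    oi <- match(unlist(lapply(programs, `[[`, "operands"),
                       use.names = FALSE), var_names)
    tend <- cumsum(tl); tstart <- tend - tl + 1L
    oend <- cumsum(ol); ostart <- oend - ol + 1L
    ti <- as.integer(ti); oi <- as.integer(oi)
    for (k in seq_along(programs)) {
      programs[[k]]$target_idx <- ti[tstart[k]:tend[k]]
      programs[[k]]$operand_idx <-
        if (ol[k]) oi[ostart[k]:oend[k]] else integer(0)
    }
  }

  structure(list(
    membranes = membranes,
    labels = labels,
    parents = parents,
    skin = labels[roots],
    programs = programs,
    program_membranes = if (length(programs))
      vapply(programs, `[[`, character(1), "membrane") else character(0),
    program_groups = if (length(programs))
      vapply(programs, `[[`, character(1), "group") else character(0),
    initial_values = var_values,
    var_membrane = stats::setNames(var_membrane, var_names),
    enzymes = enzyme_names
  ), class = "enps_system")
}

#' Initial configuration of an ENPS
#'
#' @param system an [enps_system()].
#' @return an `enps_config`: the system's initial variable values at step 0.
#' @export
enps_init <- function(system) {
  stopifnot(inherits(system, "enps_system"))
  structure(list(values = system$initial_values, step_index = 0L),
            class = "enps_config")
}

#' Execution policy for an ENPS run
#'
#' Resolves the scheduling semantics the formal model leaves open.
#'
#' * `mode = "staged"`: [enps_run()] follows an explicit schedule, executing
#'   one synchronous parallel step per schedule entry (each entry selects
#'   membranes and/or program groups).
#' * `mode = "parallel"`: every membrane is active at every step; the run
#'   stops when the halt variable reaches its threshold, when no program
#'   fires, optionally at a fixed point, or fails after `max_steps`.
#' * `consumption = "non-consuming"` (default): production operands keep
#'   their values when a rule fires. `"consuming"` is the classical NPS
#'   behaviour where every operand of a fired rule is zeroed before
#'   repartition increments are added.
#'
#' Repartition targets of fired rules are always reset to 0 at the start of
#' the step and then receive the summed increments of all rules that target
#' them (assignment semantics); variables no fired rule targets are untouched.
#'
#' @param mode `"staged"` or `"parallel"`.
#' @param consumption `"non-consuming"` or `"consuming"`.
#' @param max_steps guard for `"parallel"` mode; exceeding it raises a
#'   classed non-halting error (`enps_nonhalting_error`).
#' @param halt_variable optional variable name: the run halts once its value
#'   reaches `halt_threshold`.
#' @param halt_threshold numeric threshold for `halt_variable` (default 1).
#' @param halt_on_fixpoint in `"parallel"` mode, also halt when a step leaves
#'   every variable unchanged.
#' @return an object of class `enps_policy`.
#' @export
enps_policy <- function(mode = c("staged", "parallel"),
                        consumption = c("non-consuming", "consuming"),
                        max_steps = 1000L,
                        halt_variable = NULL, halt_threshold = 1,
                        halt_on_fixpoint = FALSE) {
  mode <- match.arg(mode)
  consumption <- match.arg(consumption)
  max_steps <- as.integer(max_steps)
  if (is.na(max_steps) || max_steps < 1L)
    stop("max_steps must be a positive integer", call. = FALSE)
  structure(list(mode = mode, consumption = consumption,
                 max_steps = max_steps,
                 halt_variable = halt_variable,
                 halt_threshold = halt_threshold,
                 halt_on_fixpoint = isTRUE(halt_on_fixpoint)),
            class = "enps_policy")
}

#' @export
print.enps_program <- function(x, ...) {
  ez <- if (is.na(x$enzyme)) "" else
    sprintf(" |%s (%s)", x$enzyme, if (x$comparison == "ge") ">=" else ">")
  rep_str <- paste(sprintf("%g|%s", x$coefficients, x$targets),
                   collapse = " + ")
  cat(sprintf("<enps_program%s> [membrane %s] %s%s -> %s\n",
              if (is.na(x$name)) "" else paste0(" ", x$name),
              x$membrane, deparse1(x$production), ez, rep_str))
  invisible(x)
}

#' @export
print.enps_system <- function(x, ...) {
  cat(sprintf("<enps_system> %d membranes (skin: %s), %d variables (%d enzymes), %d programs\n",
              length(x$labels), x$skin, length(x$initial_values),
              length(x$enzymes), length(x$programs)))
  invisible(x)
}

#' @export
print.enps_config <- function(x, ...) {
  cat(sprintf("<enps_config> step %d, %d variables\n",
              x$step_index, length(x$values)))
  if (length(x$values) <= 20L) print(x$values)
  invisible(x)
}
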