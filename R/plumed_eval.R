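# Internal evaluator for the emitted PLUMED dialect.  It parses the script
# into an ordered expression graph and recomputes the CV on raw coordinates,
# standing in for the `plumed driver` recalculation check.  It is a test
# harness for files this package emits, not a general PLUMED replacement.

PLUMED_FUNS <- c("+", "-", "*", "/", "(", "exp", "tanh", "max")

#' Parse a PLUMED script in the package dialect
#'
#' Accepts exactly what \code{\link{render_plumed}} can produce: comments,
#' \code{WHOLEMOLECULES}, an optional \code{FIT_TO_TEMPLATE} directive,
#' \code{POSITION} lines and \code{CUSTOM} expression lines (with
#' \code{PERIODIC=NO} and functions drawn from
#' \{+, -, *, /, exp, tanh, max\}).  Forward references, duplicate labels,
#' unknown directives and out-of-dialect functions are parse errors naming
#' the line.
#'
#' @param x a \code{plumed_script}, a character vector of lines, or the path
#'   to a script file.
#' @return An object of class \code{expr_graph}: ordered nodes, a
#'   \code{has_fit} flag, the referenced template path and the serials used.
#' @export
parse_plumed <- function(x) {
  lines <- if (inherits(x, "plumed_script")) x$lines
           else if (is.character(x) && length(x) == 1L && file.exists(x) &&
                    !grepl("\n", x)) readLines(x, warn = FALSE)
           else if (is.character(x)) unlist(strsplit(x, "\n", fixed = TRUE))
           else stopf("cannot parse object of class %s", class(x)[1L])
  nodes <- list()
  defined <- character(0)   # labels usable as ARG (includes p*.x/.y/.z)
  labels <- character(0)    # bare labels, for duplicate detection
  used <- character(0)
  has_fit <- FALSE
  template <- NA_character_
  serials <- integer(0)
  perr <- function(i, fmt, ...) {
    stopf("PLUMED parse error at line %d: %s", i, sprintf(fmt, ...))
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (grepl("^WHOLEMOLECULES\\s", line)) {
      if (!grepl("^WHOLEMOLECULES ENTITY0=[0-9]+(,[0-9]+)*$", line)) {
        perr(i, "malformed WHOLEMOLECULES directive")
      }
      next
    }
    if (grepl("^FIT_TO_TEMPLATE\\s", line)) {
      m <- regmatches(line,
        regexec("^FIT_TO_TEMPLATE STRIDE=1 REFERENCE=(\\S+) TYPE=OPTIMAL$", line))[[1L]]
      if (length(m) != 2L) perr(i, "malformed FIT_TO_TEMPLATE directive")
      has_fit <- TRUE
      template <- m[2L]
      next
    }
    m <- regmatches(line, regexec("^([A-Za-z][A-Za-z0-9_]*):\\s+(.*)$", line))[[1L]]
    if (length(m) != 3L) perr(i, "expected '<label>: <directive>', got '%s'", line)
    label <- m[2L]; body <- m[3L]
    if (label %in% labels) perr(i, "duplicate label '%s'", label)
    if (grepl("^POSITION\\s", body)) {
      pm <- regmatches(body, regexec("^POSITION ATOM=([0-9]+)$", body))[[1L]]
      if (length(pm) != 2L) perr(i, "malformed POSITION directive")
      serial <- as.integer(pm[2L])
      nodes[[length(nodes) + 1L]] <- list(kind = "position", label = label,
                                          serial = serial, line = i)
      serials <- c(serials, serial)
      labels <- c(labels, label)
      defined <- c(defined, paste0(label, c(".x", ".y", ".z")))
    } else if (grepl("^(CUSTOM|MATHEVAL)\\s", body)) {
      cm <- regmatches(body, regexec(
        "^(CUSTOM|MATHEVAL) ARG=(\\S+)( VAR=(\\S+))? FUNC=(\\S+) PERIODIC=NO$",
        body))[[1L]]
      if (length(cm) != 6L) perr(i, "malformed CUSTOM directive")
      args <- strsplit(cm[3L], ",", fixed = TRUE)[[1L]]
      vars <- if (nzchar(cm[5L])) strsplit(cm[5L], ",", fixed = TRUE)[[1L]]
              else if (length(args) == 1L) "x"
              else perr(i, "VAR is required when a CUSTOM line has several ARGs")
      if (length(vars) != length(args)) perr(i, "VAR and ARG counts differ")
      missing <- setdiff(args, defined)
      if (length(missing) > 0L) {
        perr(i, "ARG '%s' is not defined on an earlier line", missing[1L])
      }
      expr <- tryCatch(str2lang(cm[6L]),
                       error = function(e) perr(i, "unparseable FUNC: %s",
                                                conditionMessage(e)))
      check_plumed_expr(expr, vars, i)
      nodes[[length(nodes) + 1L]] <- list(kind = "custom", label = label,
                                          args = args, vars = vars,
                                          expr = expr, line = i)
      labels <- c(labels, label)
      defined <- c(defined, label)
      used <- union(used, args)
    } else {
      perr(i, "unknown directive '%s'", strsplit(body, "\\s")[[1L]][1L])
    }
  }
  custom_labels <- vapply(Filter(function(n) n$kind == "custom", nodes),
                          `[[`, "", "label")
  if (length(custom_labels) == 0L) stopf("PLUMED script defines no expression nodes")
  terminal <- setdiff(custom_labels, used)
  if (length(terminal) != 1L) {
    stopf("PLUMED script must have exactly one terminal CV node (found: %s)",
          paste(terminal, collapse = ", "))
  }
  structure(list(nodes = nodes, has_fit = has_fit, template = template,
                 serials = serials, output = terminal),
            class = "expr_graph")
}

# Reject anything outside the dialect: functions in PLUMED_FUNS, symbols in
# `vars`, numeric literals.
check_plumed_expr <- function(e, vars, lineno) {
  if (is.numeric(e)) return(invisible(TRUE))
  if (is.symbol(e)) {
    if (!as.character(e) %in% vars) {
      stopf("PLUMED parse error at line %d: unknown variable '%s' in FUNC",
            lineno, as.character(e))
    }
    return(invisible(TRUE))
  }
  if (is.call(e)) {
    fn <- as.character(e[[1L]])
    if (!fn %in% PLUMED_FUNS) {
      stopf("PLUMED parse error at line %d: function '%s' is outside the dialect (%s)",
            lineno, fn, paste(setdiff(PLUMED_FUNS, "("), collapse = ", "))
    }
    for (k in seq_along(e)[-1L]) check_plumed_expr(e[[k]], vars, lineno)
    return(invisible(TRUE))
  }
  stopf("PLUMED parse error at line %d: unsupported token in FUNC", lineno)
}

#' @export
print.expr_graph <- function(x, ...) {
  cat(sprintf("<expr_graph> %d nodes, fit=%s, output '%s'\n",
              length(x$nodes), x$has_fit, x$output))
  invisible(x)
}

#' Evaluate the CV encoded in a parsed PLUMED script
#'
#' Applies the template fit (when the script carries a FIT_TO_TEMPLATE
#' directive), fills the POSITION nodes from the frame, and evaluates the
#' expression nodes in file order.  The result is the CV in original units,
#' matching the in-memory pipeline to the script's printed weight precision.
#'
#' @param graph an \code{\link{parse_plumed}} result.
#' @param frame N x 3 coordinates in nm.
#' @param reference the \code{reference_structure} whose coordinates serve as
#'   the fitting template and whose serials map POSITION atoms to rows.
#' @return The CV value (scalar, original units).
#' @export
evaluate_plumed <- function(graph, frame, reference) {
  frame <- as.matrix(frame)
  if (nrow(frame) != reference$atom_count) {
    stopf("frame has %d atoms but the reference has %d",
          nrow(frame), reference$atom_count)
  }
  if (graph$has_fit) {
    sup <- kabsch_superpose(frame, reference$coords)
    frame <- apply_superposition(sup, frame)
  }
  env <- new.env(parent = baseenv())
  values <- list()
  for (node in graph$nodes) {
    if (node$kind == "position") {
      row <- match(node$serial, reference$atom_serials)
      if (is.na(row)) {
        stopf("POSITION ATOM=%d does not match any reference serial", node$serial)
      }
      values[[paste0(node$label, ".x")]] <- frame[row, 1L]
      values[[paste0(node$label, ".y")]] <- frame[row, 2L]
      values[[paste0(node$label, ".z")]] <- frame[row, 3L]
    } else {
      argvals <- values[node$args]
      names(argvals) <- node$vars
      values[[node$label]] <- eval(node$expr,
                                   envir = list2env(argvals, parent = baseenv()))
    }
  }
  values[[graph$output]]
}

#' Recalculate the CV along a trajectory (driver mode)
#'
#' Evaluates the exported CV for every frame, mimicking the COLVAR output of
#' \code{plumed driver}: two whitespace-separated columns, frame index and CV.
#'
#' @param graph an \code{expr_graph} (or anything \code{\link{parse_plumed}}
#'   accepts).
#' @param trajectory a \code{trajectory}.
#' @param reference the matching \code{reference_structure}.
#' @param path optional output file; when given, a COLVAR-style file is
#'   written.
#' @return Numeric vector of CV values, one per frame (invisibly when
#'   \code{path} is given).
#' @export
plumed_driver <- function(graph, trajectory, reference, path = NULL) {
  if (!inherits(graph, "expr_graph")) graph <- parse_plumed(graph)
  values <- vapply(seq_len(trajectory$frame_count), function(fr) {
    evaluate_plumed(graph, trajectory$coords[fr, , , drop = TRUE], reference)
  }, numeric(1))
  if (!is.null(path)) {
    writeLines(c("#! FIELDS time cv",
                 sprintf("%d %.9g", seq_along(values), values)), path)
    return(invisible(values))
  }
  values
}
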