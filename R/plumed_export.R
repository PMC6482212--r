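# Serialize the trained network into a PLUMED input file.  Every neuron
# becomes one CUSTOM expression line with inlined numeric weights, so the
# file runs in stock PLUMED with no plugins; the final line maps the scaled
# network output back to original CV units.

#' Render the trained network as a PLUMED input
#'
#' The emitted script contains, in order: a \code{WHOLEMOLECULES} directive
#' over the analysis atoms; unless \code{nofit}, a
#' \code{FIT_TO_TEMPLATE STRIDE=1 REFERENCE=<template> TYPE=OPTIMAL} line
#' (least-squares superposition, matching \code{\link{kabsch_superpose}});
#' one \code{POSITION} line per analysis atom using the original serial
#' numbers; per-atom scaled inputs dividing .x/.y/.z by the box edges; one
#' expression line per hidden/output neuron (affine combination with inlined
#' weights wrapped in its activation); and a final line mapping the scaled
#' output through \code{cv_min + (cv_max - cv_min) * out}.  Labels follow a
#' fixed scheme (\code{p<serial>}, \code{sx_<i>}/\code{sy_<i>}/\code{sz_<i>},
#' \code{l<layer>_<j>}, final \code{cv_label}) so the file is greppable and
#' byte-deterministic for a given network.
#'
#' @param net a trained \code{network_spec}; its input size must equal
#'   3 x atom count of \code{reference}.
#' @param reference the \code{reference_structure} used in training.
#' @param scaling the \code{target_scaling} from \code{\link{scale_targets}}.
#' @param nofit omit the FIT_TO_TEMPLATE line (pre-fitted trajectories).
#' @param cv_label label of the final CV line (default \code{"annCV"}).
#' @param template_path filename the FIT_TO_TEMPLATE line references
#'   (write it with \code{\link{write_template_pdb}}).
#' @param digits significant digits used to print weights (default 9; the
#'   round-trip error of the evaluator stays below 1e-6 at this precision).
#' @return An object of class \code{plumed_script} (fields \code{lines},
#'   \code{template_path}, \code{numeric_precision}, \code{cv_label}).
#' @seealso \code{\link{write_plumed}}, \code{\link{parse_plumed}},
#'   \code{\link{renumber_atoms}}
#' @export
render_plumed <- function(net, reference, scaling, nofit = FALSE,
                          cv_label = "annCV", template_path = "template.pdb",
                          digits = 9L) {
  if (!inherits(net, "network_spec")) stopf("`net` must be a network_spec")
  if (!inherits(reference, "reference_structure")) {
    stopf("`reference` must be a reference_structure")
  }
  if (!inherits(scaling, "target_scaling")) {
    stopf("`scaling` must come from scale_targets()")
  }
  n <- reference$atom_count
  if (net$layer_sizes[1L] != 3L * n) {
    stopf("network expects %d inputs but the reference has %d atoms (3N = %d)",
          net$layer_sizes[1L], n, 3L * n)
  }
  for (a in net$activations) plumed_activation(a, "u")  # validate up front
  serials <- reference$atom_serials
  l <- box_lengths(reference$box)
  num <- function(x) fmt_num(x, digits)
  lines <- c(
    "# PLUMED input generated by cvnet: neural-network collective variable",
    sprintf("# architecture %s, activations %s",
            paste(net$layer_sizes, collapse = "-"),
            paste(net$activations, collapse = "/")),
    sprintf("WHOLEMOLECULES ENTITY0=%s", paste(serials, collapse = ",")))
  if (!nofit) {
    lines <- c(lines, sprintf("FIT_TO_TEMPLATE STRIDE=1 REFERENCE=%s TYPE=OPTIMAL",
                              template_path))
  }
  lines <- c(lines, sprintf("p%d: POSITION ATOM=%d", serials, serials))
  for (i in seq_len(n)) {
    lines <- c(lines,
      sprintf("sx_%d: CUSTOM ARG=p%d.x FUNC=x/%s PERIODIC=NO", i, serials[i], num(l[1])),
      sprintf("sy_%d: CUSTOM ARG=p%d.y FUNC=x/%s PERIODIC=NO", i, serials[i], num(l[2])),
      sprintf("sz_%d: CUSTOM ARG=p%d.z FUNC=x/%s PERIODIC=NO", i, serials[i], num(l[3])))
  }
  in_labels <- as.vector(t(cbind(sprintf("sx_%d", 1:n),
                                 sprintf("sy_%d", 1:n),
                                 sprintf("sz_%d", 1:n))))
  prev <- in_labels
  for (layer in seq_along(net$weights)) {
    w <- net$weights[[layer]]; b <- net$biases[[layer]]
    labels <- sprintf("l%d_%d", layer, seq_len(ncol(w)))
    vars <- sprintf("v%d", seq_along(prev))
    for (j in seq_len(ncol(w))) {
      affine <- affine_expr(w[, j], vars, b[j], digits)
      lines <- c(lines, sprintf("%s: CUSTOM ARG=%s VAR=%s FUNC=%s PERIODIC=NO",
                                labels[j], paste(prev, collapse = ","),
                                paste(vars, collapse = ","),
                                plumed_activation(net$activations[layer], affine)))
    }
    prev <- labels
  }
  lines <- c(lines, sprintf("%s: CUSTOM ARG=%s VAR=v1 FUNC=%s+%s*v1 PERIODIC=NO",
                            cv_label, prev[1L], num(scaling$cv_min),
                            num(scaling$cv_max - scaling$cv_min)))
  structure(list(lines = lines, template_path = template_path,
                 numeric_precision = as.integer(digits), cv_label = cv_label),
            class = "plumed_script")
}

# "w1*v1+w2*v2-...-b" with explicit signs; deterministic text.
affine_expr <- function(w, vars, b, digits) {
  terms <- character(length(w))
  for (k in seq_along(w)) {
    sgn <- if (w[k] < 0) "-" else if (k == 1L) "" else "+"
    terms[k] <- paste0(sgn, fmt_num(abs(w[k]), digits), "*", vars[k])
  }
  bias <- paste0(if (b < 0) "-" else "+", fmt_num(abs(b), digits))
  paste0(paste(terms, collapse = ""), bias)
}

# Render activation `name` applied to expression string `u`, using only the
# dialect's function set {+,-,*,/,exp,tanh,max}.
plumed_activation <- function(name, u) {
  switch(name,
    linear   = u,
    sigmoid  = sprintf("1/(1+exp(-(%s)))", u),
    tanh     = sprintf("tanh(%s)", u),
    relu     = sprintf("max(%s,0)", u),
    softsign = sprintf("(%s)/(1+max(%s,0-(%s)))", u, u, u),
    elu      = sprintf("max(%s,0)+exp(0-max(0-(%s),0))-1", u, u),
    stopf("activation '%s' cannot be rendered as a PLUMED expression (supported: %s)",
          name, paste(ACTIVATIONS, collapse = ", ")))
}

#' @export
print.plumed_script <- function(x, ...) {
  cat(sprintf("<plumed_script> %d lines, CV label '%s', template %s\n",
              length(x$lines), x$cv_label, x$template_path))
  invisible(x)
}

#' Write a PLUMED script to disk
#' @param script a \code{plumed_script}.
#' @param path output path (conventionally \code{plumed.dat}).
#' @return \code{path}, invisibly.
#' @export
write_plumed <- function(script, path) {
  writeLines(script$lines, path)
  invisible(path)
}

#' Write the fitting template PDB
#'
#' Re-writes the reference structure as the template the FIT_TO_TEMPLATE line
#' references, with occupancy and beta columns set to 1.00 (PLUMED uses them
#' as alignment/displacement weights and rejects empty columns).
#'
#' @param reference a \code{reference_structure}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_template_pdb <- function(reference, path) {
  elety <- if (!is.null(reference$atom)) reference$atom$elety else NULL
  lines <- format_pdb_atoms(reference$coords * 10, reference$atom_serials,
                            occ = 1, beta = 1, elety = elety)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Rewrite atom serial numbers in a PLUMED script
#'
#' When the training set and the simulated system number atoms differently
#' (a structure-set numbering vs. a force-field topology), every atom
#' reference in the script must be renumbered before use.  Only
#' \code{ATOM=} references and the \code{WHOLEMOLECULES} entity list are
#' rewritten; labels and weights are untouched, so the output is otherwise
#' byte-identical.
#'
#' @param script a \code{plumed_script}.
#' @param mapping named integer vector: \code{mapping[["old"]] = new}.
#' @return The renumbered \code{plumed_script}.
#' @export
renumber_atoms <- function(script, mapping) {
  if (is.null(names(mapping))) stopf("`mapping` must be a named vector (old -> new)")
  map1 <- function(old) {
    new <- mapping[as.character(old)]
    if (any(is.na(new))) {
      stopf("no mapping for atom serial %s",
            paste(old[is.na(new)], collapse = ", "))
    }
    as.integer(new)
  }
  lines <- script$lines
  for (i in seq_along(lines)) {
    if (grepl("^WHOLEMOLECULES ", lines[i])) {
      old <- as.integer(strsplit(sub("^WHOLEMOLECULES ENTITY0=", "", lines[i]),
                                 ",", fixed = TRUE)[[1L]])
      lines[i] <- sprintf("WHOLEMOLECULES ENTITY0=%s",
                          paste(map1(old), collapse = ","))
    } else if (grepl(" POSITION ATOM=", lines[i])) {
      old <- as.integer(sub(".* POSITION ATOM=([0-9]+)$", "\\1", lines[i]))
      lines[i] <- sub("ATOM=[0-9]+$", paste0("ATOM=", map1(old)), lines[i])
    }
  }
  script$lines <- lines
  script
}
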