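#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fingerprint a parameter set
#'
#' Stable content hash used to check that traces, schedules, results and
#' microsimulation ledgers were all produced from the same parameterization.
#'
#' @param p A `param_set`.
#' @return A character scalar hash.
#' @export
param_fingerprint <- function(p) {
  stopifnot(inherits(p, "param_set"))
  q <- unclass(p)
  # cached life-table data is derived, not primary content
  q$structural$life_table_data <- NULL
  rlang::hash(q)
}

#' Read a value inside a parameter set by dotted path
#'
#' Paths address nested fields, e.g. `"costs.monthly_inpatient"` or
#' `"mortality_no_icd.sudden_cardiac.value"`. A path ending in a block that
#' carries a `value` key resolves to that value
#' (`"utilities.annual_utility_well"` returns the utility itself).
#'
#' @param p A `param_set`.
#' @param path Dotted path string.
#' @return The numeric value at the path.
#' @export
param_get_path <- function(p, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- p
  for (k in parts) {
    if (!is.list(node) || is.null(node[[k]])) {
      stop("unknown parameter path: ", path, call. = FALSE)
    }
    node <- node[[k]]
  }
  if (is.list(node) && !is.null(node$value)) node <- node$value
  if (!is.numeric(node)) stop("path does not resolve to a numeric value: ", path, call. = FALSE)
  node
}

#' Substitute a value inside a parameter set by dotted path
#'
#' The counterpart of [param_get_path()]. Two scaling pseudo-paths are
#' understood for one-way sensitivity axes that vary a whole block at once:
#' a path ending in `"@scale"` multiplies every probability/cost/utility
#' value in the block by `value` (duration fields are left untouched), e.g.
#' `"mortality_no_icd.@scale"` for the conventional-therapy mortality axis.
#'
#' @param p A `param_set`.
#' @param path Dotted path string, optionally ending in `@scale`.
#' @param value Replacement value (or multiplier for `@scale`).
#' @return The modified `param_set` (not re-validated; see [validate_param_set()]).
#' @export
param_set_path <- function(p, path, value) {
  stopifnot(is.numeric(value), length(value) == 1L)
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (parts[length(parts)] == "@scale") {
    parts <- parts[-length(parts)]
    block <- p
    for (k in parts) block <- block[[k]]
    p <- .assign_path(p, parts, .scale_block(block, value))
    return(p)
  }
  node <- p
  for (k in parts) {
    if (!is.list(node) || is.null(node[[k]])) {
      stop("unknown parameter path: ", path, call. = FALSE)
    }
    node <- node[[k]]
  }
  if (is.list(node) && !is.null(node$value)) {
    node$value <- value
  } else {
    node <- value
  }
  .assign_path(p, parts, node)
}

.assign_path <- function(p, parts, value) {
  if (length(parts) == 1L) {
    p[[parts]] <- value
    return(p)
  }
  p[[parts[1L]]] <- .assign_path(p[[parts[1L]]], parts[-1L], value)
  p
}

.scale_block <- function(block, f) {
  if (is.numeric(block)) return(block * f)
  if (!is.list(block)) return(block)
  for (k in names(block)) {
    if (grepl("duration|causes|basis|dist", k)) next
    if (is.list(block[[k]]) && !is.null(block[[k]]$value)) {
      block[[k]]$value <- block[[k]]$value * f
    } else if (is.numeric(block[[k]])) {
      block[[k]] <- block[[k]] * f
    } else if (is.list(block[[k]])) {
      block[[k]] <- .scale_block(block[[k]], f)
    }
  }
  block
}
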