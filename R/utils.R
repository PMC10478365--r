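#' Valid interaction types
#'
#' The seven interaction categories a typed association network may
#' carry: five regulatory categories plus generic associations and
#' physical protein-protein interactions.
#'
#' @return Character vector of the seven valid type labels.
#' @export
#' @examples
#' interaction_types()
interaction_types <- function() {
  c(
    "activity_regulation", "degradation_regulation",
    "expression_regulation", "transport_regulation",
    "downregulation", "associative", "protein_protein"
  )
}

#' Default regulatory interaction types
#'
#' All interaction categories except generic associations and physical
#' protein-protein binding. Degradation regulation is included: it is a
#' regulation category even though descriptions of regulatory networks
#' often enumerate only expression/activity/transport regulation.
#'
#' @return Character vector of regulatory type labels.
#' @export
regulatory_types <- function() {
  setdiff(interaction_types(), c("associative", "protein_protein"))
}

# case-insensitive symbol key; symbols are case-preserved but matched
# case-insensitively across files (source databases differ in casing)
sym_key <- function(x) toupper(x)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must lie in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

check_itype <- function(itype, line_no = NULL) {
  bad <- setdiff(unique(itype), interaction_types())
  if (length(bad) > 0L) {
    where <- if (!is.null(line_no)) {
      idx <- which(itype %in% bad)
      sprintf(" (line %s)", paste(line_no[idx], collapse = ", "))
    } else {
      ""
    }
    abort(sprintf(
      "Unknown interaction type(s): %s%s. Valid types: %s.",
      paste(unique(bad), collapse = ", "), where,
      paste(interaction_types(), collapse = ", ")
    ))
  }
  invisible(itype)
}

valid_go_id <- function(x) grepl("^GO:\\d{7}$", x)

check_go_ids <- function(ids) {
  bad <- unique(ids[!valid_go_id(ids)])
  if (length(bad) > 0L) {
    abort(sprintf(
      "Malformed GO process id(s): %s (expected the form GO:0000000).",
      paste(head(bad, 5L), collapse = ", ")
    ))
  }
  invisible(ids)
}
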