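#' Canonical name of a gene combination
#'
#' Strain names aggregate studies in which the order of the genetic
#' interventions varied, so a combination gets one deterministic name:
#' the distinct gene symbols sorted alphabetically (case-insensitive,
#' byte-order tie-break) and joined with `";"`. The wild type (empty gene
#' set) gets the reserved name `"WT"`, never the empty string.
#'
#' @param genes Character vector of gene symbols (duplicates and empty
#'   strings are dropped).
#' @return A single string, e.g. `canonical_name(c("daf-2", "daf-16"))`
#'   is `"daf-16;daf-2"`.
#' @examples
#' canonical_name(c("daf-2", "daf-16"))
#' canonical_name(character(0))
#' @export
canonical_name <- function(genes) {
  genes <- unique(trimws(as.character(genes)))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0) {
    return(wt_name())
  }
  ord <- order(tolower(genes), genes, method = "radix")
  paste(genes[ord], collapse = ";")
}

#' Reserved wild-type strain name
#' @return The string `"WT"`.
#' @export
wt_name <- function() "WT"

#' Gene set of a canonical strain name
#'
#' Inverse of [canonical_name()]: splits a canonical name back into its
#' gene symbols. The wild-type name maps to an empty set.
#'
#' @param name Canonical strain name.
#' @return Character vector of gene symbols (sorted, possibly empty).
#' @export
gene_set <- function(name) {
  if (length(name) != 1 || is.na(name)) {
    abort("`name` must be a single non-missing strain name.")
  }
  if (identical(name, wt_name()) || !nzchar(name)) {
    return(character(0))
  }
  strsplit(name, ";", fixed = TRUE)[[1]]
}

#' Direction implied by an intervention type
#'
#' Loss-of-function mutations, knockouts and RNAi inhibit gene function;
#' gain-of-function mutations and overexpression activate it.
#'
#' @param intervention_type Character vector drawn from the controlled
#'   vocabulary `r paste0('"', names(INTERVENTION_DIRECTIONS), '"', collapse = ", ")`.
#' @return Character vector of `"inhibit"` / `"activate"` (`NA` for empty
#'   or unknown types).
#' @export
intervention_direction <- function(intervention_type) {
  unname(INTERVENTION_DIRECTIONS[as.character(intervention_type)])
}
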