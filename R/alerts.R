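# Structural alerts for human aromatase toxicity: a registry of 21 SMARTS
# fragments, substructure matching, and the shared-alert rule behind
# mechanistic similarity. Both toxic- and non-toxic-labelled alerts take
# part in mechanistic similarity; the label is carried for reporting only.

#' Load a structural-alert registry
#'
#' By default loads the 21-alert registry for human aromatase toxicity
#' shipped with the package. A user registry for another endpoint can be
#' supplied through the same tab-separated format (columns `alert_id`,
#' `smarts`, `label`, optional `smarts_adjusted`).
#'
#' Every pattern is compiled at load time; a pattern the matcher cannot
#' compile raises a configuration error naming the alert. If a shipped
#' pattern ever needed adjustment to compile, the adjusted form would be
#' recorded in the `smarts_adjusted` column and reported -- the original
#' string is never edited in place.
#'
#' @param path registry file; `NULL` for the shipped aromatase registry.
#' @return a `rax_alerts` data frame with columns `alert_id`, `smarts`,
#'   `label` and `pattern` (the SMARTS actually matched).
#' @examples
#' reg <- load_alerts()
#' nrow(reg)  # 21
#' @export
load_alerts <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aromatase_alerts.tsv",
                        package = "intrax", mustWork = TRUE)
  }
  reg <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = character(0))
  need <- c("alert_id", "smarts", "label")
  miss <- setdiff(need, names(reg))
  if (length(miss)) {
    stop("alert registry lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (!"smarts_adjusted" %in% names(reg)) reg$smarts_adjusted <- ""
  reg$smarts_adjusted[is.na(reg$smarts_adjusted)] <- ""
  reg$label <- tolower(reg$label)
  if (!all(reg$label %in% c("toxic", "non_toxic"))) {
    stop("alert labels must be 'toxic' or 'non_toxic'")
  }
  reg$pattern <- ifelse(nzchar(reg$smarts_adjusted),
                        reg$smarts_adjusted, reg$smarts)
  # compile check against a trivial probe molecule
  ok <- ChemmineOB::forEachMol("SMILES", "C", function(m) {
    vapply(reg$pattern, function(p) {
      !inherits(try(ChemmineOB::smartsSearch_OB(list(m), p,
                                                uniqueMatches = TRUE),
                    silent = TRUE), "try-error")
    }, logical(1))
  })[[1]]
  if (!all(ok)) {
    stop("alert pattern(s) failed to compile: ",
         paste(reg$alert_id[!ok], collapse = ", "))
  }
  structure(reg[, c("alert_id", "smarts", "label", "pattern")],
            class = c("rax_alerts", "data.frame"))
}

#' Match a structure against an alert registry
#'
#' An alert is matched when its SMARTS has at least one substructure
#' embedding in the structure. Matching is done on the charged parent with
#' aromatic perception on: the alkyl-imidazolium alert requires the
#' aromatic `[n+]` of the cationic form.
#'
#' @param x SMILES string (standardized parent structure).
#' @param registry a `rax_alerts` registry from [load_alerts()].
#' @return character vector of matched `alert_id`s (possibly empty).
#' @examples
#' match_alerts("CC#N", load_alerts())  # SA_3
#' @export
match_alerts <- function(x, registry = load_alerts()) {
  stopifnot(inherits(registry, "rax_alerts"))
  mol <- rax_mol(x)
  hits <- ChemmineOB::forEachMol("SMILES", mol$smiles, function(m) {
    vapply(registry$pattern, function(p) {
      ChemmineOB::smartsSearch_OB(list(m), p, uniqueMatches = TRUE)
    }, numeric(1))
  })[[1]]
  registry$alert_id[hits > 0]
}

#' Alerts shared between a target and a source structure
#'
#' The mechanistic-similarity rule: a source is a mechanistic candidate
#' when it shares at least one structural alert with the target. Both hit
#' sets must come from the same registry.
#'
#' @param target_hits,source_hits character vectors of matched alert ids.
#' @return character vector: the set intersection.
#' @export
shared_alerts <- function(target_hits, source_hits) {
  intersect(target_hits, source_hits)
}
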