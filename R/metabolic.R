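# Metabolic similarity: 5-bit cytochrome P450 isoform-inhibition profiles
# and their Tanimoto comparison. The external inhibition predictor is not
# re-implemented; profiles enter from a file or from a pluggable
# structure -> profile callable.

#' Isoform order of a CYP inhibition profile
#' @export
cyp_isoforms <- c("CYP1A2", "CYP2C9", "CYP2C19", "CYP2D6", "CYP3A4")

#' Load CYP inhibition profiles from CSV
#'
#' Expects a header `id,CYP1A2,CYP2C9,CYP2C19,CYP2D6,CYP3A4` with 0/1
#' entries; `1` marks expected inhibition of the isoform. When the ids of a
#' dataset are supplied, profile rows for unknown compounds are dropped with
#' a warning (they are ignored, not an error).
#'
#' @param path CSV file.
#' @param ids optional character vector of dataset ids used to filter.
#' @return a `rax_profiles` object: a 0/1 integer matrix with one row per
#'   compound id and the five isoforms as columns.
#' @export
load_profiles <- function(path, ids = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("id", cyp_isoforms), names(df))
  if (length(miss)) {
    stop("profile table lacks column(s): ", paste(miss, collapse = ", "))
  }
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    stop("duplicate profile id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  m <- as.matrix(df[, cyp_isoforms])
  mode(m) <- "integer"
  if (anyNA(m) || !all(m %in% c(0L, 1L))) {
    stop("profile entries must be binary (0/1)")
  }
  rownames(m) <- df$id
  if (!is.null(ids)) {
    extra <- setdiff(rownames(m), ids)
    if (length(extra)) {
      warning("ignoring ", length(extra),
              " profile row(s) for compounds not in the dataset: ",
              paste(utils::head(extra, 5), collapse = ", "),
              if (length(extra) > 5) ", ..." else "")
      m <- m[setdiff(rownames(m), extra), , drop = FALSE]
    }
  }
  structure(m, class = c("rax_profiles", class(m)))
}

#' Retrieve one compound's profile, or NULL when unavailable
#' @noRd
profile_for <- function(profiles, id) {
  if (is.null(profiles)) return(NULL)
  if (!id %in% rownames(profiles)) return(NULL)
  as.integer(profiles[id, ])
}

#' Tanimoto similarity of two CYP inhibition profiles
#'
#' Tanimoto over the ordered 5-bit vectors. Two all-zero profiles (neither
#' compound expected to inhibit any isoform) count as identical predicted
#' metabolic behaviour and score 1; the raw Tanimoto would be 0/0.
#'
#' @param a,b 0/1 vectors of length 5 (isoform order
#'   1A2, 2C9, 2C19, 2D6, 3A4).
#' @return similarity in \[0, 1\].
#' @examples
#' metabolic_similarity(c(0, 0, 0, 1, 0), c(0, 0, 0, 1, 0))  # 1
#' metabolic_similarity(c(1, 0, 1, 0, 0), c(1, 0, 0, 0, 0))  # 0.5
#' @export
metabolic_similarity <- function(a, b) {
  if (length(a) != 5L || length(b) != 5L) {
    stop("CYP profiles must have exactly 5 entries")
  }
  tanimoto(a, b, zero_zero = "one")
}
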