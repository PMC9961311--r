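# Case-study fixtures and the synthetic homologous-series generator.
#
# The case-study compounds are the named substances of the two worked
# examples (an alkyl-imidazolium target and a 2-aminobenzothiazole target)
# with SMILES reconstructed from their systematic names; the reconstructed
# SMILES ships next to name and CAS so the reconstruction can be audited.
# The additional, unnamed analogues of the two structural-similarity lists
# are represented by synthetic stand-ins (flagged `synthetic_standin`)
# whose activities reproduce the reported list tallies; their CYP profiles
# are all-zero so they never enter the metabolic list.

#' Case-study fixture datasets
#'
#' Returns the source compounds, targets and CYP profiles of the two
#' worked case studies.
#'
#' @param case `"imidazolium"` (case study 1), `"benzothiazole"` (case
#'   study 2) or `"both"`.
#' @param standins include the synthetic stand-ins for the unnamed
#'   structural analogues (default `TRUE`; without them only the named
#'   compounds remain).
#' @return a list: `dataset` (a `rax_dataset` of source compounds),
#'   `targets` (data frame `id`, `smiles`, `activity`), `profiles`
#'   (a `rax_profiles` matrix covering sources and targets).
#' @examples
#' fx <- case_study_fixtures("benzothiazole")
#' fx$targets$id
#' @export
case_study_fixtures <- function(case = c("both", "imidazolium",
                                         "benzothiazole"),
                                standins = TRUE) {
  case <- match.arg(case)
  cpath <- system.file("extdata", "case_study_compounds.csv",
                       package = "intrax", mustWork = TRUE)
  ppath <- system.file("extdata", "case_study_profiles.csv",
                       package = "intrax", mustWork = TRUE)
  df <- utils::read.csv(cpath, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (case != "both") df <- df[df$case == case, ]
  if (!standins) df <- df[df$provenance != "synthetic_standin", ]
  targets <- df[df$role == "target", c("id", "smiles", "activity")]
  rownames(targets) <- NULL
  sources <- rax_dataset(df[df$role == "source", ],
                         provenance = "case-study fixtures")
  profiles <- load_profiles(ppath)
  profiles <- profiles[rownames(profiles) %in% df$id, , drop = FALSE]
  class(profiles) <- c("rax_profiles", class(unclass(profiles)))
  list(dataset = sources, targets = targets, profiles = profiles)
}

#' Generate a synthetic azole dataset with a known activity rule
#'
#' Builds homologous series that mirror the structure-activity patterns of
#' the case studies, with exact ground truth:
#'
#' * `imidazolium`: 1-alkyl-3-methylimidazolium cations with chain lengths
#'   `chain_range`; active when the N-alkyl chain has at least
#'   `active_chain_min` carbons (the chain-length rule also governing the
#'   alkyl-imidazolium structural alert). Actives carry the CYP profile
#'   `(0,0,0,1,0)`, shorter homologues an all-zero profile.
#' * `benzothiazole`: 2-aminobenzothiazoles with an alkoxy chain of
#'   `alkoxy_range` carbons at ring position 6 (active, profile
#'   `(1,0,1,0,0)`) or position 4 (inactive, profile `(1,0,0,0,0)`).
#'
#' Labels can be flipped with probability `noise` (seeded, deterministic:
#' identical spec and seed give identical output; `noise = 1` flips every
#' label). The pre-noise labels are returned as ground truth.
#'
#' @param series which series to generate.
#' @param chain_range integer chain lengths for the imidazolium series.
#' @param alkoxy_range integer alkoxy lengths for the benzothiazole series.
#' @param active_chain_min chain length from which imidazolium homologues
#'   are active (default 8).
#' @param noise label-flip rate in \[0, 1\].
#' @param seed integer seed driving the noise draws.
#' @return a list: `dataset` (`rax_dataset`, activities after noise),
#'   `profiles` (`rax_profiles`), `truth` (named vector of pre-noise
#'   labels).
#' @examples
#' syn <- synthetic_azoles(series = "imidazolium", chain_range = 2:10)
#' table(syn$dataset$activity)
#' @export
synthetic_azoles <- function(series = c("both", "imidazolium",
                                        "benzothiazole"),
                             chain_range = 2:18, alkoxy_range = 1:6,
                             active_chain_min = 8, noise = 0, seed = 1) {
  series <- match.arg(series)
  stopifnot(noise >= 0, noise <= 1)
  rows <- list(); prof <- list()
  if (series %in% c("both", "imidazolium")) {
    if (length(chain_range) == 0) stop("empty imidazolium series")
    for (n in chain_range) {
      id <- sprintf("IM-C%02d", n)
      active <- n >= active_chain_min
      rows[[id]] <- data.frame(
        id = id, cas = "",
        name = sprintf("1-(C%d-alkyl)-3-methylimidazolium", n),
        smiles = paste0(strrep("C", n), "n1cc[n+](C)c1"),
        activity = if (active) "active" else "inactive",
        series = "imidazolium", stringsAsFactors = FALSE)
      prof[[id]] <- if (active) c(0L, 0L, 0L, 1L, 0L) else integer(5)
    }
  }
  if (series %in% c("both", "benzothiazole")) {
    if (length(alkoxy_range) == 0) stop("empty benzothiazole series")
    for (k in alkoxy_range) {
      id6 <- sprintf("BT6-C%02d", k)
      rows[[id6]] <- data.frame(
        id = id6, cas = "",
        name = sprintf("2-amino-6-(C%d-alkoxy)benzothiazole", k),
        smiles = paste0(strrep("C", k), "Oc1ccc2nc(N)sc2c1"),
        activity = "active", series = "benzothiazole",
        stringsAsFactors = FALSE)
      prof[[id6]] <- c(1L, 0L, 1L, 0L, 0L)
      id4 <- sprintf("BT4-C%02d", k)
      rows[[id4]] <- data.frame(
        id = id4, cas = "",
        name = sprintf("2-amino-4-(C%d-alkoxy)benzothiazole", k),
        smiles = paste0(strrep("C", k), "Oc1cccc2sc(N)nc12"),
        activity = "inactive", series = "benzothiazole",
        stringsAsFactors = FALSE)
      prof[[id4]] <- c(1L, 0L, 0L, 0L, 0L)
    }
  }
  df <- do.call(rbind, rows)
  truth <- stats::setNames(df$activity, df$id)
  if (noise > 0) {
    rng <- local({
      set.seed(seed)
      stats::runif(nrow(df))
    })
    flip <- rng < noise
    df$activity[flip] <- ifelse(df$activity[flip] == "active",
                                "inactive", "active")
  }
  m <- do.call(rbind, prof)
  colnames(m) <- cyp_isoforms
  list(
    dataset = rax_dataset(df, provenance = sprintf(
      "synthetic series=%s noise=%g seed=%d", series, noise, seed)),
    profiles = structure(m, class = c("rax_profiles", class(m))),
    truth = truth
  )
}
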