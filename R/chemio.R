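# Compound records, structure standardization, dataset I/O and the
# curation rules used to prepare the source dataset: potency conversion,
# duplicate reconciliation and azole classification.

.activity_levels <- c("active", "inactive", "unknown")

# Map free-text activity strings onto the qualitative enum. Agonist and
# antagonist calls are both recorded as "active": the endpoint is binding /
# modulation of the enzyme, not its direction.
normalize_activity <- function(x) {
  x0 <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x0))
  out[x0 %in% c("", "na", "unknown")] <- "unknown"
  out[grepl("^active", x0)] <- "active"
  out[x0 == "inactive"] <- "inactive"
  bad <- is.na(out)
  if (any(bad)) {
    stop("unknown activity string(s): ",
         paste(unique(x[bad]), collapse = ", "))
  }
  out
}

#' Standardize a structure to its parent form
#'
#' Splits a SMILES into disconnected fragments, keeps the largest organic
#' fragment (counter-ions removed; ties broken by carbon count, then by the
#' lexicographically smallest canonical SMILES), and preserves formal
#' charges on the retained fragment -- a permanently charged imidazolium
#' cation stays charged. The structure key emitted for duplicate detection
#' is the standard InChI of the parent, whose mobile-hydrogen layer collapses
#' tautomers deterministically.
#'
#' @param smiles a single SMILES string.
#' @return a list with elements `smiles_input`, `smiles_parent` (canonical
#'   SMILES of the parent) and `structure_key` (standard InChI).
#' @examples
#' standardize_smiles("CC[n+]1ccn(C)c1.[Cl-]")$smiles_parent
#' @export
standardize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  frags <- strsplit(trimws(smiles), ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (length(frags) == 0) rax_parse_error(smiles, "empty SMILES")
  info <- lapply(frags, function(f) {
    mol <- rax_mol(f)   # errors (rax_parse_error) propagate
    list(cansmi = mol$cansmi,
         heavy = nrow(mol$atoms),
         carbons = sum(mol$atoms$elem == "C"))
  })
  organic <- vapply(info, function(x) x$carbons > 0, logical(1))
  if (!any(organic)) {
    cond <- structure(
      class = c("rax_inorganic_error", "error", "condition"),
      list(message = sprintf(
        "no organic parent fragment in '%s' (inorganic/no-parent)", smiles),
        call = NULL, smiles = smiles))
    stop(cond)
  }
  info <- info[organic]
  ord <- order(-vapply(info, `[[`, numeric(1), "heavy"),
               -vapply(info, `[[`, numeric(1), "carbons"),
               vapply(info, `[[`, character(1), "cansmi"))
  parent <- info[[ord[1]]]$cansmi
  list(smiles_input = smiles,
       smiles_parent = parent,
       structure_key = ob_inchi(parent))
}

#' Convert an AC50 in nanomolar to the molar -log scale
#'
#' `pAC50 = 9 - log10(AC50[nM])`, i.e. the negative decadic logarithm of the
#' molar half-maximal activity concentration.
#'
#' @param ac50_nM positive numeric vector (nanomolar).
#' @return numeric vector of pAC50 values (molar -log scale).
#' @examples
#' pac50_from_ac50(c(1, 1000))  # 9, 6
#' @export
pac50_from_ac50 <- function(ac50_nM) {
  if (!is.numeric(ac50_nM)) stop("ac50_nM must be numeric")
  if (any(!is.na(ac50_nM) & ac50_nM <= 0)) {
    stop("ac50_nM must be strictly positive")
  }
  9 - log10(ac50_nM)
}

#' Reconcile replicate records of one structure
#'
#' All records must share one standardized-structure key. Qualitative labels
#' must agree, otherwise the group is rejected. When quantitative values are
#' present, the activity range (max/min AC50) may not exceed 1:3; within
#' that range a single record is returned whose potency is the mean on the
#' -log molar scale (the geometric mean of AC50), outside it the group is
#' rejected.
#'
#' @param records a data frame with columns `activity` and (optionally)
#'   `ac50_nM`; additional columns such as `id` are carried through from the
#'   first record.
#' @param max_ratio largest tolerated AC50 fold-range (default 3).
#' @return a list with `status` ("kept" or "rejected"), `reason` (for
#'   rejections), and for kept groups `activity` plus `ac50_nM`/`pac50`
#'   summaries.
#' @examples
#' reconcile_duplicates(data.frame(activity = "active",
#'                                 ac50_nM = c(100, 250)))
#' @export
reconcile_duplicates <- function(records, max_ratio = 3) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            "activity" %in% names(records))
  act <- normalize_activity(records$activity)
  act_known <- unique(act[act != "unknown"])
  if (length(act_known) > 1) {
    return(list(status = "rejected", reason = "conflicting_labels"))
  }
  activity <- if (length(act_known) == 1) act_known else "unknown"
  ac50 <- if ("ac50_nM" %in% names(records)) records$ac50_nM else
    rep(NA_real_, nrow(records))
  ac50 <- ac50[!is.na(ac50)]
  if (length(ac50) > 0) {
    if (any(ac50 <= 0)) stop("ac50_nM must be strictly positive")
    if (max(ac50) / min(ac50) > max_ratio) {
      return(list(status = "rejected", reason = "activity_range"))
    }
    pac50 <- mean(pac50_from_ac50(ac50))
    return(list(status = "kept", activity = activity,
                pac50 = pac50, ac50_nM = 10^(9 - pac50),
                n = nrow(records)))
  }
  list(status = "kept", activity = activity, pac50 = NA_real_,
       ac50_nM = NA_real_, n = nrow(records))
}

#' Classify the azole character of a structure
#'
#' Looks at all aromatic five-membered rings containing at least one
#' nitrogen and classifies by the maximum nitrogen count among them.
#'
#' @param x a SMILES string (standardized structure).
#' @return one of `"none"`, `"monoazole"`, `"diazole"`, `"triazole"`,
#'   `"tetrazole"`.
#' @examples
#' classify_azole("c1cc[nH]c1")   # monoazole
#' classify_azole("c1cnc[nH]1")   # diazole
#' @export
classify_azole <- function(x) {
  mol <- rax_mol(x)
  ri <- ring_info(mol)
  sel <- ri$size == 5 & ri$aromatic & ri$n_nitrogen >= 1
  if (!any(sel)) return("none")
  c("monoazole", "diazole", "triazole", "tetrazole")[
    min(max(ri$n_nitrogen[sel]), 4L)]
}

# ---- dataset container ------------------------------------------------

#' Build a source dataset from compound records
#'
#' Standardizes every structure, attaches structure keys, converts potencies
#' and validates ids and activity labels. Rows used as read-across sources
#' must carry a known activity; `unknown` is only admissible for prediction
#' targets.
#'
#' @param df data frame with columns `id`, `cas`, `name`, `smiles`,
#'   `activity` and optionally `ac50_nM` (plus any extra columns, which are
#'   kept).
#' @param provenance free-text provenance note stored as an attribute.
#' @return a `rax_dataset`: the input data plus `smiles_parent`,
#'   `structure_key` and `pac50` columns.
#' @export
rax_dataset <- function(df, provenance = "") {
  need <- c("id", "cas", "name", "smiles", "activity")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0) stop("empty dataset")
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    stop("duplicate id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  df$activity <- normalize_activity(df$activity)
  std <- lapply(df$smiles, standardize_smiles)
  df$smiles_parent <- vapply(std, `[[`, character(1), "smiles_parent")
  df$structure_key <- vapply(std, `[[`, character(1), "structure_key")
  if (!"ac50_nM" %in% names(df)) df$ac50_nM <- NA_real_
  df$pac50 <- ifelse(is.na(df$ac50_nM), NA_real_,
                     pac50_from_ac50(df$ac50_nM))
  dup <- duplicated(df$structure_key)
  if (any(dup)) {
    warning("dataset contains ", sum(dup), " duplicated structure key(s); ",
            "consider curate_dataset()")
  }
  structure(df, class = c("rax_dataset", "data.frame"),
            provenance = provenance)
}

#' @export
print.rax_dataset <- function(x, ...) {
  cat(sprintf("<rax_dataset: %d compounds (%d active, %d inactive, %d unknown)>\n",
              nrow(x), sum(x$activity == "active"),
              sum(x$activity == "inactive"), sum(x$activity == "unknown")))
  prov <- attr(x, "provenance")
  if (nzchar(prov)) cat("provenance:", prov, "\n")
  print.data.frame(utils::head(as.data.frame(x)[,
    intersect(c("id", "cas", "activity", "smiles_parent"), names(x))], 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Collapse structure-key duplicates of a dataset
#'
#' Groups rows by standardized-structure key and applies
#' [reconcile_duplicates()] to every group: agreeing replicates within a
#' 1:3 activity range are merged into one record (mean potency on the -log
#' scale), others are dropped.
#'
#' @param ds a `rax_dataset`.
#' @return a list with `dataset` (curated `rax_dataset`) and `rejected`
#'   (data frame of dropped groups with reasons).
#' @export
curate_dataset <- function(ds) {
  stopifnot(inherits(ds, "rax_dataset"))
  groups <- split(seq_len(nrow(ds)), ds$structure_key)
  keep <- list(); rejected <- list()
  for (key in names(groups)) {
    idx <- groups[[key]]
    rec <- as.data.frame(ds)[idx, ]
    if (length(idx) == 1) { keep[[key]] <- rec; next }
    r <- reconcile_duplicates(rec)
    if (r$status == "kept") {
      merged <- rec[1, ]
      merged$activity <- r$activity
      merged$ac50_nM <- r$ac50_nM
      merged$pac50 <- r$pac50
      keep[[key]] <- merged
    } else {
      rejected[[key]] <- data.frame(structure_key = key,
                                    ids = paste(rec$id, collapse = ";"),
                                    reason = r$reason)
    }
  }
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  list(
    dataset = structure(out, class = c("rax_dataset", "data.frame"),
                        provenance = attr(ds, "provenance")),
    rejected = if (length(rejected)) do.call(rbind, rejected) else
      data.frame(structure_key = character(0), ids = character(0),
                 reason = character(0))
  )
}

# ---- file I/O ---------------------------------------------------------

#' Read a source dataset from CSV or SDF
#'
#' The CSV dialect is UTF-8, comma-separated, with a mandatory header
#' `id,cas,name,smiles,activity[,ac50_nM]`. SDF files carry the same fields
#' as named data-block properties. Activity strings are mapped
#' case-insensitively onto active/inactive/unknown ("active agonist" and
#' "active antagonist" both count as active).
#'
#' @param path input file.
#' @param format `"csv"` or `"sdf"` (default: guessed from the extension).
#' @return a `rax_dataset`.
#' @export
read_dataset <- function(path, format = c("auto", "csv", "sdf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in% c("sdf", "sd"))
      "sdf" else "csv"
  }
  if (format == "csv") {
    if (file.size(path) == 0) stop("empty dataset: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    if (nrow(df) == 0) stop("empty dataset: ", path)
    if ("ac50_nM" %in% names(df)) {
      df$ac50_nM <- suppressWarnings(as.numeric(df$ac50_nM))
    }
    return(rax_dataset(df, provenance = path))
  }
  sdf <- ChemmineR::read.SDFset(path)
  if (length(sdf) == 0) stop("empty dataset: ", path)
  blocks <- ChemmineR::datablock(sdf)
  fields <- c("id", "cas", "name", "activity", "ac50_nM")
  rows <- lapply(seq_along(sdf), function(i) {
    b <- blocks[[i]]
    smi <- as.character(ChemmineR::sdf2smiles(sdf[i]))
    vals <- lapply(fields, function(f) if (f %in% names(b)) b[[f]] else NA)
    names(vals) <- fields
    data.frame(id = vals$id, cas = vals$cas, name = vals$name,
               smiles = smi, activity = vals$activity,
               ac50_nM = suppressWarnings(as.numeric(vals$ac50_nM)),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (anyNA(df$id)) stop("missing mandatory SDF property: id")
  rax_dataset(df, provenance = path)
}

#' Write a source dataset to CSV or SDF
#'
#' Round-trip stable on the record fields: `write_dataset()` followed by
#' [read_dataset()] recovers id, cas, name, input SMILES, activity and
#' AC50.
#'
#' @param ds a `rax_dataset`.
#' @param path output file.
#' @param format `"csv"` or `"sdf"` (default: guessed from the extension).
#' @export
write_dataset <- function(ds, path, format = c("auto", "csv", "sdf")) {
  stopifnot(inherits(ds, "rax_dataset"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in% c("sdf", "sd"))
      "sdf" else "csv"
  }
  df <- as.data.frame(ds)
  if (format == "csv") {
    cols <- c("id", "cas", "name", "smiles", "activity")
    if (any(!is.na(df$ac50_nM))) cols <- c(cols, "ac50_nM")
    utils::write.csv(df[, cols], path, row.names = FALSE, quote = TRUE,
                     na = "")
    return(invisible(path))
  }
  sdfs <- suppressWarnings(ChemmineR::smiles2sdf(df$smiles))
  props <- lapply(seq_len(nrow(df)), function(i) {
    p <- c(id = df$id[i], cas = df$cas[i], name = df$name[i],
           activity = df$activity[i])
    if (!is.na(df$ac50_nM[i])) p <- c(p, ac50_nM = df$ac50_nM[i])
    p
  })
  ChemmineR::cid(sdfs) <- make.unique(df$id)
  ChemmineR::datablock(sdfs) <- props
  ChemmineR::write.SDF(sdfs, path, cid = TRUE)
  invisible(path)
}
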