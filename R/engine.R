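# The integrated read-across core: three candidate lists (structural,
# metabolic, mechanistic), their intersection as the analogue category, and
# the majority-vote prediction, wrapped in a fitted-model-style S3 object.

#' Fit a read-across model over a source dataset
#'
#' Precomputes structural fingerprints and alert hits for every source
#' compound and stores the configuration used for candidate retrieval:
#' similarity thresholds (inclusive, default 0.7 for both structural and
#' metabolic similarity), the integration mode, and the tie policy of the
#' majority vote.
#'
#' @param dataset a `rax_dataset` of labelled source compounds (see
#'   [read_dataset()] / [rax_dataset()]).
#' @param profiles CYP inhibition profiles: a `rax_profiles` matrix (see
#'   [load_profiles()]), a path to the profile CSV, a callable
#'   `function(smiles)` returning a 5-bit vector (pluggable predictor), or
#'   `NULL` (metabolic candidacy then stays empty and integrated-mode
#'   targets become unpredicted).
#' @param alerts a `rax_alerts` registry, default the shipped aromatase
#'   registry.
#' @param strs_threshold,mts_threshold inclusive similarity thresholds in
#'   \[0, 1\].
#' @param mode `"IntS"` (intersection of the three lists, default) or
#'   `"StrS"` (vote over the structural list alone).
#' @param tie_policy `"equivocal"` (tied votes give no call, default) or
#'   `"worst_case_active"` (conservative worst case: ties count as active).
#' @param fingerprinter fingerprint generator, default
#'   [pubchem_fingerprint()]; any callable returning a `bitfp`-compatible
#'   object can be plugged in.
#' @return an object of class `rax`.
#' @examples
#' \donttest{
#' fx <- case_study_fixtures("imidazolium")
#' m <- rax(fx$dataset, profiles = fx$profiles)
#' predict(m, fx$targets)
#' }
#' @export
rax <- function(dataset, profiles = NULL, alerts = load_alerts(),
                strs_threshold = 0.7, mts_threshold = 0.7,
                mode = c("IntS", "StrS"),
                tie_policy = c("equivocal", "worst_case_active"),
                fingerprinter = pubchem_fingerprint) {
  stopifnot(inherits(dataset, "rax_dataset"))
  mode <- match.arg(mode)
  tie_policy <- match.arg(tie_policy)
  stopifnot(strs_threshold >= 0, mts_threshold >= 0)
  if (is.character(profiles) && length(profiles) == 1) {
    profiles <- load_profiles(profiles)
  }
  plugin <- NULL
  if (is.function(profiles)) {
    plugin <- profiles
    prof <- t(vapply(seq_len(nrow(dataset)), function(i) {
      as.integer(plugin(dataset$smiles_parent[i]))
    }, integer(5)))
    rownames(prof) <- dataset$id
    colnames(prof) <- cyp_isoforms
    profiles <- structure(prof, class = c("rax_profiles", class(prof)))
  }
  fps <- lapply(dataset$smiles_parent, fingerprinter)
  names(fps) <- dataset$id
  hits <- lapply(dataset$smiles_parent, match_alerts, registry = alerts)
  names(hits) <- dataset$id
  structure(
    list(dataset = dataset, profiles = profiles, alerts = alerts,
         profile_plugin = plugin,
         config = list(strs_threshold = strs_threshold,
                       mts_threshold = mts_threshold,
                       mode = mode, tie_policy = tie_policy),
         fingerprinter = fingerprinter,
         fps = fps, alert_hits = hits),
    class = "rax")
}

#' @export
print.rax <- function(x, ...) {
  cfg <- x$config
  cat("Integrated-similarity read-across model\n")
  cat(sprintf("  source compounds : %d (%d active, %d inactive)\n",
              nrow(x$dataset), sum(x$dataset$activity == "active"),
              sum(x$dataset$activity == "inactive")))
  cat(sprintf("  CYP profiles     : %s\n",
              if (is.null(x$profiles)) "none" else
                sprintf("%d compounds", nrow(x$profiles))))
  cat(sprintf("  alert registry   : %d alerts\n", nrow(x$alerts)))
  cat(sprintf("  thresholds       : StrS >= %.2f, MtS >= %.2f (inclusive)\n",
              cfg$strs_threshold, cfg$mts_threshold))
  cat(sprintf("  mode / ties      : %s / %s\n", cfg$mode, cfg$tie_policy))
  invisible(x)
}

# ---- candidate lists --------------------------------------------------

#' Structural candidate list for one target
#'
#' All source compounds whose fingerprint Tanimoto with the target reaches
#' the threshold, ranked by descending score; rank ties are broken by id
#' (ascending) for reproducibility. Sources sharing the target's structure
#' key are excluded (the leave-one-out contract).
#'
#' @param model a `rax` model.
#' @param target target SMILES (standardized internally) or a `bitfp`.
#' @param threshold inclusive similarity threshold; default from the model.
#' @param exclude_keys structure keys removed from the pool.
#' @return data frame `id`, `score`, `rank` sorted by rank.
#' @export
candidates_structural <- function(model, target,
                                  threshold = model$config$strs_threshold,
                                  exclude_keys = character(0)) {
  fp <- if (inherits(target, "bitfp")) target else
    model$fingerprinter(standardize_smiles(target)$smiles_parent)
  pool <- !(model$dataset$structure_key %in% exclude_keys)
  ids <- model$dataset$id[pool]
  score <- vapply(ids, function(i) {
    tryCatch(tanimoto(fp, model$fps[[i]]), error = function(e) NA_real_)
  }, numeric(1))
  keep <- !is.na(score) & score >= threshold
  out <- data.frame(id = ids[keep], score = unname(score[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Metabolic candidate list for one target
#'
#' Source compounds whose CYP-profile Tanimoto with the target reaches the
#' threshold. Sources without a profile are omitted (with a warning); a
#' missing target profile is an error for this function -- in batch
#' prediction it maps to an unpredicted outcome instead.
#'
#' @param model a `rax` model.
#' @param target_profile 5-bit vector for the target.
#' @param threshold inclusive similarity threshold; default from the model.
#' @param exclude_keys structure keys removed from the pool.
#' @param quiet suppress the missing-profile warning (used internally by
#'   batch runs).
#' @return data frame `id`, `score`.
#' @export
candidates_metabolic <- function(model, target_profile,
                                 threshold = model$config$mts_threshold,
                                 exclude_keys = character(0),
                                 quiet = FALSE) {
  if (is.null(target_profile)) stop("target profile unavailable")
  pool <- !(model$dataset$structure_key %in% exclude_keys)
  ids <- model$dataset$id[pool]
  has <- vapply(ids, function(i)
    !is.null(profile_for(model$profiles, i)), logical(1))
  if (any(!has) && !quiet) {
    warning(sum(!has), " source compound(s) lack CYP profiles and are ",
            "omitted from metabolic candidacy")
  }
  ids <- ids[has]
  score <- vapply(ids, function(i) {
    metabolic_similarity(target_profile, profile_for(model$profiles, i))
  }, numeric(1))
  keep <- score >= threshold
  out <- data.frame(id = ids[keep], score = unname(score[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Mechanistic candidate list for one target
#'
#' Source compounds sharing at least one structural alert with the target,
#' annotated with the shared alert ids.
#'
#' @param model a `rax` model.
#' @param target_hits character vector of the target's matched alert ids.
#' @param exclude_keys structure keys removed from the pool.
#' @return data frame `id`, `shared` (list column of alert ids).
#' @export
candidates_mechanistic <- function(model, target_hits,
                                   exclude_keys = character(0)) {
  pool <- !(model$dataset$structure_key %in% exclude_keys)
  ids <- model$dataset$id[pool]
  shared <- lapply(ids, function(i)
    shared_alerts(target_hits, model$alert_hits[[i]]))
  keep <- lengths(shared) > 0
  out <- data.frame(id = ids[keep], stringsAsFactors = FALSE)
  out$shared <- shared[keep]
  rownames(out) <- NULL
  out
}

#' Intersect the three candidate lists into an analogue category
#'
#' Only compounds present simultaneously in the structural, metabolic and
#' mechanistic lists enter the category (equal weights, no cap on the
#' member count); the evidence of all three metrics is merged per member.
#'
#' @param structural,metabolic,mechanistic candidate lists as returned by
#'   the `candidates_*` functions.
#' @param dataset the source `rax_dataset` (for activity labels).
#' @return data frame with one row per category member: `id`, `activity`,
#'   `strs`, `rank`, `mts`, `shared` (list column).
#' @export
integrate_lists <- function(structural, metabolic, mechanistic, dataset) {
  ids <- intersect(intersect(structural$id, metabolic$id), mechanistic$id)
  out <- structural[structural$id %in% ids, , drop = FALSE]
  names(out)[names(out) == "score"] <- "strs"
  out$mts <- metabolic$score[match(out$id, metabolic$id)]
  out$shared <- mechanistic$shared[match(out$id, mechanistic$id)]
  out$activity <- dataset$activity[match(out$id, dataset$id)]
  rownames(out) <- NULL
  out[, c("id", "activity", "strs", "rank", "mts", "shared")]
}

#' Majority vote over an analogue category
#'
#' Predicts the label held by the strict majority of category members. An
#' empty category gives `unpredicted`; a tied vote gives `equivocal` under
#' the default tie policy (grouped with unpredicted in the statistics) or
#' `active` under the conservative worst-case policy.
#'
#' @param category data frame with an `activity` column (`active` /
#'   `inactive`); members with unknown activity are an error.
#' @param tie_policy `"equivocal"` or `"worst_case_active"`.
#' @return a list: `status` (`predicted`/`unpredicted`/`equivocal`),
#'   `label` (when predicted), `votes_active`, `votes_inactive`.
#' @examples
#' majority_vote(data.frame(activity = c("active", "active", "inactive")))
#' @export
majority_vote <- function(category,
                          tie_policy = c("equivocal", "worst_case_active")) {
  tie_policy <- match.arg(tie_policy)
  if (is.null(category) || nrow(category) == 0) {
    return(list(status = "unpredicted", label = NA_character_,
                votes_active = 0L, votes_inactive = 0L))
  }
  if (any(!category$activity %in% c("active", "inactive"))) {
    stop("category members must carry a known activity label")
  }
  va <- sum(category$activity == "active")
  vi <- sum(category$activity == "inactive")
  if (va == vi) {
    if (tie_policy == "worst_case_active") {
      return(list(status = "predicted", label = "active",
                  votes_active = va, votes_inactive = vi))
    }
    return(list(status = "equivocal", label = NA_character_,
                votes_active = va, votes_inactive = vi))
  }
  list(status = "predicted",
       label = if (va > vi) "active" else "inactive",
       votes_active = va, votes_inactive = vi)
}

# Evaluate one target against the model pool: builds the three lists, the
# category and both-mode votes. Internal work-horse for predict() and loo();
# fp/hits allow reuse of the model's precomputed values in LOO runs.
target_eval <- function(model, id, smiles_parent, target_profile,
                        exclude_keys = character(0),
                        fp = NULL, hits = NULL) {
  if (is.null(fp)) {
    fp <- tryCatch(model$fingerprinter(smiles_parent),
                   error = function(e) NULL)
  }
  if (is.null(fp)) {
    return(list(error = "fingerprint_failed"))
  }
  if (is.null(hits)) hits <- match_alerts(smiles_parent, model$alerts)
  structural <- candidates_structural(model, fp,
                                      exclude_keys = exclude_keys)
  structural$activity <- model$dataset$activity[
    match(structural$id, model$dataset$id)]
  metabolic <- if (is.null(target_profile)) NULL else
    candidates_metabolic(model, target_profile,
                         exclude_keys = exclude_keys, quiet = TRUE)
  mechanistic <- candidates_mechanistic(model, hits,
                                        exclude_keys = exclude_keys)
  category <- if (is.null(metabolic)) NULL else
    integrate_lists(structural, metabolic, mechanistic, model$dataset)
  strs_cat <- model$dataset[match(structural$id, model$dataset$id), ]
  list(target_id = id, alert_hits = hits,
       structural = structural, metabolic = metabolic,
       mechanistic = mechanistic, category = category,
       vote_ints = if (is.null(category)) NULL else
         majority_vote(category, model$config$tie_policy),
       vote_strs = majority_vote(
         data.frame(activity = strs_cat$activity,
                    stringsAsFactors = FALSE),
         model$config$tie_policy),
       profile_missing = is.null(target_profile))
}

# assemble one prediction record from a target evaluation
prediction_record <- function(ev, mode) {
  if (!is.null(ev$error)) {
    return(data.frame(id = ev$target_id %||% NA_character_, mode = mode,
                      status = "unpredicted", label = NA_character_,
                      votes_active = 0L, votes_inactive = 0L,
                      n_members = 0L, reason = ev$error,
                      stringsAsFactors = FALSE))
  }
  if (mode == "IntS") {
    if (ev$profile_missing) {
      return(data.frame(id = ev$target_id, mode = mode,
                        status = "unpredicted", label = NA_character_,
                        votes_active = 0L, votes_inactive = 0L,
                        n_members = 0L, reason = "target profile unavailable",
                        stringsAsFactors = FALSE))
    }
    v <- ev$vote_ints
    n <- nrow(ev$category)
    reason <- if (v$status == "unpredicted") {
      if (nrow(ev$mechanistic) == 0) "empty mechanistic list"
      else if (nrow(ev$structural) == 0) "empty structural list"
      else if (nrow(ev$metabolic) == 0) "empty metabolic list"
      else "empty intersection"
    } else ""
  } else {
    v <- ev$vote_strs
    n <- nrow(ev$structural)
    reason <- if (v$status == "unpredicted") "empty structural list" else ""
  }
  data.frame(id = ev$target_id, mode = mode, status = v$status,
             label = v$label, votes_active = v$votes_active,
             votes_inactive = v$votes_inactive, n_members = n,
             reason = reason, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Replace the activity labels of a fitted model's dataset
#'
#' For label-perturbation experiments (e.g. repeated noisy replicates of a
#' synthetic series): swaps in a dataset with identical compounds but
#' possibly different labels, reusing the model's precomputed fingerprints
#' and alert hits.
#'
#' @param model a `rax` model.
#' @param dataset a `rax_dataset` with the same ids and structure keys.
#' @return the updated model.
#' @export
update_activities <- function(model, dataset) {
  stopifnot(inherits(model, "rax"), inherits(dataset, "rax_dataset"),
            identical(as.character(dataset$id),
                      as.character(model$dataset$id)),
            identical(dataset$structure_key, model$dataset$structure_key))
  model$dataset <- dataset
  model
}

#' Predict activity for target structures by read-across
#'
#' Runs the full workflow for each target: candidate retrieval by the three
#' similarity views, intersection into the analogue category (integrated
#' mode) or the structural list alone (StrS mode), and the majority vote.
#' Component errors (unparsable structure, missing target profile) map to
#' an `unpredicted` outcome with a reason rather than aborting the batch.
#'
#' @param object a `rax` model.
#' @param newdata targets: a character vector of SMILES (names become ids),
#'   or a data frame with columns `id`, `smiles`.
#' @param profiles optional profile source for the targets (`rax_profiles`
#'   matrix or CSV path); defaults to the model's profiles (matched by id)
#'   or its profile plugin.
#' @param mode override the model's integration mode for this call.
#' @param ... unused.
#' @return a `rax_prediction`: a data frame of per-target outcomes with the
#'   full evidence (candidate lists and category per target) attached as
#'   attribute `"evidence"`.
#' @export
predict.rax <- function(object, newdata, profiles = NULL,
                        mode = object$config$mode, ...) {
  mode <- match.arg(mode, c("IntS", "StrS"))
  if (is.character(newdata)) {
    ids <- names(newdata) %||% newdata
    ids[!nzchar(ids)] <- newdata[!nzchar(ids)]
    newdata <- data.frame(id = ids, smiles = unname(newdata),
                          stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(newdata), all(c("id", "smiles") %in% names(newdata)))
  if (is.character(profiles) && length(profiles) == 1) {
    profiles <- load_profiles(profiles)
  }
  records <- list(); evidence <- list()
  for (i in seq_len(nrow(newdata))) {
    id <- as.character(newdata$id[i])
    ev <- tryCatch({
      std <- standardize_smiles(newdata$smiles[i])
      tp <- profile_for(profiles, id) %||% profile_for(object$profiles, id)
      if (is.null(tp) && !is.null(object$profile_plugin)) {
        tp <- as.integer(object$profile_plugin(std$smiles_parent))
      }
      ev <- target_eval(object, id, std$smiles_parent, tp,
                        exclude_keys = std$structure_key)
      ev$target_id <- id
      ev
    }, error = function(e) list(target_id = id,
                                error = conditionMessage(e)))
    records[[i]] <- prediction_record(ev, mode)
    evidence[[id]] <- ev
  }
  out <- do.call(rbind, records)
  structure(out, class = c("rax_prediction", "data.frame"),
            evidence = evidence, mode = mode)
}

#' @export
print.rax_prediction <- function(x, ...) {
  cat(sprintf("Read-across predictions (%s mode)\n", attr(x, "mode")))
  print.data.frame(as.data.frame(x)[,
    c("id", "status", "label", "votes_active", "votes_inactive",
      "n_members", "reason")])
  invisible(x)
}

#' Evidence report for one predicted target
#'
#' Returns the per-source evidence behind a prediction in the layout of a
#' case-study report: list membership (IntS/StrS), activity, structural
#' score and rank, metabolic score and shared alerts.
#'
#' @param prediction a `rax_prediction`.
#' @param id target id (default: the first target).
#' @return a data frame, one row per source compound in any list.
#' @export
evidence_report <- function(prediction, id = NULL) {
  ev <- attr(prediction, "evidence")
  if (is.null(id)) id <- names(ev)[1]
  e <- ev[[id]]
  if (!is.null(e$error)) stop("no evidence: ", e$error)
  strs <- e$structural
  cat_ids <- if (is.null(e$category)) character(0) else e$category$id
  mts <- e$metabolic
  out <- data.frame(
    id = strs$id,
    membership = ifelse(strs$id %in% cat_ids, "IntS+StrS", "StrS"),
    activity = strs$activity,
    rank = strs$rank,
    strs = strs$score,
    stringsAsFactors = FALSE
  )
  out$mts <- if (is.null(mts)) NA_real_ else
    mts$score[match(out$id, mts$id)]
  mech <- e$mechanistic
  out$shared_alerts <- vapply(out$id, function(i) {
    j <- match(i, mech$id)
    if (is.na(j)) "" else paste(mech$shared[[j]], collapse = "+")
  }, character(1))
  out
}
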