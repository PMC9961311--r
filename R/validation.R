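# Leave-one-out validation: confusion matrices (active = positive),
# performance statistics, unpredicted-rate accounting and the non-unique
# source-compound match tally.

#' Confusion-matrix container
#'
#' @param tp,fn,fp,tn,unpredicted non-negative counts; `unpredicted`
#'   includes equivocal (tied-vote) targets.
#' @return a `rax_confusion` list with the counts and their total.
#' @export
rax_confusion <- function(tp = 0, fn = 0, fp = 0, tn = 0, unpredicted = 0) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn,
              unpredicted = unpredicted)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(as.list(c(counts, total = sum(counts))),
            class = "rax_confusion")
}

#' @export
print.rax_confusion <- function(x, ...) {
  cat(sprintf("tp=%d fn=%d fp=%d tn=%d unpredicted=%d (total %d)\n",
              x$tp, x$fn, x$fp, x$tn, x$unpredicted, x$total))
  invisible(x)
}

#' Performance statistics from a confusion matrix
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy
#' `(tp+tn)/(tp+fn+fp+tn)`, error rate `1 - accuracy`, unpredicted rate
#' `unpredicted/total`, the Matthews correlation coefficient with the
#' square-root denominator
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, and the
#' likelihood ratio `((tp+tn)/(fp+fn)) * ((tp+fn)/(tn+fp))` (correct over
#' wrong predictions, scaled by the class balance positives/negatives).
#' Unpredicted targets are excluded from every denominator except the
#' unpredicted rate.
#'
#' A statistic whose denominator is zero is reported as `NA` (absent), not
#' as 0; a likelihood ratio with zero wrong predictions is `Inf`. Values
#' are returned at full precision -- rounding to two decimals happens only
#' at report time.
#'
#' @param m a `rax_confusion` (or a list with fields `tp`, `fn`, `fp`,
#'   `tn`, `unpredicted`, `total`).
#' @return a `rax_stats` list: `sensitivity`, `specificity`, `accuracy`,
#'   `error_rate`, `unpredicted_rate`, `mcc`, `lr`.
#' @examples
#' s <- stats_from_matrix(rax_confusion(tp = 34, fn = 3, fp = 5, tn = 27))
#' round(s$mcc, 2)
#' @export
stats_from_matrix <- function(m) {
  tp <- m$tp; fn <- m$fn; fp <- m$fp; tn <- m$tn
  unpred <- m$unpredicted %||% 0
  total <- m$total %||% (tp + fn + fp + tn + unpred)
  div <- function(num, den) if (den > 0) num / den else NA_real_
  mcc_den <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  lr <- if (fp + fn == 0) {
    if (tp + tn > 0 && tn + fp > 0) Inf else NA_real_
  } else {
    div((tp + tn) / (fp + fn) * (tp + fn), tn + fp)
  }
  structure(list(
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    accuracy = div(tp + tn, tp + fn + fp + tn),
    error_rate = if (tp + fn + fp + tn > 0)
      1 - (tp + tn) / (tp + fn + fp + tn) else NA_real_,
    unpredicted_rate = div(unpred, total),
    mcc = if (mcc_den > 0) (tp * tn - fp * fn) / sqrt(mcc_den) else NA_real_,
    lr = lr
  ), class = "rax_stats")
}

#' @export
print.rax_stats <- function(x, digits = 2, ...) {
  for (nm in names(x)) {
    cat(sprintf("  %-17s %s\n", nm,
                ifelse(is.na(x[[nm]]), "absent", round(x[[nm]], digits))))
  }
  invisible(x)
}

#' Leave-one-out validation of a read-across model
#'
#' Predicts every source compound with itself (and any compound sharing its
#' structure key) removed from the pool, in both integration modes, and
#' tallies confusion matrices (active = positive), performance statistics
#' and the non-unique match accounting.
#'
#' @param model a `rax` model whose dataset rows all carry known activity.
#' @return a `rax_loo` object: `records` (per-target predictions for both
#'   modes), `confusion`, `stats` and `accounting` (per mode).
#' @export
loo <- function(model) {
  stopifnot(inherits(model, "rax"))
  ds <- model$dataset
  if (nrow(ds) < 2) stop("leave-one-out needs at least 2 compounds")
  if (any(ds$activity == "unknown")) {
    stop("all source compounds must be labelled for validation")
  }
  records <- list(); members <- list(IntS = list(), StrS = list())
  for (i in seq_len(nrow(ds))) {
    id <- ds$id[i]
    tp <- profile_for(model$profiles, id)
    if (is.null(tp) && !is.null(model$profile_plugin)) {
      tp <- as.integer(model$profile_plugin(ds$smiles_parent[i]))
    }
    ev <- target_eval(model, id, ds$smiles_parent[i], tp,
                      exclude_keys = ds$structure_key[i],
                      fp = model$fps[[id]], hits = model$alert_hits[[id]])
    ev$target_id <- id
    records[[length(records) + 1L]] <- prediction_record(ev, "IntS")
    records[[length(records) + 1L]] <- prediction_record(ev, "StrS")
    if (!is.null(ev$category) && nrow(ev$category) > 0) {
      members$IntS[[id]] <- ev$category$activity
    }
    if (!is.null(ev$structural) && nrow(ev$structural) > 0) {
      members$StrS[[id]] <- ev$structural$activity
    }
  }
  records <- do.call(rbind, records)
  truth <- stats::setNames(ds$activity, ds$id)
  confusion <- lapply(c(IntS = "IntS", StrS = "StrS"), function(mode) {
    r <- records[records$mode == mode, ]
    exp_act <- truth[r$id] == "active"
    pred <- r$status == "predicted"
    rax_confusion(
      tp = sum(pred & exp_act & r$label == "active"),
      fn = sum(pred & exp_act & r$label == "inactive"),
      fp = sum(pred & !exp_act & r$label == "active"),
      tn = sum(pred & !exp_act & r$label == "inactive"),
      unpredicted = sum(!pred)
    )
  })
  accounting <- lapply(members, function(mm) match_accounting(mm, truth))
  structure(list(records = records,
                 confusion = confusion,
                 stats = lapply(confusion, stats_from_matrix),
                 accounting = accounting),
            class = "rax_loo")
}

#' Non-unique source-compound match accounting
#'
#' Every category member contributes one (non-unique) count: a source
#' compound appearing in several categories counts once per category. Each
#' member either matches or does not match its target's experimental
#' activity; per-class splits and the ratio of non-matching to matching
#' counts are reported.
#'
#' @param categories named list (by target id) of member activity vectors.
#' @param truth named character vector of target activities.
#' @return a list: `n_match`, `n_nomatch`, per-class breakdowns, `ratio`
#'   (`n_nomatch / n_match`; `NA` when nothing matched).
#' @examples
#' match_accounting(list(t1 = c("active", "inactive")),
#'                  c(t1 = "active"))
#' @export
match_accounting <- function(categories, truth) {
  n_match <- n_nomatch <- 0L
  match_by <- nomatch_by <- c(active = 0L, inactive = 0L)
  for (id in names(categories)) {
    acts <- categories[[id]]
    is_match <- acts == truth[[id]]
    n_match <- n_match + sum(is_match)
    n_nomatch <- n_nomatch + sum(!is_match)
    for (cl in c("active", "inactive")) {
      match_by[cl] <- match_by[cl] + sum(is_match & acts == cl)
      nomatch_by[cl] <- nomatch_by[cl] + sum(!is_match & acts == cl)
    }
  }
  list(n_match = n_match, n_nomatch = n_nomatch,
       match_by_class = match_by, nomatch_by_class = nomatch_by,
       ratio = if (n_match > 0) n_nomatch / n_match else NA_real_)
}

#' @export
print.rax_loo <- function(x, digits = 2, ...) {
  cat("Leave-one-out validation\n")
  for (mode in c("StrS", "IntS")) {
    m <- x$confusion[[mode]]
    cat(sprintf("\n%s:  ", mode)); print(m)
    print(x$stats[[mode]], digits = digits)
    a <- x$accounting[[mode]]
    cat(sprintf("  SC match tally    %d match / %d no-match (ratio %s)\n",
                a$n_match, a$n_nomatch,
                ifelse(is.na(a$ratio), "absent", round(a$ratio, digits))))
  }
  invisible(x)
}

#' @export
summary.rax <- function(object, ...) loo(object)

#' Write the per-target records and the statistics of a LOO run
#'
#' @param x a `rax_loo` object.
#' @param csv optional path for the per-target CSV records.
#' @param json optional path for the JSON statistics block (both modes side
#'   by side).
#' @return `x`, invisibly.
#' @export
write_loo_report <- function(x, csv = NULL, json = NULL) {
  stopifnot(inherits(x, "rax_loo"))
  if (!is.null(csv)) {
    utils::write.csv(x$records, csv, row.names = FALSE)
  }
  if (!is.null(json)) {
    blocks <- lapply(x$stats, function(s) lapply(unclass(s), function(v) {
      if (is.na(v)) NULL else v
    }))
    for (mode in names(blocks)) {
      blocks[[mode]]$confusion <- unclass(x$confusion[[mode]])
      a <- x$accounting[[mode]]
      blocks[[mode]]$match_accounting <- list(
        n_match = a$n_match, n_nomatch = a$n_nomatch,
        match_by_class = as.list(a$match_by_class),
        nomatch_by_class = as.list(a$nomatch_by_class),
        ratio = if (is.na(a$ratio)) NULL else a$ratio)
    }
    jsonlite::write_json(blocks, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(x)
}
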