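# Candidate lists, integration, majority vote and the prediction surface.

test_that("case study 1: the imidazolium category and vote reproduce", {
  cm <- case_model("imidazolium")
  p <- predict(cm$model, cm$fx$targets[, c("id", "smiles")])
  expect_identical(p$status, "predicted")
  expect_identical(p$label, "active")
  expect_equal(p$votes_active, 3)
  expect_equal(p$votes_inactive, 0)
  er <- evidence_report(p)
  members <- er$id[er$membership == "IntS+StrS"]
  expect_setequal(members, c("1,3-Didecyl-2-methylimidazolium",
                             "1-Methyl-3-octadecylimidazolium hexafluorophosphate",
                             "1-Methyl-3-tetradecylimidazolium chloride"))
  # reported ranking: octadecyl 1st, tetradecyl 2nd among structural hits
  expect_identical(er$id[er$rank == 1],
                   "1-Methyl-3-octadecylimidazolium hexafluorophosphate")
  expect_identical(er$id[er$rank == 2],
                   "1-Methyl-3-tetradecylimidazolium chloride")
  # 11 structural analogues in total
  expect_equal(nrow(er), 11)
  # the hexyl analogue sits in the structural list only
  hexyl <- er[er$id == "1-Hexyl-3-methylimidazolium chloride", ]
  expect_identical(hexyl$membership, "StrS")
  expect_equal(hexyl$strs, 0.95, tolerance = 0.021)
})

test_that("case study 2: benzothiazole category, vote and StrS tally", {
  cm <- case_model("benzothiazole")
  p <- predict(cm$model, cm$fx$targets[, c("id", "smiles")])
  expect_identical(p$label, "active")
  expect_equal(p$n_members, 3)
  er <- evidence_report(p)
  expect_setequal(er$id[er$membership == "IntS+StrS"],
                  c("Methabenzthiazuron", "Riluzole", "Tioxidazole"))
  # reference similarity scores, within the fingerprint-dialect tolerance
  sc <- function(id) er$strs[er$id == id]
  expect_equal(sc("Riluzole"), 0.94, tolerance = 0.021)
  expect_equal(sc("Tioxidazole"), 0.94, tolerance = 0.021)
  expect_equal(sc("Methabenzthiazuron"), 0.73, tolerance = 0.021)
  expect_equal(sc("2-Amino-4-methoxybenzothiazole"), 0.90, tolerance = 0.021)
  # the 4-substituted analogue is excluded by the metabolic component alone
  amb <- er[er$id == "2-Amino-4-methoxybenzothiazole", ]
  expect_identical(amb$membership, "StrS")
  expect_identical(amb$shared_alerts, "SA_1")
  # structural-only vote: 6 active vs 3 inactive
  ps <- predict(cm$model, cm$fx$targets[, c("id", "smiles")], mode = "StrS")
  expect_equal(ps$votes_active, 6)
  expect_equal(ps$votes_inactive, 3)
  expect_identical(ps$label, "active")
})

test_that("structural candidates honour threshold, ranking and exclusion", {
  cm <- case_model("imidazolium")
  fp <- pubchem_fingerprint(im_smiles(16))
  # a threshold above 1 can never be reached
  expect_equal(nrow(candidates_structural(cm$model, fp, threshold = 1.01)), 0)
  full <- candidates_structural(cm$model, fp, threshold = 0)
  expect_equal(nrow(full), nrow(cm$model$dataset))
  expect_identical(full$rank, seq_len(nrow(full)))
  expect_true(all(diff(full$score) <= 0))
  # leave-one-out contract: structures sharing the target key are excluded
  key <- standardize_smiles(im_smiles(14))$structure_key
  excl <- candidates_structural(cm$model, fp, threshold = 0,
                                exclude_keys = key)
  expect_false("1-Methyl-3-tetradecylimidazolium chloride" %in% excl$id)
})

test_that("metabolic candidates handle thresholds and missing profiles", {
  cm <- case_model("imidazolium")
  tp <- c(0L, 0L, 0L, 1L, 0L)
  hits <- candidates_metabolic(cm$model, tp)
  expect_setequal(hits$id, c("1,3-Didecyl-2-methylimidazolium",
                             "1-Methyl-3-octadecylimidazolium hexafluorophosphate",
                             "1-Methyl-3-tetradecylimidazolium chloride"))
  # threshold 0 admits every source compound that has a profile
  all_with <- candidates_metabolic(cm$model, tp, threshold = 0)
  expect_equal(nrow(all_with),
               sum(cm$model$dataset$id %in% rownames(cm$model$profiles)))
  expect_error(candidates_metabolic(cm$model, NULL), "unavailable")
  # a model without profiles yields an empty list, with a warning
  m2 <- cm$model; m2$profiles <- NULL
  expect_warning(none <- candidates_metabolic(m2, tp), "omitted")
  expect_equal(nrow(none), 0)
})

test_that("mechanistic candidates require a shared alert", {
  cm <- case_model("imidazolium")
  mech <- candidates_mechanistic(cm$model, "SA_2")
  expect_true(all(lengths(mech$shared) >= 1))
  sa2 <- vapply(mech$shared, function(s) "SA_2" %in% s, logical(1))
  expect_true(all(sa2))
  # a target with no alerts has no mechanistic candidates
  expect_equal(nrow(candidates_mechanistic(cm$model, character(0))), 0)
})

test_that("majority vote follows the strict-majority rule", {
  mk <- function(a, i) data.frame(activity = c(rep("active", a),
                                               rep("inactive", i)))
  expect_identical(majority_vote(mk(3, 0))$label, "active")
  v <- majority_vote(mk(10, 3))
  expect_identical(v$label, "active")   # the reported false-positive case
  expect_equal(v$votes_active, 10)
  expect_identical(majority_vote(mk(0, 1))$label, "inactive")
  tie <- majority_vote(mk(2, 2))
  expect_identical(tie$status, "equivocal")
  expect_identical(majority_vote(mk(2, 2),
                                 tie_policy = "worst_case_active")$label,
                   "active")
  expect_identical(majority_vote(mk(0, 0))$status, "unpredicted")
  expect_error(majority_vote(data.frame(activity = "unknown")), "known")
})

test_that("unpredictable targets return reasons instead of aborting", {
  cm <- case_model("imidazolium")
  # no matched alerts -> empty mechanistic list under integration
  p <- predict(cm$model,
               c(cyclohexane = "C1CCCCC1"),
               profiles = NULL)
  expect_identical(p$status, "unpredicted")
  expect_identical(p$reason, "target profile unavailable")
  # with a profile but no alert
  prof <- matrix(c(0L, 0L, 0L, 1L, 0L), nrow = 1,
                 dimnames = list("cyclohexane", cyp_isoforms))
  p2 <- predict(cm$model, c(cyclohexane = "C1CCCCC1"), profiles = prof)
  expect_identical(p2$status, "unpredicted")
  expect_identical(p2$reason, "empty mechanistic list")
  # unparsable target SMILES -> unpredicted record, batch continues
  p3 <- predict(cm$model, c(bad = "xx((", ok = im_smiles(16)), mode = "StrS")
  expect_identical(p3$status[1], "unpredicted")
  expect_identical(p3$status[2], "predicted")
})

test_that("category members are a subset of every candidate list", {
  sm <- syn_model()
  ds <- sm$syn$dataset
  set.seed(11)
  for (i in sample(nrow(ds), 6)) {
    id <- ds$id[i]
    fp <- sm$model$fps[[id]]
    hits <- sm$model$alert_hits[[id]]
    tp <- intrax:::profile_for(sm$model$profiles, id)
    str <- candidates_structural(sm$model, fp,
                                 exclude_keys = ds$structure_key[i])
    met <- candidates_metabolic(sm$model, tp,
                                exclude_keys = ds$structure_key[i])
    mech <- candidates_mechanistic(sm$model, hits,
                                   exclude_keys = ds$structure_key[i])
    cat_ <- integrate_lists(str, met, mech, ds)
    expect_true(all(cat_$id %in% str$id))
    expect_true(all(cat_$id %in% met$id))
    expect_true(all(cat_$id %in% mech$id))
    # raising either threshold never enlarges the category
    str2 <- candidates_structural(sm$model, fp, threshold = 0.9,
                                  exclude_keys = ds$structure_key[i])
    met2 <- candidates_metabolic(sm$model, tp, threshold = 0.9,
                                 exclude_keys = ds$structure_key[i])
    cat2 <- integrate_lists(str2, met2, mech, ds)
    expect_true(all(cat2$id %in% cat_$id))
  }
})

test_that("predict agrees with brute-force enumeration on small datasets", {
  sm <- syn_model()
  ds <- sm$syn$dataset
  model <- sm$model
  set.seed(23)
  for (i in sample(nrow(ds), 5)) {
    id <- ds$id[i]
    # brute force: score every source directly, no list machinery
    fp <- model$fps[[id]]
    tp <- intrax:::profile_for(model$profiles, id)
    hits <- model$alert_hits[[id]]
    members <- character(0)
    for (j in seq_len(nrow(ds))[-i]) {
      sid <- ds$id[j]
      strs <- tanimoto(fp, model$fps[[sid]])
      mts <- metabolic_similarity(tp, intrax:::profile_for(model$profiles, sid))
      shared <- intersect(hits, model$alert_hits[[sid]])
      if (strs >= 0.7 && mts >= 0.7 && length(shared) > 0) {
        members <- c(members, sid)
      }
    }
    votes <- table(factor(ds$activity[match(members, ds$id)],
                          levels = c("active", "inactive")))
    expected_label <- if (length(members) == 0) NA_character_
      else if (votes["active"] == votes["inactive"]) NA_character_
      else if (votes["active"] > votes["inactive"]) "active" else "inactive"
    ev <- intrax:::target_eval(model, id, ds$smiles_parent[i], tp,
                               exclude_keys = ds$structure_key[i])
    expect_setequal(ev$category$id, members)
    rec <- intrax:::prediction_record(ev, "IntS")
    expect_identical(rec$label, expected_label)
  }
})

test_that("model configuration is carried and printed", {
  cm <- case_model("imidazolium")
  expect_identical(cm$model$config$mode, "IntS")
  expect_equal(cm$model$config$strs_threshold, 0.7)
  out <- capture.output(print(cm$model))
  expect_true(any(grepl("StrS >= 0.70", out)))
  out2 <- capture.output(print(predict(cm$model, cm$fx$targets[, c("id", "smiles")])))
  expect_true(any(grepl("IntS mode", out2)))
})
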