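# Structure standardization, curation formulas and dataset I/O.

test_that("standardization strips counter-ions but keeps charges", {
  s <- standardize_smiles("CCCCCCCCCCCCCCCC[n+]1ccn(C)c1.[Cl-]")
  expect_false(grepl("Cl", s$smiles_parent))
  expect_true(grepl("\\[n\\+\\]", s$smiles_parent))
  # single neutral fragment passes through unchanged (canonical form)
  benzene <- standardize_smiles("c1ccccc1")
  expect_identical(benzene$smiles_parent, "c1ccccc1")
  # no organic fragment -> structured error
  expect_error(standardize_smiles("[Na+].[Cl-]"), class = "rax_inorganic_error")
  expect_error(standardize_smiles("notasmiles(("), class = "rax_parse_error")
})

test_that("standardization is idempotent and keys collapse tautomers", {
  s1 <- standardize_smiles("CC[n+]1ccn(C)c1.[Cl-]")
  s2 <- standardize_smiles(s1$smiles_parent)
  expect_identical(s1$smiles_parent, s2$smiles_parent)
  expect_identical(s1$structure_key, s2$structure_key)
  # 2-pyridone / 2-hydroxypyridine share one key, different parents
  a <- standardize_smiles("Oc1ccccn1")
  b <- standardize_smiles("O=c1cccc[nH]1")
  expect_identical(a$structure_key, b$structure_key)
})

test_that("pAC50 conversion follows 9 - log10(AC50[nM])", {
  expect_equal(pac50_from_ac50(1), 9)
  expect_equal(pac50_from_ac50(1000), 6)
  expect_equal(pac50_from_ac50(250), 6.60206, tolerance = 1e-5)
  expect_error(pac50_from_ac50(0))
  expect_error(pac50_from_ac50(-5))
  # strictly decreasing
  x <- sort(10^runif(25, -1, 6))
  expect_true(all(diff(pac50_from_ac50(x)) < 0))
})

test_that("duplicate reconciliation applies the 1:3 range rule", {
  kept <- reconcile_duplicates(data.frame(activity = "active",
                                          ac50_nM = c(100, 250)))
  expect_identical(kept$status, "kept")
  # mean taken on the -log molar scale = geometric mean of AC50
  expect_equal(kept$pac50, mean(9 - log10(c(100, 250))))
  expect_equal(kept$ac50_nM, sqrt(100 * 250), tolerance = 1e-8)

  expect_identical(
    reconcile_duplicates(data.frame(activity = "active",
                                    ac50_nM = c(100, 400)))$status,
    "rejected")
  single <- reconcile_duplicates(data.frame(activity = "inactive",
                                            ac50_nM = 50))
  expect_identical(single$status, "kept")
  expect_equal(single$ac50_nM, 50)

  conflict <- reconcile_duplicates(
    data.frame(activity = c("active", "inactive"), ac50_nM = c(10, 11)))
  expect_identical(conflict$status, "rejected")
  expect_identical(conflict$reason, "conflicting_labels")
  # qualitative-only groups: kept when labels agree
  qual <- reconcile_duplicates(data.frame(activity = c("active", "active")))
  expect_identical(qual$status, "kept")
})

test_that("duplicate reconciliation is permutation-invariant", {
  rec <- data.frame(activity = "active", ac50_nM = c(30, 75, 55))
  perms <- list(1:3, c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))
  outs <- lapply(perms, function(p) reconcile_duplicates(rec[p, , drop = FALSE]))
  for (o in outs[-1]) expect_equal(o, outs[[1]])
})

test_that("azole classification counts ring nitrogens of aromatic 5-rings", {
  expect_identical(classify_azole("c1cc[nH]c1"), "monoazole")   # pyrrole
  expect_identical(classify_azole("c1cnc[nH]1"), "diazole")     # imidazole
  expect_identical(classify_azole("c1ncn[nH]1"), "triazole")
  expect_identical(classify_azole("c1nnn[nH]1"), "tetrazole")
  expect_identical(classify_azole("c1ccccc1"), "none")
  expect_identical(classify_azole("C1CCNC1"), "none")           # not aromatic
  # invariant under SMILES rewriting of the same molecule
  expect_identical(classify_azole("C1=CN=CN1"), "diazole")
  expect_identical(classify_azole(standardize_smiles("c1cnc[nH]1")$smiles_parent),
                   "diazole")
  # the maximum over rings decides
  expect_identical(classify_azole("c1ccc(-c2nnn[nH]2)cc1"), "tetrazole")
})

test_that("CSV datasets round-trip and activity strings are normalized", {
  df <- data.frame(
    id = c("a", "b", "c", "d"),
    cas = c("50-00-0", "", "", ""),
    name = c("one", "two", "three", "four"),
    smiles = c("CCO", "c1ccccc1", "CC(=O)O", "CCN"),
    activity = c("Active agonist", "INACTIVE", "active antagonist",
                 "unknown"),
    stringsAsFactors = FALSE
  )
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  ds <- read_dataset(path)
  expect_s3_class(ds, "rax_dataset")
  expect_identical(ds$activity, c("active", "inactive", "active", "unknown"))
  out <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, out)
  back <- read_dataset(out)
  expect_identical(back$id, ds$id)
  expect_identical(back$smiles, ds$smiles)
  expect_identical(back$activity, ds$activity)
})

test_that("dataset validation rejects malformed input", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), tmp)
  expect_error(read_dataset(tmp), "empty")

  writeLines(c("id,cas,name,smiles,activity",
               "a,,x,CCO,active", "a,,y,CCN,inactive"), tmp)
  expect_error(read_dataset(tmp), "duplicate id")

  writeLines(c("id,name,smiles,activity", "a,x,CCO,active"), tmp)
  expect_error(read_dataset(tmp), "missing mandatory column")

  writeLines(c("id,cas,name,smiles,activity", "a,,x,CCO,sometimes"), tmp)
  expect_error(read_dataset(tmp), "unknown activity")
})

test_that("SDF datasets round-trip through property fields", {
  df <- data.frame(id = c("s1", "s2"), cas = c("", ""),
                   name = c("ethanol", "aniline"),
                   smiles = c("CCO", "Nc1ccccc1"),
                   activity = c("active", "inactive"),
                   stringsAsFactors = FALSE)
  ds <- rax_dataset(df)
  path <- withr::local_tempfile(fileext = ".sdf")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_identical(back$id, ds$id)
  expect_identical(back$activity, ds$activity)
  # structures survive the round trip up to canonicalization
  expect_equal(
    vapply(back$smiles, function(s) standardize_smiles(s)$structure_key, ""),
    vapply(ds$smiles, function(s) standardize_smiles(s)$structure_key, ""),
    ignore_attr = TRUE)
})

test_that("curation collapses structure-key duplicates", {
  df <- data.frame(
    id = c("a", "b", "c"),
    cas = "", name = c("x", "x-salt", "y"),
    # a and b are the same parent structure (salt vs free cation)
    smiles = c("CC[n+]1ccn(C)c1", "CC[n+]1ccn(C)c1.[Cl-]", "CCO"),
    activity = c("active", "active", "inactive"),
    ac50_nM = c(100, 200, NA),
    stringsAsFactors = FALSE
  )
  ds <- suppressWarnings(rax_dataset(df))
  cur <- curate_dataset(ds)
  expect_equal(nrow(cur$dataset), 2)
  expect_equal(nrow(cur$rejected), 0)
  merged <- cur$dataset[cur$dataset$activity == "active", ]
  expect_equal(merged$ac50_nM, sqrt(100 * 200), tolerance = 1e-8)
})
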