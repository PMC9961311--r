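# Shared, lazily built test objects. Fingerprinting every fixture compound
# takes a few seconds, so models are constructed once per test run.

.test_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- build()
  .test_cache[[key]]
}

case_model <- function(case) {
  memo(paste0("case_", case), function() {
    fx <- case_study_fixtures(case)
    list(fx = fx, model = rax(fx$dataset, profiles = fx$profiles))
  })
}

syn_model <- function() {
  memo("syn", function() {
    syn <- synthetic_azoles()
    list(syn = syn, model = rax(syn$dataset, profiles = syn$profiles))
  })
}

# imidazolium cation SMILES with an n-carbon chain on one ring nitrogen and
# a methyl on the charged one
im_smiles <- function(n) paste0(strrep("C", n), "n1cc[n+](C)c1")
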