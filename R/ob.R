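# Low-level wrappers around ChemmineOB / OpenBabel format conversion.

.rax_cache <- new.env(parent = emptyenv())

.ob_noopt <- data.frame(names = character(0), args = character(0))

ob_convert <- function(from, to, source) {
  out <- tryCatch(
    ChemmineOB::convertFormat(from, to, source, options = .ob_noopt),
    error = function(e) ""
  )
  trimws(out)
}

#' Structured parse error for bad SMILES input
#' @noRd
rax_parse_error <- function(smiles, msg = "SMILES could not be parsed") {
  cond <- structure(
    class = c("rax_parse_error", "error", "condition"),
    list(message = sprintf("%s: '%s'", msg, smiles), call = NULL,
         smiles = smiles)
  )
  stop(cond)
}

#' Canonical SMILES via OpenBabel; errors on unparsable input
#' @noRd
ob_cansmi <- function(smiles) {
  out <- ob_convert("SMI", "CAN", smiles)
  if (!nzchar(out)) rax_parse_error(smiles)
  # OB appends a title field after a tab
  sub("\t.*$", "", out)
}

#' Standard InChI of a structure (errors on unparsable input)
#' @noRd
ob_inchi <- function(smiles) {
  out <- ob_convert("SMI", "INCHI", smiles)
  out <- grep("^InChI=", strsplit(out, "\n")[[1]], value = TRUE)
  if (length(out) == 0) rax_parse_error(smiles)
  out[1]
}

# Parse the ATOM/BOND blocks of a MOL2 record into data frames.
# Atom order equals the SMILES parse order, so indices are stable across
# the molreport/MOL2 views of the same input.
parse_mol2 <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  a0 <- grep("@<TRIPOS>ATOM", lines, fixed = TRUE)[1]
  b0 <- grep("@<TRIPOS>BOND", lines, fixed = TRUE)[1]
  if (is.na(a0) || is.na(b0)) return(NULL)
  markers <- grep("@<TRIPOS>", lines, fixed = TRUE)
  a1 <- min(c(markers[markers > a0], length(lines) + 1L)) - 1L
  b1 <- min(c(markers[markers > b0], length(lines) + 1L)) - 1L
  atom_lines <- lines[seq(a0 + 1L, a1)]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  af <- strsplit(trimws(atom_lines), "[[:space:]]+")
  atoms <- data.frame(
    id   = vapply(af, function(x) as.integer(x[1]), integer(1)),
    type = vapply(af, function(x) x[6], character(1)),
    stringsAsFactors = FALSE
  )
  atoms$elem <- sub("\\..*$", "", atoms$type)
  bonds <- data.frame(a1 = integer(0), a2 = integer(0),
                      type = character(0), stringsAsFactors = FALSE)
  if (b1 >= b0 + 1L) {
    bond_lines <- lines[seq(b0 + 1L, b1)]
    bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
    if (length(bond_lines)) {
      bf <- strsplit(trimws(bond_lines), "[[:space:]]+")
      bonds <- data.frame(
        a1   = vapply(bf, function(x) as.integer(x[2]), integer(1)),
        a2   = vapply(bf, function(x) as.integer(x[3]), integer(1)),
        type = vapply(bf, function(x) x[4], character(1)),
        stringsAsFactors = FALSE
      )
    }
  }
  bonds$aromatic <- bonds$type == "ar"
  bonds$order <- ifelse(bonds$type %in% c("1", "am", "du", "un"), 1L,
                 ifelse(bonds$type == "2", 2L,
                 ifelse(bonds$type == "3", 3L, 1L)))
  # an atom is aromatic if it takes part in at least one aromatic bond
  # (MOL2 atom types underreport aromaticity for O/S ring atoms)
  atoms$aromatic <- atoms$id %in% c(bonds$a1[bonds$aromatic],
                                    bonds$a2[bonds$aromatic])
  list(atoms = atoms, bonds = bonds)
}

# Total hydrogen count parsed from a molecular formula such as "C6H11N2+"
formula_h_count <- function(formula) {
  # negative lookahead keeps He/Hf/Hg/Ho/Hs from matching as hydrogen
  m <- regmatches(formula,
                  gregexpr("H(?![a-z])[0-9]*", formula, perl = TRUE))[[1]]
  if (length(m) == 0) return(0L)
  n <- sub("^H", "", m[1])
  if (!nzchar(n)) 1L else as.integer(n)
}
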