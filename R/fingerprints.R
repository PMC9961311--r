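# 881-bit PubChem-style substructure keys and the Tanimoto coefficient.
#
# The key dictionary is the published PubChem substructure-key table, loaded
# from ChemmineR's copy of it. That copy drops everything from the first '#'
# character of a definition (a CSV-era comment artefact), so e.g. "C#C"
# became "C" and "N:C-S-[#1]" became "N:C-S-[". The affected entries are
# restored below from the published key list; six entries whose whole pattern
# started with "[#1]" are best-effort reconstructions and flagged as such in
# the emitted table. Tanimoto similarity depends only on the set of evaluated
# patterns, never on bit order.

# definitions restored at their published bit positions
.pcfp_repairs <- c(
  "417" = "C#C",
  "419" = "C#N",
  "427" = "C(#C)(-C)",
  "428" = "C(#C)(-H)",
  "429" = "C(#N)(-C)",
  "460" = "C-C-C#C",
  "466" = "N#C-C=C",
  "568" = "N#C-C-C",
  "676" = "N#C-C:C",
  "876" = "NC1C(Cl)CCC1"   # 5-ring pattern mistyped as a 4-ring in the copy
)

# hydrogen-anchored patterns reconstructed from the published list
.pcfp_reconstructed <- c(
  "510" = "[#1]-C-O-[#1]",
  "516" = "[#1]-N-N-[#1]",
  "528" = "[#1]-C-N-[#1]",
  "571" = "[#1]-C=C-[#1]",
  "599" = "[#1]-C-C-N-[#1]",
  "643" = "[#1]-C-C-O-[#1]"
)

.pcfp_sections <- data.frame(
  section = c("element_count", "ring_count", "atom_pair",
              "atom_neighborhood", "detailed_neighborhood",
              "simple_smarts", "complex_smarts"),
  from = c(0L, 115L, 263L, 327L, 416L, 460L, 713L),
  to   = c(114L, 262L, 326L, 415L, 459L, 712L, 880L),
  stringsAsFactors = FALSE
)

#' The 881-key substructure dictionary
#'
#' Returns the PubChem-style substructure key table evaluated by
#' [pubchem_fingerprint()]: bit position (0-based), key definition, section,
#' and a status column recording which truncated entries of the locally
#' available copy were repaired or reconstructed from the published list.
#'
#' @param path optional file path; when given, the table is also written
#'   there as a tab-separated file (the shipped-dictionary format).
#' @return a data frame with columns `bit`, `definition`, `section`,
#'   `status`.
#' @examples
#' keys <- fingerprint_keys()
#' nrow(keys)  # 881
#' @export
fingerprint_keys <- function(path = NULL) {
  if (is.null(.rax_cache$pcfp_keys)) {
    e <- new.env()
    utils::data("pubchemFPencoding", package = "ChemmineR", envir = e)
    tab <- e$pubchemFPencoding
    keys <- data.frame(
      bit = as.integer(tab$Bit_Position),
      definition = as.character(tab$Bit_Substructure),
      stringsAsFactors = FALSE
    )
    keys <- keys[order(keys$bit), ]
    keys$status <- "as_published"
    trunc <- grepl("\\[$", keys$definition)
    keys$definition[trunc] <- paste0(keys$definition[trunc], "#1]")
    keys$status[trunc] <- "repaired"
    i <- match(as.integer(names(.pcfp_repairs)), keys$bit)
    keys$definition[i] <- unname(.pcfp_repairs)
    keys$status[i] <- "repaired"
    j <- match(as.integer(names(.pcfp_reconstructed)), keys$bit)
    keys$definition[j] <- unname(.pcfp_reconstructed)
    keys$status[j] <- "reconstructed"
    keys$section <- vapply(keys$bit, function(b) {
      .pcfp_sections$section[.pcfp_sections$from <= b & b <= .pcfp_sections$to]
    }, character(1))
    rownames(keys) <- NULL
    .rax_cache$pcfp_keys <- keys[, c("bit", "definition", "section", "status")]
  }
  keys <- .rax_cache$pcfp_keys
  if (!is.null(path)) {
    utils::write.table(keys, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  keys
}

.elem_z <- c(H = 1, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9,
             Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17,
             K = 19, Ca = 20, As = 33, Se = 34, Br = 35, I = 53)

# Translate one linear key definition (sections 3-6) into a SMARTS string.
#
# Conventions of the published table: element tokens match the element
# regardless of aromaticity (=> [#n]); bonds are explicit (- = # : ~) with
# single as the branch default; hydrogens ("H" or "[#1]") become minimum
# H-count constraints on their heavy neighbour so that implicit-hydrogen
# molecules match. Single- and double-bond tokens are matched
# kekule-tolerantly ("-" => "-,:", "=" => "=,:"): aromatic systems also
# satisfy them, which reproduces how CDK-style implementations of these
# keys evaluate the patterns against kekulized aromatic rings.

.pcfp_bond_out <- c("-" = "-,:", "=" = "=,:", "#" = "#", ":" = ":",
                    "~" = "~")
pcfp_linear_smarts <- function(def, any_bond = FALSE) {
  s <- gsub("[#1]", "H", def, fixed = TRUE)
  s <- gsub("[As]", "As", s, fixed = TRUE)
  toks <- regmatches(s, gregexpr(
    "Cl|Br|Li|Na|Mg|Al|Si|As|Se|[BCNOFPSKIH]|[-=#:~()]", s))[[1]]
  if (sum(nchar(toks)) != nchar(s)) {
    stop("untranslatable key definition: ", def)
  }
  atoms <- list()   # z, hmin, parent, pbond
  stack <- integer(0)
  cur <- NA_integer_
  pending <- NULL
  pending_h <- 0L
  for (tok in toks) {
    if (tok == "(") {
      stack <- c(stack, cur)
    } else if (tok == ")") {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tok %in% c("-", "=", "#", ":", "~")) {
      pending <- tok
    } else if (tok == "H") {
      if (is.na(cur)) {
        pending_h <- pending_h + 1L
      } else {
        atoms[[cur]]$hmin <- atoms[[cur]]$hmin + 1L
      }
      pending <- NULL
    } else {
      i <- length(atoms) + 1L
      atoms[[i]] <- list(
        z = .elem_z[[tok]], hmin = pending_h,
        parent = cur,
        pbond = if (any_bond) "~" else if (is.null(pending)) "-" else pending
      )
      pending_h <- 0L
      cur <- i
      pending <- NULL
    }
  }
  if (length(atoms) == 0) stop("no heavy atom in key definition: ", def)
  atom_smarts <- function(i) {
    a <- atoms[[i]]
    h <- if (a$hmin > 0) {
      paste0(";", paste0("!H", seq_len(a$hmin) - 1L, collapse = ";"))
    } else ""
    paste0("[#", a$z, h, "]")
  }
  emit <- function(i) {
    kids <- which(vapply(atoms, function(a)
      identical(a$parent, i), logical(1)))
    paste0(atom_smarts(i),
           paste(vapply(kids, function(k)
             paste0("(", .pcfp_bond_out[[atoms[[k]]$pbond]], emit(k), ")"),
             character(1)),
             collapse = ""))
  }
  root <- which(vapply(atoms, function(a) is.na(a$parent), logical(1)))[1]
  emit(root)
}

# Ring substitution patterns (section 7): keep the ring skeleton as written
# (aromatic "c" ring or saturated "C" ring) and translate the two
# substituents into element-number atoms on kekule-tolerant single bonds.
pcfp_ring_smarts <- function(def) {
  m <- regexec("^(Cl|Br|[CNOS])(.*)$", def)[[1]]
  x <- regmatches(def, list(m))[[1]][2]
  core <- regmatches(def, list(m))[[1]][3]
  ym <- regexec("\\((Cl|Br|[CNOS])\\)", core)[[1]]
  y <- regmatches(core, list(ym))[[1]][2]
  core <- sub("\\((Cl|Br|[CNOS])\\)",
              sprintf("(-,:[#%d])", .elem_z[[y]]), core)
  paste0(sprintf("[#%d]-,:", .elem_z[[x]]), core)
}

# bit -> SMARTS table for sections 3-7 (computed once per session)
pcfp_smarts_table <- function() {
  if (is.null(.rax_cache$pcfp_smarts)) {
    keys <- fingerprint_keys()
    sel <- keys$bit >= 263L
    sub <- keys[sel, ]
    sub$smarts <- vapply(seq_len(nrow(sub)), function(i) {
      if (sub$section[i] == "atom_pair") {
        pcfp_linear_smarts(sub$definition[i], any_bond = TRUE)
      } else if (sub$section[i] == "complex_smarts") {
        pcfp_ring_smarts(sub$definition[i])
      } else {
        pcfp_linear_smarts(sub$definition[i])
      }
    }, character(1))
    .rax_cache$pcfp_smarts <- sub[, c("bit", "smarts")]
  }
  .rax_cache$pcfp_smarts
}

# counts for one ring-descriptor class
.ring_class_count <- function(ri, size, class) {
  sel <- ri$size == size
  sat_ar <- ri$saturated | ri$aromatic
  unsat <- !ri$aromatic & !ri$saturated
  n <- switch(class,
    "any" = sel,
    "saturated_or_aromatic_carbon-only" = sel & sat_ar & ri$carbon_only,
    "saturated_or_aromatic_nitrogen-containing" = sel & sat_ar & ri$has_n,
    "saturated_or_aromatic_heteroatom-containing" = sel & sat_ar & ri$has_hetero,
    "unsaturated_non-aromatic_carbon-only" = sel & unsat & ri$carbon_only,
    "unsaturated_non-aromatic_nitrogen-containing" = sel & unsat & ri$has_n,
    "unsaturated_non-aromatic_heteroatom-containing" = sel & unsat & ri$has_hetero,
    stop("unknown ring class: ", class))
  sum(n)
}

#' Compute the 881-bit PubChem-style substructure fingerprint
#'
#' Evaluates the full substructure-key dictionary (element counts, ring
#' counts over an ESSSR-style ring set, atom pairs, atom neighbourhoods and
#' the simple/complex SMARTS sections) for one structure. Fingerprints are
#' meant to be computed on the standardized parent structure (counter-ions
#' stripped, charges kept); see [standardize_smiles()].
#'
#' @param x a SMILES string (one structure).
#' @return an object of class `bitfp`: 881 ordered 0/1 bits plus a scheme
#'   tag (`"pubchem881"`).
#' @examples
#' fp <- pubchem_fingerprint("c1ccccc1")
#' sum(fp$bits)
#' @export
pubchem_fingerprint <- function(x) {
  mol <- rax_mol(x)
  keys <- fingerprint_keys()
  bits <- logical(881L)

  # hierarchic element counts
  s1 <- keys[keys$section == "element_count", ]
  m <- regmatches(s1$definition,
                  regexec("^>=_([0-9]+)_(\\S+)$", s1$definition))
  need <- as.integer(vapply(m, `[`, character(1), 2))
  sym <- vapply(m, `[`, character(1), 3)
  tab <- table(mol$atoms$elem)
  have <- ifelse(sym == "H", mol$n_h,
                 as.integer(tab[sym]))
  have[is.na(have)] <- 0L
  bits[s1$bit + 1L] <- have >= need

  # ring counts
  ri <- ring_info(mol)
  s2 <- keys[keys$section == "ring_count", ]
  for (i in seq_len(nrow(s2))) {
    d <- s2$definition[i]
    if (grepl("_ring_size_", d)) {
      m2 <- regexec("^>=_([0-9]+)_(.+)_ring_size_([0-9]+)$", d)[[1]]
      g <- regmatches(d, list(m2))[[1]]
      bits[s2$bit[i] + 1L] <-
        .ring_class_count(ri, as.integer(g[4]), g[3]) >= as.integer(g[2])
    } else {
      # aromatic / hetero-aromatic ring totals
      g <- regmatches(d, list(regexec("^>=_([0-9]+)_(.+)$", d)[[1]]))[[1]]
      cnt <- if (grepl("hetero", g[3])) {
        sum(ri$aromatic & ri$has_hetero)
      } else {
        sum(ri$aromatic)
      }
      bits[s2$bit[i] + 1L] <- cnt >= as.integer(g[2])
    }
  }

  # SMARTS sections, one OpenBabel pass over all patterns
  st <- pcfp_smarts_table()
  hits <- ChemmineOB::forEachMol("SMILES", mol$smiles, function(m) {
    vapply(st$smarts, function(s) {
      ChemmineOB::smartsSearch_OB(list(m), s, uniqueMatches = TRUE)
    }, numeric(1))
  })[[1]]
  bits[st$bit + 1L] <- hits > 0

  structure(
    list(bits = as.integer(bits), scheme = "pubchem881", smiles = mol$cansmi),
    class = "bitfp"
  )
}

#' @export
print.bitfp <- function(x, ...) {
  cat(sprintf("<bitfp %s: %d/%d bits set> %s\n",
              x$scheme, sum(x$bits), length(x$bits), x$smiles))
  invisible(x)
}

#' Export a fingerprint as a hexadecimal string
#'
#' Bits are packed most-significant-bit first into bytes; the final byte is
#' zero-padded.
#' @param fp a `bitfp` object.
#' @return a single hexadecimal string.
#' @export
fp_hex <- function(fp) {
  paste(sprintf("%02x", as.integer(fp_pack(fp))), collapse = "")
}

#' Export a fingerprint in the length-prefixed binary layout
#'
#' The native exchange layout for substructure fingerprints: a four-byte
#' big-endian integer holding the bit-list length, followed by the packed
#' bits.
#' @param fp a `bitfp` object.
#' @return a raw vector.
#' @export
fp_raw <- function(fp) {
  n <- length(fp$bits)
  prefix <- as.raw(c(
    bitwAnd(bitwShiftR(n, 24), 255L), bitwAnd(bitwShiftR(n, 16), 255L),
    bitwAnd(bitwShiftR(n, 8), 255L), bitwAnd(n, 255L)
  ))
  c(prefix, fp_pack(fp))
}

fp_pack <- function(fp) {
  bits <- fp$bits
  pad <- (8L - length(bits) %% 8L) %% 8L
  bits <- c(bits, rep(0L, pad))
  bytes <- matrix(bits, nrow = 8L)
  as.raw(colSums(bytes * 2L^(7:0)))
}

#' Tanimoto similarity between two binary vectors
#'
#' For binary bit vectors the Tanimoto coefficient reduces to
#' `c / (n_a + n_b - c)` where `c` is the number of shared set bits and
#' `n_a`, `n_b` the set-bit counts. The coefficient is symmetric and lies
#' in \[0, 1\].
#'
#' @param a,b `bitfp` objects or plain binary vectors of equal length (and,
#'   for `bitfp`, equal scheme).
#' @param zero_zero policy when both vectors are all-zero: `"error"`
#'   (default, appropriate for structural fingerprints where an empty
#'   fingerprint indicates a pathological input) or `"one"` (identical
#'   predicted behaviour, used for metabolic profiles).
#' @return similarity in \[0, 1\].
#' @examples
#' tanimoto(c(1, 0, 1, 0, 0), c(1, 0, 0, 0, 0))  # 0.5
#' @export
tanimoto <- function(a, b, zero_zero = c("error", "one")) {
  zero_zero <- match.arg(zero_zero)
  if (inherits(a, "bitfp") || inherits(b, "bitfp")) {
    if (!(inherits(a, "bitfp") && inherits(b, "bitfp"))) {
      stop("cannot compare a bitfp with a plain vector")
    }
    if (!identical(a$scheme, b$scheme)) {
      stop("fingerprint schemes differ: ", a$scheme, " vs ", b$scheme)
    }
    a <- a$bits; b <- b$bits
  }
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b)) stop("bit vectors differ in width")
  if (!all(a %in% c(0L, 1L)) || !all(b %in% c(0L, 1L))) {
    stop("entries must be binary (0/1)")
  }
  na <- sum(a); nb <- sum(b); cc <- sum(a & b)
  if (na + nb == 0L) {
    if (zero_zero == "one") return(1) else stop("both vectors are all-zero")
  }
  cc / (na + nb - cc)
}
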