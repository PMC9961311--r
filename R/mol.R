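# Internal molecule model: atoms, bonds, aromaticity, rings.
#
# All structure perception (SMILES parsing, aromaticity, canonicalisation,
# InChI) is delegated to OpenBabel through ChemmineOB; this file only builds
# an R-side graph view plus an ESSSR-style ring set on top of it.

#' Build the internal molecule object for one SMILES
#'
#' @param smiles a single SMILES string.
#' @return a `rax_mol` list: canonical SMILES, atom/bond tables (with
#'   aromatic flags from OpenBabel), total hydrogen count and the perceived
#'   ring set.
#' @noRd
rax_mol <- function(smiles) {
  if (inherits(smiles, "rax_mol")) return(smiles)
  stopifnot(is.character(smiles), length(smiles) == 1)
  smi <- trimws(smiles)
  if (!nzchar(smi)) rax_parse_error(smiles, "empty SMILES")
  cansmi <- ob_cansmi(smi)
  graph <- parse_mol2(ob_convert("SMI", "MOL2", smi))
  if (is.null(graph)) rax_parse_error(smiles)
  report <- ob_convert("SMI", "molreport", smi)
  formula <- sub("^FORMULA:\\s*", "",
                 grep("^FORMULA:", strsplit(report, "\n")[[1]], value = TRUE)[1])
  structure(
    list(
      smiles  = smi,
      cansmi  = cansmi,
      atoms   = graph$atoms,
      bonds   = graph$bonds,
      n_h     = formula_h_count(formula),
      formula = formula,
      rings   = essr_rings(graph$atoms, graph$bonds)
    ),
    class = "rax_mol"
  )
}

#' ESSSR-style ring perception
#'
#' For every bond that lies on a cycle, take the smallest ring through that
#' bond (breadth-first search between its end points with the bond removed)
#' and de-duplicate by atom set. This reproduces the extended
#' smallest-set-of-smallest-rings used by substructure-key fingerprints for
#' ordinary fused and spiro systems.
#'
#' @return list of integer vectors, each the ordered atom ids of one ring.
#' @noRd
essr_rings <- function(atoms, bonds, max_size = 14L) {
  n <- nrow(atoms)
  if (n == 0 || nrow(bonds) == 0) return(list())
  adj <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    a <- bonds$a1[i]; b <- bonds$a2[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  rings <- list()
  seen <- character(0)
  for (i in seq_len(nrow(bonds))) {
    a <- bonds$a1[i]; b <- bonds$a2[i]
    path <- bfs_shortest_path(adj, from = a, to = b,
                              forbid = c(a, b), max_len = max_size - 1L)
    if (is.null(path)) next
    ring <- path  # path runs a .. b; closing bond a-b completes the ring
    key <- paste(sort(ring), collapse = ",")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- ring
    }
  }
  rings
}

# Shortest path from `from` to `to` that does not use the direct edge
# between them. `forbid` marks that edge via its two endpoints.
bfs_shortest_path <- function(adj, from, to, forbid, max_len) {
  prev <- rep(NA_integer_, length(adj))
  prev[from] <- from
  frontier <- from
  depth <- 0L
  while (length(frontier) > 0 && depth < max_len) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (v == from && w == to) next  # skip the direct bond
        if (!is.na(prev[w])) next
        prev[w] <- v
        if (w == to) {
          path <- w
          while (path[1] != from) path <- c(prev[path[1]], path)
          return(path)
        }
        nxt <- c(nxt, w)
      }
    }
    frontier <- nxt
    depth <- depth + 1L
  }
  NULL
}

# Ring feature summary used by the fingerprint ring section and by
# azole classification.
ring_info <- function(mol) {
  rings <- mol$rings
  if (length(rings) == 0) {
    return(data.frame(size = integer(0), aromatic = logical(0),
                      saturated = logical(0), carbon_only = logical(0),
                      has_n = logical(0), has_hetero = logical(0),
                      n_nitrogen = integer(0)))
  }
  bond_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  btab <- mol$bonds
  bmap_ar <- stats::setNames(btab$aromatic, bond_key(btab$a1, btab$a2))
  bmap_ord <- stats::setNames(btab$order, bond_key(btab$a1, btab$a2))
  do.call(rbind, lapply(rings, function(r) {
    k <- bond_key(r, c(r[-1], r[1]))
    elems <- mol$atoms$elem[r]
    aromatic <- all(bmap_ar[k])
    data.frame(
      size = length(r),
      aromatic = aromatic,
      saturated = !aromatic && all(bmap_ord[k] == 1L),
      carbon_only = all(elems == "C"),
      has_n = any(elems == "N"),
      has_hetero = any(elems != "C"),
      n_nitrogen = sum(elems == "N")
    )
  }))
}
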