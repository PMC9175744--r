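# SMILES -> molecular graph, via OpenBabel (ChemmineOB). The V2000 molblock
# OpenBabel emits is parsed with a minimal fixed-layout reader because the
# general-purpose SDF readers available reject degenerate zero-bond
# molecules (methane, water), which are legitimate inputs here.
parse_smiles <- function(smiles, what = "SMILES") {
  if (is.na(smiles) || !nzchar(trimws(smiles))) {
    rlang::abort(paste0("empty ", what),
                 class = "signetpharm_parse_error")
  }
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, " mol\n")),
    error = function(e) ""
  )
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  counts_at <- grep("V2000", lines)[1]
  if (is.na(counts_at)) {
    rlang::abort(paste0("unparseable ", what, ": ", smiles),
                 class = "signetpharm_parse_error")
  }
  counts <- lines[counts_at]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  if (is.na(n_atoms) || n_atoms < 1) {
    rlang::abort(paste0("unparseable ", what, ": ", smiles),
                 class = "signetpharm_parse_error")
  }
  atom_lines <- lines[counts_at + seq_len(n_atoms)]
  elem <- trimws(substr(atom_lines, 32, 34))
  bonds <- if (n_bonds > 0) {
    bl <- lines[counts_at + n_atoms + seq_len(n_bonds)]
    tibble::tibble(
      a1 = as.integer(substr(bl, 1, 3)),
      a2 = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  } else {
    tibble::tibble(a1 = integer(), a2 = integer(), order = integer())
  }
  charge <- numeric(n_atoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    k <- f[1]
    for (j in seq_len(k)) {
      charge[f[2 * j]] <- f[2 * j + 1]
    }
  }
  list(elem = elem, charge = charge, bonds = bonds)
}

# periodic numbers and typical valences for implicit-hydrogen counting;
# elements outside the table get no implicit hydrogens
element_numbers <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14,
                     P = 15, S = 16, Cl = 17, Br = 35, I = 53)
typical_valence <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1,
                     P = 3, S = 2, Cl = 1, Br = 1, I = 1)

mol_features <- function(mol) {
  n <- length(mol$elem)
  deg <- tabulate(c(mol$bonds$a1, mol$bonds$a2), nbins = n)
  bond_order_sum <- numeric(n)
  ord <- ifelse(mol$bonds$order == 4L, 1.5, mol$bonds$order)
  for (i in seq_len(nrow(mol$bonds))) {
    bond_order_sum[mol$bonds$a1[i]] <- bond_order_sum[mol$bonds$a1[i]] + ord[i]
    bond_order_sum[mol$bonds$a2[i]] <- bond_order_sum[mol$bonds$a2[i]] + ord[i]
  }
  val <- typical_valence[mol$elem]
  val[is.na(val)] <- 0
  n_h <- pmax(0, round(val - bond_order_sum + mol$charge *
                         ifelse(mol$elem %in% c("N", "P", "S"), 1, -1)))
  in_ring <- logical(n)
  if (nrow(mol$bonds) > 0 && n >= 3) {
    g <- igraph::graph_from_edgelist(cbind(mol$bonds$a1, mol$bonds$a2),
                                     directed = FALSE)
    if (igraph::vcount(g) < n) {
      g <- igraph::add_vertices(g, n - igraph::vcount(g))
    }
    bc <- igraph::biconnected_components(g)
    for (comp in bc$components) {
      if (length(comp) >= 3) in_ring[as.integer(comp)] <- TRUE
    }
  }
  znum <- element_numbers[mol$elem]
  znum[is.na(znum)] <- 0
  list(z = as.integer(znum), degree = deg,
       bond_order_sum = as.integer(round(bond_order_sum * 2)),
       charge = as.integer(mol$charge), n_h = as.integer(n_h),
       in_ring = as.integer(in_ring))
}

#' Circular (Morgan-style) fingerprint of a molecule
#'
#' Encodes substructure as a fixed-length bit vector by iterative
#' neighbourhood hashing, the extended-connectivity scheme: each atom
#' starts from an invariant (atomic number, heavy-atom degree, total bond
#' order, formal charge, attached hydrogens, ring membership) and at each
#' round its identifier is rehashed together with the sorted
#' (bond order, identifier) pairs of its neighbours, capturing circular
#' substructures of growing radius. Every identifier produced in rounds
#' `0..radius` sets the bit `id mod n_bits`. SMILES parsing is delegated
#' to OpenBabel; stereochemistry, when absent from the input string, does
#' not enter the invariants.
#'
#' @param smiles a single SMILES string.
#' @param radius neighbourhood radius (default 2, i.e. ECFP4-like).
#' @param n_bits fingerprint length (default 2048).
#' @return integer vector of 0/1 of length `n_bits`.
#' @export
#' @examples
#' sum(morgan_fingerprint("CCO")) # a handful of bits for ethanol
morgan_fingerprint <- function(smiles, radius = 2, n_bits = 2048) {
  if (radius < 0 || n_bits < 1) {
    rlang::abort("radius must be >= 0 and n_bits >= 1",
                 class = "signetpharm_value_error")
  }
  mol <- parse_smiles(smiles)
  ft <- mol_features(mol)
  n <- length(mol$elem)
  ids <- vapply(seq_len(n), function(a) {
    fnv1a(c(ft$z[a], ft$degree[a], ft$bond_order_sum[a],
            ft$charge[a] + 8, ft$n_h[a], ft$in_ring[a]))
  }, numeric(1))
  all_ids <- ids
  if (radius > 0 && nrow(mol$bonds) > 0) {
    nbrs <- lapply(seq_len(n), function(a) {
      sel1 <- mol$bonds$a1 == a
      sel2 <- mol$bonds$a2 == a
      cbind(order = c(mol$bonds$order[sel1], mol$bonds$order[sel2]),
            atom = c(mol$bonds$a2[sel1], mol$bonds$a1[sel2]))
    })
    for (r in seq_len(radius)) {
      ids <- vapply(seq_len(n), function(a) {
        nb <- nbrs[[a]]
        if (nrow(nb) == 0) return(fnv1a(c(r, ids[a])))
        pairs <- cbind(nb[, "order"], ids[nb[, "atom"]])
        pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
        fnv1a(c(r, ids[a], as.numeric(t(pairs))))
      }, numeric(1))
      all_ids <- c(all_ids, ids)
    }
  }
  bits <- integer(n_bits)
  bits[unique(all_ids %% n_bits) + 1] <- 1L
  bits
}

#' Tanimoto similarity of two molecules
#'
#' `|A & B| / |A | B|` on circular fingerprints of the two SMILES. Two
#' identical input strings always score 1; note that canonical SMILES
#' lacking stereochemistry make stereoisomers indistinguishable by
#' construction (the fingerprint honours only what the string encodes).
#'
#' @param smiles_a,smiles_b SMILES strings.
#' @inheritParams morgan_fingerprint
#' @return similarity in `[0, 1]`.
#' @export
fingerprint_tanimoto <- function(smiles_a, smiles_b, radius = 2,
                                 n_bits = 2048) {
  fa <- morgan_fingerprint(smiles_a, radius, n_bits)
  fb <- morgan_fingerprint(smiles_b, radius, n_bits)
  union <- sum(fa | fb)
  if (union == 0) {
    rlang::abort("both fingerprints are empty; similarity undefined",
                 class = "signetpharm_value_error")
  }
  sum(fa & fb) / union
}
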