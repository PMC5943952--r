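# Aromaticity convention and the amidinium charge-localisation rule.
#
# The parameter tables imply a deliberately narrow aromaticity model:
# six-membered rings made of carbon and nitrogen (benzene, pyridine,
# pyridinium, fused carbo/azaarenes) are aromatic, while five-membered
# heteroaromatics (furan, thiophene, pyrrole) are treated in their Kekule
# form -- their centers appear in the tables as sp2 groups such as
# "C sp2 H=CS".  The one exception is the amidinium N-C(+)-N motif of
# imidazolium and guanidinium cations, whose two (or three) C-N bonds are
# aromatic with the positive charge on the central carbon.
#
# Readers therefore (1) kekulise any aromatic bonds present in the input,
# (2) apply the amidinium rewrite, and (3) re-aromatise six-membered C/N
# rings, giving one canonical internal representation regardless of how
# the structure was drawn.

# ---- ring enumeration -------------------------------------------------

# All simple cycles of size min_size..max_size, as lists of atom index
# vectors (each cycle once, starting at its smallest atom index).
find_rings <- function(mol, min_size = 3L, max_size = 7L) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
  }
  rings <- list()
  seen <- character()
  # DFS from each start atom; only visit atoms >= start to avoid duplicates
  for (start in seq_len(n)) {
    path <- integer(max_size)
    walk <- function(v, depth) {
      path[depth] <<- v
      for (w in adj[[v]]) {
        if (w == start && depth >= min_size) {
          cyc <- path[1:depth]
          key <- paste(sort(cyc), collapse = ",")
          if (!key %in% seen) { seen <<- c(seen, key); rings[[length(rings) + 1L]] <<- cyc }
        } else if (w > start && depth < max_size && !w %in% path[1:depth]) {
          walk(w, depth + 1L)
        }
      }
    }
    walk(start, 1L)
  }
  rings
}

bond_index <- function(mol, i, j) {
  which((mol$bonds$i == i & mol$bonds$j == j) |
        (mol$bonds$i == j & mol$bonds$j == i))
}

# ---- kekulisation -----------------------------------------------------

# Replace aromatic (order 4) bonds by an alternating single/double pattern.
# Backtracking matching on the aromatic subgraph: neutral carbons must
# receive exactly one double bond (unless they already carry a double bond,
# e.g. an exocyclic carbonyl); heteroatoms and charged carbons may instead
# contribute a lone pair / empty orbital and stay unmatched.
kekulize <- function(mol, keep_bonds = integer()) {
  # aromatic C-N bonds of an already-normalised amidinium motif (charged
  # central carbon) are part of the charge convention, not of a ring
  # alternation pattern: leave them untouched
  keep_bonds <- union(keep_bonds, amidinium_motif_bonds(mol))
  ar <- setdiff(which(mol$bonds$order == BOND_AROMATIC), keep_bonds)
  if (!length(ar)) return(mol)
  atoms <- sort(unique(c(mol$bonds$i[ar], mol$bonds$j[ar])))
  inc <- incident_bonds(mol)
  must <- logical(n_atoms(mol))      # has to receive exactly one double
  can  <- logical(n_atoms(mol))      # may receive a double
  for (a in atoms) {
    el <- mol$atoms$element[a]; chg <- mol$atoms$charge[a]
    has_double <- any(mol$bonds$order[inc[[a]]] %in% c(BOND_DOUBLE, BOND_TRIPLE))
    can[a] <- el %in% c("C", "N") && !has_double
    must[a] <- el == "C" && chg == 0L && !has_double
  }
  matched <- logical(n_atoms(mol))
  assign <- logical(length(ar))   # TRUE -> becomes double
  order_try <- ar[order(-(must[mol$bonds$i[ar]] | must[mol$bonds$j[ar]]))]

  solve <- function(k) {
    if (k > length(order_try)) {
      return(all(!must[atoms] | matched[atoms]))
    }
    e <- order_try[k]
    i <- mol$bonds$i[e]; j <- mol$bonds$j[e]
    if (can[i] && can[j] && !matched[i] && !matched[j]) {
      matched[i] <<- TRUE; matched[j] <<- TRUE
      assign[match(e, ar)] <<- TRUE
      if (solve(k + 1L)) return(TRUE)
      matched[i] <<- FALSE; matched[j] <<- FALSE
      assign[match(e, ar)] <<- FALSE
    }
    if (solve(k + 1L)) return(TRUE)
    FALSE
  }
  if (!solve(1L))
    stop("cannot kekulize aromatic system in ", mol$id %||% mol$name)
  mol$bonds$order[ar] <- ifelse(assign, BOND_DOUBLE, BOND_SINGLE)
  mol
}

# bond rows of aromatic C-N bonds around positively charged carbons with
# at least two such bonds (the normalised amidinium motif)
amidinium_motif_bonds <- function(mol) {
  out <- integer()
  for (c_at in which(mol$atoms$element == "C" & mol$atoms$charge == 1L)) {
    k <- which(((mol$bonds$i == c_at & mol$atoms$element[mol$bonds$j] == "N") |
                (mol$bonds$j == c_at & mol$atoms$element[mol$bonds$i] == "N")) &
               mol$bonds$order == BOND_AROMATIC)
    if (length(k) >= 2L) out <- c(out, k)
  }
  out
}

# ---- six-membered ring aromatisation ----------------------------------

# A six-cycle is aromatic when every member is C or N and every member has
# exactly one double bond whose partner lies in the same ring or in another
# qualifying ring (fused systems); triple bonds disqualify.  Evaluated on
# the kekulised bond orders, then all intra-ring bonds of accepted rings
# are set to order 4.
aromatize_six_rings <- function(mol) {
  rings <- Filter(function(r) length(r) == 6L, find_rings(mol, 6L, 6L))
  if (!length(rings)) return(mol)
  inc <- incident_bonds(mol)
  dbl_partner <- rep(NA_integer_, n_atoms(mol))
  ok_atom <- logical(n_atoms(mol))
  for (a in seq_len(n_atoms(mol))) {
    if (!mol$atoms$element[a] %in% c("C", "N")) next
    ords <- mol$bonds$order[inc[[a]]]
    if (any(ords == BOND_TRIPLE)) next
    dbl <- inc[[a]][ords == BOND_DOUBLE]
    if (length(dbl) != 1L) next
    ok_atom[a] <- TRUE
    dbl_partner[a] <- ifelse(mol$bonds$i[dbl] == a, mol$bonds$j[dbl], mol$bonds$i[dbl])
  }
  cand <- Filter(function(r) all(ok_atom[r]), rings)
  if (!length(cand)) return(mol)
  # fixpoint: partner must lie in the ring itself or in the aromatic set
  accepted <- logical(length(cand))
  repeat {
    pool <- unique(unlist(cand[accepted]))
    new <- FALSE
    for (k in seq_along(cand)) {
      if (accepted[k]) next
      r <- cand[[k]]
      if (all(dbl_partner[r] %in% c(r, pool))) { accepted[k] <- TRUE; new <- TRUE }
    }
    if (!new) break
  }
  for (r in cand[accepted]) {
    m <- length(r)
    for (t in seq_len(m)) {
      k <- bond_index(mol, r[t], r[t %% m + 1L])
      if (length(k)) mol$bonds$order[k] <- BOND_AROMATIC
    }
  }
  mol
}

# ---- amidinium normalisation ------------------------------------------

#' Apply the amidinium/imidazolium/guanidinium charge convention
#'
#' Cations in which a carbon sits between two (or three) nitrogen atoms --
#' imidazolium, amidinium, guanidinium -- are conventionally drawn with the
#' positive charge on a nitrogen, but the charge actually resides on the
#' central carbon.  This rewrite moves the formal charge from the nitrogen
#' to the central carbon and makes its C-N bonds aromatic; the remainder of
#' an imidazolium ring keeps its Kekule pattern (so C4/C5 stay an sp2
#' double bond).  Structures already in this convention are returned
#' unchanged; the operation is idempotent and preserves the molecular
#' formula and the net charge.
#'
#' @param mol a [molgraph].
#' @return the rewritten [molgraph].
#' @export
normalize_amidinium <- function(mol) {
  inc <- incident_bonds(mol)
  for (c_at in which(mol$atoms$element == "C")) {
    nb <- atom_neighbors(mol, c_at, inc)
    nn <- nb$j[mol$atoms$element[nb$j] == "N"]
    if (length(nn) < 2L) next
    n_pos <- nn[mol$atoms$charge[nn] == 1L]
    c_chg <- mol$atoms$charge[c_at]
    # the motif must be conjugated: unless the charge is already on the
    # carbon, at least one C-N bond must be double or aromatic (this keeps
    # e.g. gem-dinitro carbons out of the rewrite)
    cn_orders <- mol$bonds$order[vapply(nn, function(j) bond_index(mol, c_at, j), 1L)]
    if (c_chg != 1L && !any(cn_orders %in% c(BOND_DOUBLE, BOND_AROMATIC))) next

    already <- c_chg == 1L &&
      sum(mol$bonds$order[unlist(lapply(nn, function(j) bond_index(mol, c_at, j)))] ==
            BOND_AROMATIC) >= 2L
    if (already) next

    if (c_chg == 1L && length(n_pos) == 0L) {
      # drawn with the charge in place but single/double C-N bonds
    } else if (c_chg == 0L && length(n_pos) == 1L) {
      # drawn with the charge on one nitrogen
    } else if (length(n_pos) >= 1L) {
      warning("amidinium-like motif at atom ", c_at,
              " cannot be rewritten consistently; left unchanged")
      next
    } else {
      next  # neutral amidine: nothing to do
    }

    if (length(n_pos) == 1L) {
      mol$atoms$charge[n_pos] <- 0L
      mol$atoms$charge[c_at] <- 1L
    }
    motif_bonds <- integer()
    for (j in nn) {
      k <- bond_index(mol, c_at, j)
      mol$bonds$order[k] <- BOND_AROMATIC
      motif_bonds <- c(motif_bonds, k)
    }
    # if the motif sat in a fully aromatic ring, re-kekulise the remainder
    mol <- kekulize(mol, keep_bonds = motif_bonds)
    inc <- incident_bonds(mol)
  }
  mol
}
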