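# Radical breakdown of a molecule into atom-centered groups.
#
# Every group center is one heavy atom classified by element, formal
# charge, and hybridisation/aromaticity, paired with a canonical string
# encoding of its immediate bonded neighbourhood.  The (atom type,
# neighbour string) pair indexes one row of a parameter table.

# ---- group centers ----------------------------------------------------

# Heavy atoms are group centers except: halogens; terminal O/N/S attached
# through a multiple bond (carbonyl, nitrile, sulfonyl/phosphoryl/nitro
# oxygens, thiocarbonyl); and terminal negatively charged oxygens
# (carboxylate, sulfonate, nitro).  These appear in the tables only inside
# neighbour strings, never as center rows.
is_group_center <- function(mol, a, inc = incident_bonds(mol)) {
  el <- mol$atoms$element[a]
  if (el == "H" || el %in% HALOGENS) return(FALSE)
  nb <- atom_neighbors(mol, a, inc)
  if (el %in% c("O", "N", "S") && nrow(nb) == 1L) {
    if (nb$order[1] %in% c(BOND_DOUBLE, BOND_TRIPLE)) return(FALSE)
    if (el == "O" && mol$atoms$charge[a] == -1L) return(FALSE)
  }
  TRUE
}

group_centers <- function(mol) {
  inc <- incident_bonds(mol)
  which(vapply(seq_len(n_atoms(mol)), is_group_center, TRUE, mol = mol, inc = inc))
}

charge_mark <- function(chg) {
  if (chg > 0L) "(+)" else if (chg < 0L) "(-)" else ""
}

#' Atom-type label of a group center
#'
#' Classifies a heavy non-halogen atom by element, formal charge and
#' hybridisation: carbon and nitrogen are `sp3`, `sp2`, `sp` or `aromatic`
#' (from the bond pattern, never geometry), sulfur is `S2` (divalent) or
#' `S4` (hypervalent), neutral 4-coordinate phosphorus is `P4`, and charged
#' P/B drop the coordination digit (`P(+)`, `P(-)`, `B(-)`).  Oxygen is a
#' single class `O`; its context lives in the neighbour string.
#'
#' @param mol a [molgraph].
#' @param a atom index; must be a group center (not H or halogen).
#' @return the atom-type label, e.g. `"C sp3"` or `"N(+) aromatic"`.
#' @export
atom_type <- function(mol, a) {
  inc <- incident_bonds(mol)
  el <- mol$atoms$element[a]
  if (el == "H" || el %in% HALOGENS)
    stop("atom ", a, " (", el, ") is not a group center")
  chg <- mol$atoms$charge[a]
  mk <- charge_mark(chg)
  nb <- atom_neighbors(mol, a, inc)
  ords <- nb$order
  hyb <- if (any(ords == BOND_AROMATIC)) "aromatic"
    else if (sum(ords == BOND_TRIPLE) >= 1L || sum(ords == BOND_DOUBLE) >= 2L) "sp"
    else if (any(ords == BOND_DOUBLE)) "sp2"
    else "sp3"
  conn <- nrow(nb) + mol$atoms$hcount[a]
  switch(el,
    "C" = paste0("C", mk, " ", hyb),
    "N" = if (chg < 0L) "N(-)" else paste0("N", mk, " ", hyb),
    "O" = paste0("O", mk),
    "S" = if (chg != 0L) paste0("S", mk) else if (conn <= 2L) "S2"
          else if (conn <= 4L) "S4" else "S6",
    "P" = if (chg != 0L) paste0("P", mk) else paste0("P", conn),
    "Si" = paste0("Si", mk),
    "B" = paste0("B", mk),
    paste0(el, mk))
}

#' Canonical neighbour string of a group center
#'
#' Deterministic encoding of the immediate neighbourhood: implicit
#' hydrogens first (`H`, `H2`, `H3`), then one token per heavy neighbour
#' made of a bond marker (none single, `=` double, `#` triple, `:`
#' aromatic) and the element symbol (iodine written `J`), identical tokens
#' aggregated with a trailing count.  Tokens are ordered element-major
#' (B, C, N, O, P, S, Si, then F, Cl, Br, J) and, within an element, by
#' bond marker.  Formal charges of neighbours are appended as `(+)`/`(-)`
#' markers at the end of the string.  For centers of type `N sp3`, `O` and
#' `S2` the bond markers are dropped and a trailing `(pi)`/`(2pi)` records
#' how many neighbours are aromatic or multiply bonded.
#'
#' @param mol a [molgraph].
#' @param a atom index of a group center.
#' @return the neighbour string, e.g. `"H2CO"`, `"CO=O(-)"` or `"HC(pi)"`.
#' @export
canonical_neighbor_string <- function(mol, a) {
  inc <- incident_bonds(mol)
  nb <- atom_neighbors(mol, a, inc)
  h <- mol$atoms$hcount[a]
  hpart <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
  ctype <- atom_type(mol, a)
  pi_style <- ctype %in% c("N sp3", "O", "S2")

  if (!nrow(nb))
    return(paste0(hpart))

  el <- mol$atoms$element[nb$j]
  el[el == "I"] <- "J"
  marker <- c("", "=", "#", ":")[nb$order]
  if (pi_style) marker <- rep("", nrow(nb))
  erank <- match(el, NEIGHBOR_ELEMENT_ORDER)
  mrank <- match(marker, c("", "=", "#", ":"))
  ord <- order(erank, mrank)
  el <- el[ord]; marker <- marker[ord]
  nbj <- nb$j[ord]

  tok <- paste0(marker, el)
  r <- rle(tok)
  body <- paste0(r$values, ifelse(r$lengths > 1L, r$lengths, ""), collapse = "")

  charges <- mol$atoms$charge[nbj]
  cpart <- paste(vapply(charges[charges != 0L], charge_mark, ""), collapse = "")

  pipart <- ""
  if (pi_style) {
    is_pi <- vapply(nbj, function(j) {
      o <- mol$bonds$order[inc[[j]]]
      any(o %in% c(BOND_DOUBLE, BOND_TRIPLE, BOND_AROMATIC))
    }, TRUE)
    np <- sum(is_pi)
    if (np == 1L) pipart <- "(pi)" else if (np > 1L) pipart <- sprintf("(%dpi)", np)
  }
  paste0(hpart, body, cpart, pipart)
}

# ---- special groups ---------------------------------------------------

#' Hydrocarbon special-group counts
#'
#' For molecules containing only carbon and hydrogen, every carbon atom
#' contributes one additional per-carbon term: the alkane term when all
#' bonds are single, otherwise the unsaturated-hydrocarbon term.  Any
#' heteroatom switches both counts off.
#'
#' @param mol a [molgraph].
#' @return named integer vector `c(alkane_C = ..., unsatHC_C = ...)`.
#' @export
detect_hydrocarbon_special <- function(mol) {
  out <- c(alkane_C = 0L, unsatHC_C = 0L)
  els <- mol$atoms$element
  if (!all(els %in% c("C", "H"))) return(out)
  ncarb <- sum(els == "C")
  if (nrow(mol$bonds) && any(mol$bonds$order != BOND_SINGLE))
    out["unsatHC_C"] <- ncarb
  else
    out["alkane_C"] <- ncarb
  out
}

#' Intramolecular hydrogen-bond (H-acceptor) count
#'
#' Counts unordered donor/acceptor atom pairs -- a donor N or O carrying at
#' least one hydrogen, an acceptor N or O -- whose topological separation
#' admits a 5- to 7-membered hydrogen-bonded ring (graph distance 3 to 5
#' between the heavy atoms).  Each pair is counted once.  The detector is
#' off by default during prediction because only six molecules supported
#' the corresponding parameter.
#'
#' @param mol a [molgraph].
#' @return integer count of hydrogen-bond pairs.
#' @export
detect_h_acceptor <- function(mol) {
  idx <- which(mol$atoms$element %in% c("N", "O"))
  if (length(idx) < 2L) return(0L)
  donors <- idx[mol$atoms$hcount[idx] > 0L]
  if (!length(donors)) return(0L)
  d <- graph_distances(mol, idx)
  cnt <- 0L
  seen <- character()
  for (don in donors) {
    for (acc in idx) {
      if (acc == don) next
      key <- paste(min(don, acc), max(don, acc))
      if (key %in% seen) next
      dist <- d[as.character(don), as.character(acc)]
      if (is.finite(dist) && dist >= 3 && dist <= 5) {
        cnt <- cnt + 1L
        seen <- c(seen, key)
      }
    }
  }
  cnt
}

# BFS all-pairs graph distances restricted to `targets` rows/cols.
graph_distances <- function(mol, targets) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
  }
  out <- matrix(Inf, length(targets), length(targets),
                dimnames = list(targets, targets))
  for (s in seq_along(targets)) {
    dist <- rep(Inf, n)
    dist[targets[s]] <- 0
    q <- targets[s]
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (dist[w] > dist[v] + 1) {
        dist[w] <- dist[v] + 1
        q <- c(q, w)
      }
    }
    out[s, ] <- dist[targets]
  }
  out
}

# ---- perception -------------------------------------------------------

signature_key <- function(atom_type, neighbors) {
  ifelse(neighbors == "", atom_type, paste(atom_type, neighbors, sep = "|"))
}

SPECIAL_KEYS <- c("alkane_C", "unsatHC_C", "h_acceptor")

#' Break a molecule down into its atom groups
#'
#' Emits one signature per group center, aggregated into counts, plus the
#' special-group counts (per-carbon hydrocarbon terms and, optionally, the
#' intramolecular hydrogen-bond term).
#'
#' @param mol a [molgraph] that passed [validate_elements()].
#' @param h_acceptor also run the hydrogen-bond detector (off by default).
#' @param strict error when an atom-type label falls outside the closed
#'   vocabulary of the published tables (default: emit it anyway and let
#'   eligibility gating handle it).
#' @return an object of class `group_counts`: list with `id`, `counts`
#'   (named integer vector keyed `"atom type|neighbors"`), `special`
#'   (named integer vector) and `n_centers`.
#' @export
perceive <- function(mol, h_acceptor = FALSE, strict = FALSE) {
  ver <- validate_elements(mol)
  if (!ver$eligible)
    stop("element not supported: ", paste(ver$offending, collapse = ", "))
  centers <- group_centers(mol)
  keys <- character(length(centers))
  for (s in seq_along(centers)) {
    a <- centers[s]
    ty <- atom_type(mol, a)
    if (strict && !ty %in% KNOWN_ATOM_TYPES)
      stop("atom ", a, " (", mol$atoms$element[a],
           "): atom type \"", ty, "\" is outside the table vocabulary")
    keys[s] <- signature_key(ty, canonical_neighbor_string(mol, a))
  }
  tab <- table(keys)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  special <- c(detect_hydrocarbon_special(mol), h_acceptor = 0L)
  if (h_acceptor) special["h_acceptor"] <- detect_h_acceptor(mol)
  structure(list(id = mol$id, counts = counts, special = special,
                 n_centers = length(centers)),
            class = "group_counts")
}

#' @export
print.group_counts <- function(x, ...) {
  cat(sprintf("<group_counts> %s: %d centers, %d distinct groups\n",
              x$id, x$n_centers, length(x$counts)))
  for (k in names(x$counts)) cat(sprintf("  %-28s %d\n", k, x$counts[[k]]))
  sp <- x$special[x$special > 0]
  for (k in names(sp)) cat(sprintf("  [special] %-18s %d\n", k, sp[[k]]))
  invisible(x)
}

#' Group counts as a data frame
#'
#' @param x a `group_counts` object.
#' @param ... unused.
#' @return data frame with columns `id`, `atom_type`, `neighbors`, `count`;
#'   special groups appear with the special key in `atom_type` and empty
#'   `neighbors`.
#' @export
as.data.frame.group_counts <- function(x, ...) {
  parts <- strsplit(names(x$counts), "|", fixed = TRUE)
  df <- data.frame(
    id = rep(x$id, length(x$counts)),
    atom_type = vapply(parts, `[`, "", 1),
    neighbors = vapply(parts, function(p) if (length(p) > 1) p[2] else "", ""),
    count = unname(x$counts))
  sp <- x$special[x$special > 0]
  if (length(sp))
    df <- rbind(df, data.frame(id = x$id, atom_type = names(sp),
                               neighbors = "", count = unname(sp)))
  df
}

#' Write group counts to CSV
#'
#' One row per (compound, signature): columns `id`, `atom_type`,
#' `neighbors`, `count`.  Special groups are written with the special key
#' in `atom_type` and empty `neighbors`.
#'
#' @param counts_list list of `group_counts` objects.
#' @param path output CSV path.
#' @export
write_group_counts <- function(counts_list, path) {
  df <- do.call(rbind, lapply(counts_list, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read group counts from CSV
#'
#' Inverse of [write_group_counts()].
#'
#' @param path CSV with columns `id`, `atom_type`, `neighbors`, `count`.
#' @return list of `group_counts` objects, one per compound id, in file
#'   order.
#' @export
read_group_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(neighbors = "character"))
  need <- c("id", "atom_type", "neighbors", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("counts schema error: missing column(s) ",
                         paste(miss, collapse = ", "))
  df$neighbors[is.na(df$neighbors)] <- ""
  lapply(split(df, factor(df$id, levels = unique(df$id))), function(d) {
    sp <- c(alkane_C = 0L, unsatHC_C = 0L, h_acceptor = 0L)
    is_sp <- d$atom_type %in% SPECIAL_KEYS
    sp[d$atom_type[is_sp]] <- d$count[is_sp]
    counts <- stats::setNames(as.integer(d$count[!is_sp]),
                              signature_key(d$atom_type[!is_sp], d$neighbors[!is_sp]))
    structure(list(id = d$id[1], counts = counts, special = sp,
                   n_centers = sum(counts)),
              class = "group_counts")
  })
}
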