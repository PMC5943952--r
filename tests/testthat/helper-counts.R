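# Helpers shared across the test files.

# hand-build a group_counts object without going through perception
gc_make <- function(id, counts,
                    special = c(alkane_C = 0L, unsatHC_C = 0L, h_acceptor = 0L)) {
  structure(list(id = id,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 special = special, n_centers = sum(counts)),
            class = "group_counts")
}

# a reproducible synthetic training set
synth_training <- function(n, p, sigma = 0.1, seed = 1, ...) {
  synthetic_training(make_design(synth_spec(
    n_compounds = n, n_groups = p, sigma = sigma, seed = seed, ...)))
}

# apply a random atom permutation to a molgraph
permute_mol <- function(mol, seed = 1) {
  set.seed(seed)
  n <- nrow(mol$atoms)
  pos <- sample.int(n)          # pos[i] = new index of old atom i
  atoms <- mol$atoms
  atoms[pos, ] <- mol$atoms
  bonds <- mol$bonds
  bonds$i <- pos[bonds$i]
  bonds$j <- pos[bonds$j]
  out <- mol
  out$atoms <- atoms
  out$bonds <- bonds
  out
}

# sorted named count vector, for order-insensitive comparison
sorted_counts <- function(x) x[order(names(x))]
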