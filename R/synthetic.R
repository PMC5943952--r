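# Synthetic data: count-matrix simulations emulating the statistical
# structure the additivity model assumes (sparse non-negative integer
# designs, linear signal, homoscedastic noise), and a fixture set of
# molecules with hand-derived reference decompositions.

#' Specification of a synthetic group-count dataset
#'
#' @param n_compounds,n_groups problem size.
#' @param occupancy probability that a compound contains a given group.
#' @param max_count maximum per-compound count of one group (counts are
#'   uniform on 1..max_count when present).
#' @param contrib_range range of the uniform true contributions.
#' @param constant true additive constant C.
#' @param sigma standard deviation of the Gaussian noise on y.
#' @param seed RNG seed; everything is reproducible from it.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_compounds = 500, n_groups = 40, occupancy = 0.3,
                       max_count = 4, contrib_range = c(-1, 1),
                       constant = 0, sigma = 0.1, seed = 1) {
  stopifnot(n_compounds >= 1, n_groups >= 1, max_count >= 1,
            occupancy > 0, occupancy <= 1, sigma >= 0)
  structure(list(n_compounds = n_compounds, n_groups = n_groups,
                 occupancy = occupancy, max_count = max_count,
                 contrib_range = contrib_range, constant = constant,
                 sigma = sigma, seed = seed),
            class = "synth_spec")
}

#' Generate a synthetic design from a specification
#'
#' Draws a sparse integer count matrix, uniform true contributions and a
#' response `y = X a + C + N(0, sigma)`.  Columns that come out all-zero
#' are resampled so every group occurs at least once.
#'
#' @param spec a [synth_spec()].
#' @return list with integer matrix `X` (columns named `G001`, ...),
#'   `a_true`, `y` and `spec`.
#' @export
make_design <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    n <- spec$n_compounds; p <- spec$n_groups
    draw_col <- function() {
      on <- stats::runif(n) < spec$occupancy
      ifelse(on, sample.int(spec$max_count, n, replace = TRUE), 0L)
    }
    X <- matrix(0L, n, p, dimnames = list(NULL, sprintf("G%03d", seq_len(p))))
    for (jcol in seq_len(p)) {
      v <- draw_col()
      while (all(v == 0)) v <- draw_col()
      X[, jcol] <- v
    }
    a_true <- stats::runif(p, spec$contrib_range[1], spec$contrib_range[2])
    y <- as.numeric(X %*% a_true) + spec$constant +
      stats::rnorm(n, 0, spec$sigma)
    list(X = X, a_true = a_true, y = y, spec = spec)
  })
}

#' Wrap a synthetic design as a training set
#'
#' Converts the rows of a [make_design()] result into `group_counts`
#' objects (group keys = column names) so the fitting and cross-validation
#' machinery can run on simulated data.
#'
#' @param design a [make_design()] result.
#' @return a `training_set`.
#' @export
synthetic_training <- function(design) {
  counts_list <- lapply(seq_len(nrow(design$X)), function(r) {
    v <- design$X[r, ]
    v <- v[v > 0]
    structure(list(id = sprintf("S%04d", r),
                   counts = stats::setNames(as.integer(v), names(v)),
                   special = c(alkane_C = 0L, unsatHC_C = 0L, h_acceptor = 0L),
                   n_centers = sum(v)),
              class = "group_counts")
  })
  training_set(counts_list, design$y)
}

#' Fixture molecules with hand-derived decompositions
#'
#' A packaged reference set: the nine worked ionic-liquid group examples
#' (tetrafluoroborate, pyridinium, 2-methylimidazolium,
#' 1-methylimidazolium, 1-methylpyridinium,
#' bis(trifluoromethanesulfonyl)amide, tetramethylphosphonium,
#' hexafluorophosphate, methylsulfonate) plus simple organics (methanol,
#' ethanol, hexane, benzene, toluene, acetic acid, phenol,
#' salicylaldehyde, ethylene glycol), each with its frozen hand-derived
#' group decomposition.  These fixtures pin down the behaviour of the
#' perception grammar.
#'
#' @param parse also parse each SMILES into a [molgraph] (requires
#'   ChemmineOB); when `FALSE` only ids, SMILES and expected counts are
#'   returned.
#' @return named list (by fixture id) of lists with `id`, `smiles`, `mol`
#'   (or `NULL`), `expected` (named expected count vector keyed
#'   `"atom type|neighbors"`) and `special` (expected special counts).
#' @export
fixture_molecules <- function(parse = TRUE) {
  dir <- system.file("extdata", package = "groupadd")
  mols <- utils::read.csv(file.path(dir, "fixtures.csv"),
                          stringsAsFactors = FALSE)
  cnts <- utils::read.csv(file.path(dir, "fixture_counts.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(neighbors = "character"))
  cnts$neighbors[is.na(cnts$neighbors)] <- ""
  out <- lapply(seq_len(nrow(mols)), function(r) {
    id <- mols$id[r]
    cc <- cnts[cnts$id == id, ]
    expected <- stats::setNames(as.integer(cc$count),
                                signature_key(cc$atom_type, cc$neighbors))
    list(id = id, smiles = mols$smiles[r],
         mol = if (parse) read_smiles(mols$smiles[r], name = id, id = id) else NULL,
         expected = expected,
         special = c(alkane_C = mols$alkane_C[r],
                     unsatHC_C = mols$unsatHC_C[r],
                     h_acceptor = mols$h_acceptor[r]))
  })
  stats::setNames(out, mols$id)
}
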