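# Parameter tables: the published group contributions for the two
# descriptors, their CSV serialisation, and validity recomputation.

DESCRIPTORS <- c("log_eta_293K", "log_gamma_inf_298K")

# md5 checksums of the packaged transcriptions; load_packaged() refuses to
# proceed when a data file was altered.
PACKAGED_MD5 <- c(
  "log_eta_293K_groups.csv"        = "32785f7225d3400a9a9a44c362c56b90",
  "log_eta_293K_stats.csv"         = "d9c9819588cf7e04c70102c75f4f937a",
  "log_gamma_inf_298K_groups.csv"  = "afe1cef5780ff564b86fa5a235389757",
  "log_gamma_inf_298K_stats.csv"   = "e12942895aecec2c8e979b991a699fd2")

# map the printed special-group rows onto internal special keys
special_key_for <- function(atom_type, neighbors) {
  ifelse(atom_type == "Const", "CONST",
  ifelse(atom_type == "H" & neighbors == "H Acceptor", "h_acceptor",
  ifelse(atom_type == "Alkane", "alkane_C",
  ifelse(atom_type == "Unsaturated HC", "unsatHC_C", NA_character_))))
}

new_parameter_table <- function(descriptor, entries, constant, uses_constant,
                                uses_special, stats = NULL) {
  entries$special_key <- special_key_for(entries$atom_type, entries$neighbors)
  entries$key <- ifelse(is.na(entries$special_key),
                        signature_key(entries$atom_type, entries$neighbors),
                        entries$special_key)
  dup <- entries$key[duplicated(entries$key)]
  if (length(dup)) {
    rows <- entries$entry[entries$key %in% dup]
    stop("duplicate signature(s) ", paste(unique(dup), collapse = ", "),
         " at entries ", paste(rows, collapse = ", "))
  }
  if (is.unsorted(entries$entry, strictly = TRUE))
    stop("entry numbers must be unique and ascending")
  if (is.null(entries$valid))
    entries$valid <- entries$molecules >= 3L | entries$special_key %in% "CONST"
  structure(list(descriptor = descriptor, entries = entries,
                 constant = constant, uses_constant = uses_constant,
                 uses_special = uses_special, stats = stats),
            class = "parameter_table")
}

#' @export
print.parameter_table <- function(x, ...) {
  cat(sprintf("<parameter_table> %s: %d entries (%d valid), C = %g%s\n",
              x$descriptor, nrow(x$entries), sum(x$entries$valid),
              x$constant,
              if (x$uses_special) ", with special groups" else ""))
  invisible(x)
}

#' Load a packaged parameter table
#'
#' Returns the published group-contribution table for one of the two
#' descriptors: `"log_eta_293K"`, the decimal log of the liquid viscosity
#' coefficient in cP at 293.15 K (126 entries including the constant
#' C = -0.70), or `"log_gamma_inf_298K"`, the decimal log of the activity
#' coefficient at infinite dilution in water at 298.15 K (116 entries of
#' which three are special groups; C = 0).  Contributions are stored
#' exactly as printed (two decimals); the summary statistics rows (A-H)
#' are exposed as the `stats` metadata, not as entries.  Validity flags
#' are derived from the printed molecule counts with the >= 3 rule.
#'
#' @param descriptor one of `"log_eta_293K"`, `"log_gamma_inf_298K"`.
#' @return a `parameter_table`.
#' @export
load_packaged <- function(descriptor = DESCRIPTORS) {
  descriptor <- match.arg(descriptor)
  dir <- system.file("extdata", package = "groupadd")
  files <- paste0(descriptor, c("_groups.csv", "_stats.csv"))
  for (f in files) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("packaged data file missing: ", f)
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, unname(PACKAGED_MD5[f])))
      stop("packaged data file corrupted (checksum mismatch): ", f)
  }
  g <- utils::read.csv(file.path(dir, files[1]), stringsAsFactors = FALSE,
                       colClasses = c(neighbors = "character"))
  g$neighbors[is.na(g$neighbors)] <- ""
  s <- utils::read.csv(file.path(dir, files[2]), stringsAsFactors = FALSE)
  if (descriptor == "log_eta_293K") {
    constant <- g$contribution[g$atom_type == "Const"]
    new_parameter_table(descriptor, g, constant = constant,
                        uses_constant = TRUE, uses_special = FALSE, stats = s)
  } else {
    new_parameter_table(descriptor, g, constant = 0,
                        uses_constant = FALSE, uses_special = TRUE, stats = s)
  }
}

#' Write a parameter table to CSV
#'
#' Lossless round-trip dialect: columns `entry`, `atom_type`, `neighbors`,
#' `contribution`, `occurrences`, `molecules`, `valid`.
#'
#' @param table a `parameter_table`.
#' @param path output CSV path.
#' @export
write_table <- function(table, path) {
  cols <- c("entry", "atom_type", "neighbors", "contribution",
            "occurrences", "molecules", "valid")
  utils::write.csv(table$entries[cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a parameter table from CSV
#'
#' Inverse of [write_table()].  Descriptor metadata (constant, whether the
#' constant and the special groups are used) is supplied by the caller
#' since the CSV stores entries only.
#'
#' @param path CSV path in the [write_table()] dialect.
#' @param descriptor descriptor id.
#' @param constant additive constant C.
#' @param uses_constant,uses_special model structure flags.
#' @return a `parameter_table`.
#' @export
read_table <- function(path, descriptor = "custom", constant = 0,
                       uses_constant = any(g$atom_type == "Const"),
                       uses_special = any(!is.na(special_key_for(g$atom_type, g$neighbors)) &
                                          special_key_for(g$atom_type, g$neighbors) != "CONST")) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(neighbors = "character"))
  need <- c("entry", "atom_type", "neighbors", "contribution",
            "occurrences", "molecules")
  miss <- setdiff(need, names(g))
  if (length(miss)) stop("table schema error: missing column(s) ",
                         paste(miss, collapse = ", "))
  g$neighbors[is.na(g$neighbors)] <- ""
  if (missing(constant) && any(g$atom_type == "Const"))
    constant <- g$contribution[g$atom_type == "Const"][1]
  new_parameter_table(descriptor, g, constant = constant,
                      uses_constant = uses_constant, uses_special = uses_special)
}

#' Recompute group validity from a dataset
#'
#' A group is valid for prediction when it is represented by at least
#' three distinct molecules of the dataset.  The flags of `table` are
#' replaced by flags derived from `counts_list`; groups absent from the
#' dataset become invalid.  The molecule counts are updated accordingly.
#'
#' @param table a `parameter_table`.
#' @param counts_list list of `group_counts` objects (one per molecule).
#' @return the updated `parameter_table`.
#' @export
recompute_validity <- function(table, counts_list) {
  nmol <- molecule_support(counts_list)
  keys <- table$entries$key
  n <- ifelse(keys %in% names(nmol), nmol[keys], 0L)
  table$entries$molecules <- as.integer(n)
  table$entries$valid <- n >= 3L | table$entries$special_key %in% "CONST"
  table
}

# number of distinct molecules supporting each signature / special key
molecule_support <- function(counts_list) {
  keys <- unlist(lapply(counts_list, function(gc)
    unique(c(names(gc$counts), names(gc$special)[gc$special > 0]))))
  tab <- table(keys)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

# total occurrences of each signature / special key
occurrence_counts <- function(counts_list) {
  all <- unlist(lapply(counts_list, function(gc)
    c(gc$counts, gc$special[gc$special > 0])))
  tapply(all, names(all), sum)
}
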