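#!/usr/bin/env Rscript
# Optional integration script: recomputes the full training and
# cross-validation statistics (N, R2, average/standard deviation, Q2,
# sigma_cv, outliers) for a real compound collection.  The original
# experimental compound lists are not shipped with the package; supply
# them as an SDF file plus a CSV of experimental values to reproduce the
# published statistics lines.
#
# Usage:
#   Rscript scripts/reproduce_paper_stats.R --sdf compounds.sdf \
#       --values values.csv --descriptor visc|gamma [--id-field FIELD] \
#       [--k 10] [--seed 20171221] [--out report.json]
#
# values.csv needs columns id, value (log units of the chosen descriptor).

suppressMessages(library(groupadd))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(k = 10L, seed = 20171221L, descriptor = "visc",
            id_field = NULL, out = "paper_stats.json")
i <- 1
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  key <- gsub("-", "_", key)
  opt[[key]] <- args[i + 1]
  i <- i + 2
}
opt$k <- as.integer(opt$k); opt$seed <- as.integer(opt$seed)
if (is.null(opt$sdf) || is.null(opt$values))
  stop("--sdf and --values are required")

uses_constant <- opt$descriptor == "visc"
uses_special <- opt$descriptor == "gamma"

mols <- read_sdf(opt$sdf, id_field = opt$id_field)
vals <- read.csv(opt$values, stringsAsFactors = FALSE)
eligible <- Filter(function(m) length(m$offending_elements) == 0, mols)
counts <- lapply(eligible, perceive)
ids <- vapply(counts, `[[`, "", "id")
m <- match(ids, vals$id)
keep <- !is.na(m)
training <- training_set(counts[keep], vals$value[m[keep]])

fit <- fit_with_outlier_removal(training, uses_constant = uses_constant,
                                uses_special = uses_special,
                                k = opt$k, seed = opt$seed)
cv <- cross_validate(subset_final <- training_set(
        training$counts[!training$ids %in% fit$outliers$id],
        training$values[!training$ids %in% fit$outliers$id]),
      k = opt$k, seed = opt$seed,
      uses_constant = uses_constant, uses_special = uses_special)

report <- list(
  descriptor = opt$descriptor,
  n_input = length(mols), n_trained = fit$n_used,
  valid_groups = sum(fit$table$entries$valid &
                       fit$table$entries$atom_type != "Const"),
  r2 = fit$r2, avg_dev = fit$avg_dev, sd_dev = fit$sd_dev,
  k = cv$k, n_predictable_cv = cv$n_predictable,
  q2 = cv$q2, avg_dev_cv = cv$avg_dev, sd_dev_cv = cv$sd_dev,
  outliers = fit$outliers)
jsonlite::write_json(report, opt$out, auto_unbox = TRUE, digits = NA)
cat(sprintf("N = %d, R2 = %.4f, sd = %.2f | CV: N = %d, Q2 = %.4f, sd = %.2f\n",
            fit$n_used, fit$r2, fit$sd_dev,
            cv$n_predictable, cv$q2, cv$sd_dev))
cat("report written to", opt$out, "\n")
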