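#!/usr/bin/env Rscript
# Optional reproduction of the published benchmark numbers. These require
# the curated moonlighting / non-moonlighting FASTA files (not bundled;
# obtain them from the study's data deposit) — pass their paths below.
#
#   Rscript scripts/reproduce_study.R --mp mp.fasta --nonmp nonmp.fasta \
#       [--repeats 100] [--seed 1] [--out reproduction/]
#
# Produces: the shared-fold CV + holdout report for SAAC and QSOrder with
# the SVM, KNN and NB classifiers; per-cell COP detection at the inclusive
# threshold of 90; COP summary statistics (class fractions, always-wrong
# fraction F.M., frequency); and the combined COP set.

suppressPackageStartupMessages({
  library(optparse)
  library(mooncop)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--mp", type = "character"),
  make_option("--nonmp", type = "character"),
  make_option("--repeats", type = "integer", default = 100L),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "reproduction")
)))
if (is.null(opts$mp) || is.null(opts$nonmp)) {
  stop("supply --mp and --nonmp FASTA paths (see header comment)")
}

dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
dataset <- read_fasta_pair(opts$mp, opts$nonmp)
message("dataset: ", nrow(dataset), " proteins (",
        sum(dataset$label == "MP"), " MP / ",
        sum(dataset$label == "NONMP"), " non-MP)")

bench <- benchmark_grid(dataset,
                        descriptors = c("SAAC", "QSOrder"),
                        families = c("SVM", "KNN", "NB"),
                        test_fraction = 0.2,
                        repeats = opts$repeats, K = 10L,
                        seed = opts$seed, keep_logs = TRUE)
write_feature_table(bench$report, file.path(opts$out, "report.tsv"))
print(bench)

labels <- dataset[, c("id", "label")]
sets <- list()
stats <- purrr::map_dfr(names(bench$logs), function(cell) {
  parts <- strsplit(cell, ".", fixed = TRUE)[[1]]
  t <- tally_misclassifications(bench$logs[[cell]])
  cops <- detect_cops(t, threshold = round(0.9 * opts$repeats))
  sets[[cell]] <<- cops
  cop_stats(cops, labels, t, parts[1], parts[2])
})
readr::write_tsv(stats, file.path(opts$out, "cop_stats.tsv"))
print(stats)

combined <- combine_cops(sets, "intersection")
writeLines(combined, file.path(opts$out, "cops_combined.txt"))
message(length(combined), " proteins in the combined COP set; outputs in ",
        normalizePath(opts$out))
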