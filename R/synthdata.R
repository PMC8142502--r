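#' Configure the synthetic sequence generator
#'
#' The generator emulates two compositional sequence classes: MP
#' sequences are drawn i.i.d. from a residue distribution in which a
#' designated set of "MP-typed" residues is enriched by a factor
#' `1 + delta` (and the rest depleted by `1 - delta`), NONMP sequences
#' from the complementary enrichment. The first and last 5 residues are
#' drawn with a stronger enrichment (`min(1, 1.5 * delta)`) so that
#' terminal-segment descriptors carry class signal beyond global
#' composition. A fraction of records per class is generated from the
#' *opposite* class's distribution but keeps the nominal label — these
#' label-flipped proteins are the ground-truth outliers the COP machinery
#' should recover.
#'
#' @param n_per_class Sequences per class.
#' @param length_range Min/max sequence length; the minimum must be at
#'   least 31 so every bundled descriptor (up to SOCNumber's 30 lags) is
#'   defined.
#' @param delta Compositional effect size in `[0, 1]`; 0 makes the
#'   classes identical, 1 makes them disjoint in residue usage.
#' @param outlier_fraction Fraction of label-flipped records per class,
#'   in `[0, 0.5)`.
#' @param baseline Baseline residue probabilities (named, length 20,
#'   summing to 1); default uniform.
#' @param mp_residues Residues enriched in the MP class (default the 10
#'   residues `ACDEFGHIKL`, chosen so enrichment keeps the distribution
#'   normalized under a uniform baseline).
#' @param seed Integer seed.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_per_class = 100L, length_range = c(60L, 200L),
                         delta = 0.2, outlier_fraction = 0,
                         baseline = NULL, mp_residues = NULL, seed = 1L) {
  if (is.null(baseline)) {
    baseline <- setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  baseline <- baseline[AA_ALPHABET]
  if (anyNA(baseline) || abs(sum(baseline) - 1) > 1e-8 || any(baseline < 0)) {
    stop("baseline must be 20 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  if (is.null(mp_residues)) mp_residues <- AA_ALPHABET[1:10]
  stopifnot(all(mp_residues %in% AA_ALPHABET))
  if (length_range[1] < 31L) {
    stop("minimum length must be >= 31 (sequence-order descriptors need ",
         "length > 30)", call. = FALSE)
  }
  if (delta < 0 || delta > 1) stop("delta must be in [0, 1]", call. = FALSE)
  if (outlier_fraction < 0 || outlier_fraction >= 0.5) {
    stop("outlier_fraction must be in [0, 0.5)", call. = FALSE)
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 length_range = as.integer(length_range),
                 delta = delta, outlier_fraction = outlier_fraction,
                 baseline = baseline, mp_residues = mp_residues,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# class-specific residue distribution: enrich `res` by (1 + delta),
# deplete the rest by (1 - delta), renormalize
enriched_probs <- function(baseline, res, delta) {
  p <- baseline
  up <- names(p) %in% res
  p[up] <- p[up] * (1 + delta)
  p[!up] <- p[!up] * (1 - delta)
  p / sum(p)
}

#' Generate a labeled synthetic dataset with known outliers
#'
#' Draws sequences per [synth_config()]; fully reproducible under the
#' config seed. The returned attribute `outlier_ids` records the
#' ground-truth label-flipped proteins.
#'
#' @param config A [synth_config()].
#' @return A protein dataset tibble with attribute `outlier_ids`
#'   (character vector) and `config`.
#' @examples
#' d <- generate_synthetic(synth_config(n_per_class = 10, delta = 1))
#' class_counts(d)
#' @export
generate_synthetic <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  delta_term <- min(1, 1.5 * config$delta)
  dists <- list(
    MP = list(core = enriched_probs(config$baseline, config$mp_residues,
                                    config$delta),
              term = enriched_probs(config$baseline, config$mp_residues,
                                    delta_term)),
    NONMP = list(core = enriched_probs(config$baseline,
                                       setdiff(AA_ALPHABET, config$mp_residues),
                                       config$delta),
                 term = enriched_probs(config$baseline,
                                       setdiff(AA_ALPHABET, config$mp_residues),
                                       delta_term)))
  n_out <- floor(config$outlier_fraction * config$n_per_class)
  withr::with_seed(derive_seed(config$seed, 3L), {
    recs <- purrr::map_dfr(c("MP", "NONMP"), function(lab) {
      purrr::map_dfr(seq_len(config$n_per_class), function(i) {
        flipped <- i <= n_out
        src <- dists[[if (flipped) setdiff(c("MP", "NONMP"), lab) else lab]]
        L <- sample(seq.int(config$length_range[1], config$length_range[2]), 1)
        term <- min(5L, L %/% 3L)
        core <- sample(AA_ALPHABET, L - 2L * term, replace = TRUE,
                       prob = src$core)
        nterm <- sample(AA_ALPHABET, term, replace = TRUE, prob = src$term)
        cterm <- sample(AA_ALPHABET, term, replace = TRUE, prob = src$term)
        tibble(id = sprintf("%s_%03d", tolower(lab), i),
               sequence = paste(c(nterm, core, cterm), collapse = ""),
               label = lab,
               description = if (flipped) "flipped" else "",
               flipped = flipped)
      })
    })
  })
  out <- as_protein_dataset(recs[, c("id", "sequence", "label",
                                     "description")], sanitize = NULL)
  attr(out, "outlier_ids") <- recs$id[recs$flipped]
  attr(out, "config") <- config
  out
}

#' Hand-checkable fixture sequences
#'
#' Tiny sequences whose descriptor values can be verified by hand (or by
#' the brute-force oracles in the test suite): homopolymers, the
#' 20-residue pangram, alternating and segment-homogeneous sequences.
#'
#' @return Protein dataset tibble.
#' @export
worked_fixtures <- function() {
  as_protein_dataset(tibble(
    id = c("homoA", "homoK10", "pangram", "acac", "aaaa", "segments",
           "mid1"),
    sequence = c(strrep("A", 40), strrep("K", 10),
                 paste(AA_ALPHABET, collapse = ""), "ACAC", "AAAA",
                 "AAAAACCCCCDDDDD", "AAAAACAAAAA"),
    label = "UNKNOWN"), sanitize = NULL)
}
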