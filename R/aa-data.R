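#' Bundled residue-level reference tables
#'
#' The descriptor formulas depend on a small set of residue-level reference
#' tables that ship with the package as plain-text files under
#' `inst/extdata/`:
#'
#' * `aa_grouped_alphabet()` — the default 8-class physicochemical grouping
#'   (aliphatic, hydroxyl, sulfur-containing, aromatic, basic, acidic,
#'   amide, proline) used by all grouped descriptor variants.
#' * `ctd_partitions()` — three-class partitions of the 20 residues for the
#'   seven physicochemical properties of the composition/transition/
#'   distribution (CTD) descriptor.
#' * `aa_distance_matrix()` — the two 20 x 20 residue distance matrices used
#'   by the sequence-order descriptors: Grantham's chemical distance
#'   (recomputed from his composition/polarity/volume formula) and a
#'   synthetic physicochemical stand-in for the Schneider-Wrede distance
#'   built from standardized hydropathy, hydrophilicity and side-chain-mass
#'   scales (the original matrix values are not redistributable here; only
#'   the zero-diagonal metric semantics are guaranteed).
#' * `codon_counts()` — standard-genetic-code synonymous codon counts per
#'   residue (total 61), the theoretical means of the DDE descriptor.
#' * `reduced_alphabet()` — clustered (reduced) alphabets for the k-tuple
#'   composition engine, keyed by declared group count.
#'
#' @param name For `aa_distance_matrix()`, one of `"grantham"`,
#'   `"schneider_wrede"` (the synthetic stand-in). For `reduced_alphabet()`,
#'   a table name such as `"g4"`; see `list_reduced_alphabets()`.
#' @return A tibble (`aa_grouped_alphabet`, `ctd_partitions`), a named
#'   numeric vector (`codon_counts`), a 20 x 20 numeric matrix
#'   (`aa_distance_matrix`), or a list with elements `mapping` (named
#'   integer vector over the 20 residues) and `g` (declared group count)
#'   for `reduced_alphabet`.
#' @examples
#' aa_grouped_alphabet()
#' aa_distance_matrix("grantham")["A", "R"]
#' @name reference-tables
NULL

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "mooncop")
  if (!nzchar(p)) p <- file.path("inst", "extdata", file)  # pre-install use
  if (!file.exists(p)) stop("bundled table not found: ", file, call. = FALSE)
  p
}

read_extdata <- function(file) {
  key <- paste0("extdata_", file)
  if (is.null(the[[key]])) {
    the[[key]] <- utils::read.table(extdata_path(file), header = TRUE,
                                    sep = "\t", check.names = FALSE,
                                    stringsAsFactors = FALSE)
  }
  the[[key]]
}

#' @rdname reference-tables
#' @export
aa_grouped_alphabet <- function() {
  tb <- as_tibble(read_extdata("grouped_alphabet_g8.tsv"))
  stopifnot(setequal(tb$residue, AA_ALPHABET))
  tb
}

# residue -> group index named integer vector for the default g=8 alphabet
grouped_mapping <- function() {
  tb <- aa_grouped_alphabet()
  setNames(as.integer(tb$group), tb$residue)[AA_ALPHABET]
}

#' @rdname reference-tables
#' @export
ctd_partitions <- function() {
  tb <- as_tibble(read_extdata("ctd_partitions.tsv"))
  stopifnot(length(unique(tb$property)) == 7L,
            all(table(tb$property) == 20L))
  tb
}

#' @rdname reference-tables
#' @export
aa_distance_matrix <- function(name = c("schneider_wrede", "grantham")) {
  name <- match.arg(name)
  file <- switch(name,
                 grantham = "dist_grantham.tsv",
                 schneider_wrede = "dist_schneider_wrede_synthetic.tsv")
  tb <- read_extdata(file)
  m <- as.matrix(tb[, -1])
  rownames(m) <- tb[[1]]
  m <- m[AA_ALPHABET, AA_ALPHABET]
  stopifnot(all(diag(m) == 0), all(is.finite(m)), all(m >= 0))
  m
}

#' @rdname reference-tables
#' @export
codon_counts <- function() {
  tb <- read_extdata("codon_counts.tsv")
  cc <- setNames(as.integer(tb$codons), tb$residue)[AA_ALPHABET]
  stopifnot(sum(cc) == 61L)
  cc
}

#' @rdname reference-tables
#' @export
list_reduced_alphabets <- function() unique(read_extdata("reduced_alphabets.tsv")$table)

#' @rdname reference-tables
#' @export
reduced_alphabet <- function(name) {
  tb <- read_extdata("reduced_alphabets.tsv")
  tb <- tb[tb$table == name, , drop = FALSE]
  if (nrow(tb) == 0L) {
    stop("unknown reduced alphabet '", name, "'; available: ",
         paste(list_reduced_alphabets(), collapse = ", "), call. = FALSE)
  }
  mapping <- setNames(as.integer(tb$group), tb$residue)[AA_ALPHABET]
  stopifnot(!anyNA(mapping))
  list(name = name, mapping = mapping, g = unique(tb$declared_groups))
}
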