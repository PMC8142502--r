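#' Sanitize a raw amino-acid sequence
#'
#' Normalizes a raw sequence string to the 20-letter amino-acid alphabet
#' `ACDEFGHIKLMNPQRSTVWY`. Case is folded to upper case and whitespace
#' removed first; remaining non-canonical characters are then handled
#' according to `policy`:
#'
#' * `"map_x"` (default): ambiguity codes are mapped to a canonical
#'   representative — B to N, Z to Q, U to C, O to K, J to L, and X (or any
#'   other letter) to `x_to`. Keeps every protein usable by every
#'   descriptor.
#' * `"drop"`: non-canonical characters are removed.
#' * `"strict"`: any non-canonical character is an error naming the
#'   offending residue and its position — useful for auditing inputs.
#'
#' @param raw Character vector of raw sequences.
#' @param policy One of `"map_x"`, `"drop"`, `"strict"`.
#' @param x_to Canonical residue that `X` and unknown letters map to under
#'   `"map_x"` (default `"A"`).
#' @return Character vector of sanitized sequences.
#' @examples
#' sanitize_sequence("ac de\n")          # "ACDE"
#' sanitize_sequence("ACXDE", "drop")    # "ACDE"
#' sanitize_sequence("ACBDE")            # "ACNDE"
#' @export
sanitize_sequence <- function(raw, policy = c("map_x", "drop", "strict"),
                              x_to = "A") {
  policy <- match.arg(policy)
  stopifnot(is.character(raw), x_to %in% AA_ALPHABET)
  out <- toupper(gsub("[[:space:]*]", "", raw))
  vapply(out, function(s) {
    ch <- strsplit(s, "")[[1]]
    bad <- !(ch %in% AA_ALPHABET)
    if (any(bad)) {
      if (policy == "strict") {
        i <- which(bad)[1]
        stop("non-canonical residue '", ch[i], "' at position ", i,
             call. = FALSE)
      } else if (policy == "drop") {
        ch <- ch[!bad]
      } else {
        map <- c(B = "N", Z = "Q", U = "C", O = "K", J = "L")
        ch[bad] <- ifelse(ch[bad] %in% names(map), map[ch[bad]], x_to)
      }
    }
    if (length(ch) == 0L) {
      stop("sequence empty after sanitization", call. = FALSE)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Build a labeled protein dataset
#'
#' A protein dataset is an ordinary tibble with columns `id` (unique,
#' non-empty), `sequence` (canonical 20-letter amino acids), `label`
#' (`"MP"`, `"NONMP"` or `"UNKNOWN"`) and `description`. All pipeline
#' functions accept and return this shape; `as_protein_dataset()` validates
#' an existing data frame.
#'
#' @param data Data frame with at least `id` and `sequence` columns;
#'   `label` defaults to `"UNKNOWN"`, `description` to `""`.
#' @param sanitize Policy passed to [sanitize_sequence()]; `NULL` skips
#'   sanitization (sequences must already be canonical).
#' @return A validated protein dataset tibble.
#' @export
as_protein_dataset <- function(data, sanitize = "map_x") {
  stopifnot(is.data.frame(data), all(c("id", "sequence") %in% names(data)))
  out <- as_tibble(data)
  if (!"label" %in% names(out)) out$label <- "UNKNOWN"
  if (!"description" %in% names(out)) out$description <- ""
  out <- out[, c("id", "sequence", "label", "description")]
  out$id <- as.character(out$id)
  if (any(!nzchar(out$id))) stop("empty protein id", call. = FALSE)
  dup <- out$id[duplicated(out$id)]
  if (length(dup) > 0L) {
    stop("duplicate protein id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (!all(out$label %in% c("MP", "NONMP", "UNKNOWN"))) {
    stop("label must be one of MP, NONMP, UNKNOWN", call. = FALSE)
  }
  if (!is.null(sanitize)) {
    out$sequence <- sanitize_sequence(out$sequence, sanitize)
  } else if (any(grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"),
                       out$sequence))) {
    stop("non-canonical residues present; pass a sanitize policy",
         call. = FALSE)
  }
  out
}

#' Read protein sequences from FASTA
#'
#' `read_fasta()` reads one FASTA file and assigns every record the given
#' class label. `read_fasta_pair()` reads the two-file layout with one file
#' per class (moonlighting and non-moonlighting) and concatenates them.
#' The header token up to the first whitespace becomes the record id; the
#' remainder is kept as the description.
#'
#' @param path,mp_path,nonmp_path FASTA file path(s).
#' @param label Class label for all records in `path`: `"MP"`, `"NONMP"`
#'   or `"UNKNOWN"`.
#' @param sanitize Sanitization policy, see [sanitize_sequence()].
#' @return A protein dataset tibble (see [as_protein_dataset()]).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 some protein", "ACDE", ">p2", "WYWY"), fa)
#' read_fasta(fa, label = "MP")
#' @export
read_fasta <- function(path, label = "UNKNOWN", sanitize = "map_x") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)  # no alphabet restriction here;
  if (length(ss) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  headers <- names(ss)                    # sanitize_sequence owns that
  recs <- tibble(id = sub("\\s.*$", "", headers),
                 sequence = as.character(ss),
                 description = trimws(sub("^\\S*", "", headers)))
  if (any(!nzchar(recs$sequence))) {
    stop("empty sequence for record(s): ",
         paste(recs$id[!nzchar(recs$sequence)], collapse = ", "),
         call. = FALSE)
  }
  recs$label <- label
  as_protein_dataset(recs, sanitize = sanitize)
}

#' @rdname read_fasta
#' @export
read_fasta_pair <- function(mp_path, nonmp_path, sanitize = "map_x") {
  as_protein_dataset(bind_rows(read_fasta(mp_path, "MP", sanitize),
                               read_fasta(nonmp_path, "NONMP", sanitize)),
                     sanitize = NULL)
}

#' Write a protein dataset to FASTA
#'
#' @param data Protein dataset tibble.
#' @param path Output file path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, width = 60L) {
  data <- as_protein_dataset(data, sanitize = NULL)
  hdr <- ifelse(nzchar(data$description),
                paste(data$id, data$description), data$id)
  ss <- Biostrings::BStringSet(setNames(data$sequence, hdr))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Class counts of a labeled dataset
#'
#' @param data Protein dataset tibble.
#' @return Tibble with columns `label` and `n`.
#' @export
class_counts <- function(data) {
  count(as_protein_dataset(data, sanitize = NULL), .data$label, name = "n")
}

# training preconditions shared by the CV machinery
check_trainable <- function(data, min_per_class = 2L) {
  cc <- class_counts(data)
  for (lab in c("MP", "NONMP")) {
    n <- cc$n[cc$label == lab]
    if (length(n) == 0L || n < min_per_class) {
      stop("need at least ", min_per_class, " '", lab,
           "' proteins to train (found ",
           if (length(n) == 0L) 0L else n, ")", call. = FALSE)
    }
  }
  invisible(data)
}
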