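# Descriptor registry: maps the published descriptor names onto the
# per-sequence functions and their default parameters, and records the
# vector length implied by any parameter set so extraction can enforce the
# dimensionality contract up front.

registry_entries <- function() {
  list(
    AAC = list(fn = function(seq, p) aac(seq),
               len = function(p) 20L, defaults = list()),
    AAKpart = list(fn = function(seq, p) aak_part_composition(seq, p$k),
                   len = function(p) 20L * p$k, defaults = list(k = 3L)),
    SAAC = list(fn = function(seq, p) saac(seq, p$nt, p$ct),
                len = function(p) 60L, defaults = list(nt = 5L, ct = 5L)),
    SGAAC = list(fn = function(seq, p) sgaac(seq, p$nt, p$ct),
                 len = function(p) 24L, defaults = list(nt = 5L, ct = 5L)),
    kAAComposition = list(fn = function(seq, p) kmer_composition(seq, p$k),
                          len = function(p) 20L^p$k, defaults = list(k = 3L)),
    kGAAComposition = list(
      fn = function(seq, p) kmer_composition(seq, p$k, grouped = TRUE),
      len = function(p) 8L^p$k, defaults = list(k = 3L)),
    CkSAApair = list(fn = function(seq, p) cks_pair(seq, p$gap),
                     len = function(p) 400L, defaults = list(gap = 1L)),
    CkSGAApair = list(fn = function(seq, p) cks_pair(seq, p$gap, grouped = TRUE),
                      len = function(p) 64L, defaults = list(gap = 1L)),
    DDE = list(fn = function(seq, p) dde(seq),
               len = function(p) 400L, defaults = list()),
    GrpDDE = list(fn = function(seq, p) dde(seq, grouped = TRUE),
                  len = function(p) 64L, defaults = list()),
    CTDC = list(fn = function(seq, p) ctdc(seq),
                len = function(p) 21L, defaults = list()),
    CTDT = list(fn = function(seq, p) ctdt(seq),
                len = function(p) 21L, defaults = list()),
    CTDD = list(fn = function(seq, p) ctdd(seq),
                len = function(p) 105L, defaults = list()),
    CTD = list(fn = function(seq, p) ctd(seq),
               len = function(p) 147L, defaults = list()),
    SOCNumber = list(fn = function(seq, p) socnumber(seq, p$nlag),
                     len = function(p) 2L * p$nlag,
                     defaults = list(nlag = 30L)),
    QSOrder = list(fn = function(seq, p) qsorder(seq, p$nlag, p$w),
                   len = function(p) 2L * (20L + p$nlag),
                   defaults = list(nlag = 5L, w = 0.1)),
    PseKRAAC = list(
      fn = function(seq, p) reduced_ktuple(seq, p$table, p$k),
      len = function(p) {
        tb <- if (is.character(p$table)) reduced_alphabet(p$table) else p$table
        as.integer(tb$g)^p$k
      },
      defaults = list(table = "g4", k = 2L)),
    AAutoCor = list(
      fn = function(seq, p) autocorrelation(seq, nlag = p$nlag, kinds = p$kinds),
      len = function(p) length(p$kinds) * 8L * p$nlag,
      defaults = list(nlag = 19L,
                      kinds = c("moreau_broto", "moran", "geary")))
  )
}

#' Descriptor registry
#'
#' `list_descriptors()` names every registered descriptor.
#' `descriptor_spec()` resolves a name plus parameter overrides into a
#' spec object carrying the expected vector length; the spec is what
#' [extract_features()] executes.
#'
#' @param name Registered descriptor name (see `list_descriptors()`).
#' @param ... Parameter overrides (e.g. `nt = 5`, `k = 2`,
#'   `table = "g16"`).
#' @return `descriptor_spec()` returns an object of class
#'   `"descriptor_spec"` with fields `name`, `params` and
#'   `expected_length`.
#' @examples
#' list_descriptors()
#' descriptor_spec("SAAC")$expected_length  # 60
#' descriptor_spec("PseKRAAC", table = "g16")$expected_length  # 256
#' @export
list_descriptors <- function() names(registry_entries())

#' @rdname list_descriptors
#' @export
descriptor_spec <- function(name, ...) {
  reg <- registry_entries()
  if (!name %in% names(reg)) {
    stop("unknown descriptor '", name, "'; registered: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  entry <- reg[[name]]
  params <- modifyList(entry$defaults, list(...))
  extra <- setdiff(names(params), names(entry$defaults))
  if (length(extra) > 0L) {
    stop("unknown parameter(s) for ", name, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, params = params,
                 expected_length = entry$len(params)),
            class = "descriptor_spec")
}

#' @export
print.descriptor_spec <- function(x, ...) {
  cat("<descriptor_spec> ", x$name, " (length ", x$expected_length, ")\n",
      sep = "")
  if (length(x$params) > 0L) {
    cat("  params: ",
        paste(names(x$params),
              vapply(x$params, function(v) paste(format(v), collapse = ","),
                     character(1)),
              sep = " = ", collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' Extract a feature matrix from a protein dataset
#'
#' Computes one descriptor for every protein and returns a tibble with the
#' protein `id` as first column and one column per feature, named
#' `<descriptor>.<feature>`. A sequence that violates the descriptor's
#' precondition (e.g. shorter than the maximum lag) aborts the extraction
#' with an error naming the offending protein; no padded rows are emitted.
#'
#' @param data Protein dataset tibble (see [as_protein_dataset()]).
#' @param descriptor Descriptor name, or a spec from [descriptor_spec()].
#' @param ... Parameter overrides when `descriptor` is a name.
#' @return Tibble of `nrow(data)` rows and `expected_length + 1` columns.
#' @examples
#' d <- tibble::tibble(id = c("p1", "p2"),
#'                     sequence = c(strrep("ACDKW", 10), strrep("LMNPQ", 10)))
#' extract_features(d, "SGAAC")
#' @export
extract_features <- function(data, descriptor, ...) {
  data <- as_protein_dataset(data, sanitize = NULL)
  spec <- if (inherits(descriptor, "descriptor_spec")) descriptor
          else descriptor_spec(descriptor, ...)
  fn <- registry_entries()[[spec$name]]$fn
  rows <- purrr::map2(data$id, data$sequence, function(id, s) {
    v <- tryCatch(fn(s, spec$params), error = function(e) {
      stop("descriptor ", spec$name, " failed for protein '", id, "': ",
           conditionMessage(e), call. = FALSE)
    })
    if (length(v) != spec$expected_length || any(!is.finite(v))) {
      stop("descriptor ", spec$name, " produced an invalid vector for '",
           id, "'", call. = FALSE)
    }
    v
  })
  m <- do.call(rbind, rows)
  colnames(m) <- paste0(spec$name, ".", colnames(m))
  dplyr::bind_cols(tibble(id = data$id), as_tibble(m))
}
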