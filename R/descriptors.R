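# Per-sequence descriptor functions. Each takes a canonical sequence string
# and returns a named numeric vector whose length matches the descriptor's
# published dimensionality at default parameters. Residues are always
# indexed in alphabetical order (AA_ALPHABET); grouped variants index the
# classes of the default 8-group physicochemical alphabet.

seq_index <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  idx <- match(ch, AA_ALPHABET)
  if (anyNA(idx)) {
    stop("non-canonical residue '", ch[which(is.na(idx))[1]],
         "'; sanitize the sequence first", call. = FALSE)
  }
  idx
}

# half-up rounding: the occurrence-index convention of the CTD
# distribution component (round(2.5) must be 3, not R's banker's 2)
round_half_up <- function(x) floor(x + 0.5)

comp_of_index <- function(idx, a, labels) {
  setNames(tabulate(idx, nbins = a) / length(idx), labels)
}

#' Amino-acid composition (AAC)
#'
#' Relative frequency of each of the 20 residues, alphabetical order;
#' entries sum to 1.
#'
#' @param seq Canonical amino-acid sequence string.
#' @return Named numeric vector of length 20.
#' @examples
#' aac("AAC")
#' @export
aac <- function(seq) {
  idx <- seq_index(seq)
  comp_of_index(idx, 20L, AA_ALPHABET)
}

#' K-part amino-acid composition (AAKpart)
#'
#' Splits the sequence into `k` contiguous parts of near-equal length (the
#' first `length %% k` parts receive one extra residue) and concatenates
#' the 20-residue composition of each part. Default `k = 3` gives the
#' published length 60.
#'
#' @inheritParams aac
#' @param k Number of contiguous parts.
#' @return Named numeric vector of length `20 * k`.
#' @export
aak_part_composition <- function(seq, k = 3L) {
  idx <- seq_index(seq)
  L <- length(idx)
  if (L < k) stop("sequence shorter than k = ", k, " parts", call. = FALSE)
  base <- L %/% k
  sizes <- rep(base, k) + c(rep(1L, L %% k), rep(0L, k - L %% k))
  part <- rep(seq_len(k), times = sizes)
  out <- unlist(lapply(seq_len(k), function(p) {
    comp_of_index(idx[part == p], 20L,
                  paste0("part", p, ".", AA_ALPHABET))
  }))
  out
}

#' Split (grouped) amino-acid composition (SAAC / SGAAC)
#'
#' Composition computed separately on the N-terminal segment (first `nt`
#' residues), the middle remainder, and the C-terminal segment (last `ct`
#' residues), then concatenated. Ungrouped (default) this is SAAC, length
#' `3 * 20 = 60`; with `grouped = TRUE` residues are first mapped to the
#' default 8-class alphabet giving SGAAC, length `3 * 8 = 24`.
#'
#' @inheritParams aac
#' @param nt,ct N- and C-terminal segment lengths (both default 5).
#' @param grouped Use the 8-class grouped alphabet.
#' @return Named numeric vector of length 60 (ungrouped) or 24 (grouped).
#' @export
saac <- function(seq, nt = 5L, ct = 5L, grouped = FALSE) {
  idx <- seq_index(seq)
  L <- length(idx)
  if (L < nt + ct + 1L) {
    stop("sequence of length ", L, " too short for nt = ", nt,
         ", ct = ", ct, call. = FALSE)
  }
  if (grouped) {
    idx <- grouped_mapping()[idx]
    a <- 8L
    labels <- paste0("G", 1:8)
  } else {
    a <- 20L
    labels <- AA_ALPHABET
  }
  segs <- list(nterm = idx[seq_len(nt)],
               middle = idx[seq.int(nt + 1L, L - ct)],
               cterm = idx[seq.int(L - ct + 1L, L)])
  unlist(lapply(names(segs), function(s) {
    comp_of_index(segs[[s]], a, paste0(s, ".", labels))
  }))
}

#' @rdname saac
#' @export
sgaac <- function(seq, nt = 5L, ct = 5L) saac(seq, nt, ct, grouped = TRUE)

kmer_labels <- function(a, k, letters) {
  grid <- expand.grid(rev(replicate(k, letters, simplify = FALSE)),
                      stringsAsFactors = FALSE)
  apply(as.matrix(grid[, rev(seq_len(k)), drop = FALSE]), 1, paste,
        collapse = "")
}

kmer_codes <- function(idx, a, k) {
  n <- length(idx) - k + 1L
  code <- rep(0L, n)
  for (j in seq_len(k)) {
    code <- code * a + (idx[seq.int(j, j + n - 1L)] - 1L)
  }
  code + 1L
}

#' Overlapping k-mer (grouped) composition
#'
#' Frequencies of all overlapping k-mers in lexicographic order, each count
#' divided by `length - k + 1`. Ungrouped with `k = 3` this is the
#' k-amino-acid composition of length `20^3 = 8000`; over the 8-class
#' grouped alphabet it is the grouped variant of length `8^3 = 512`.
#'
#' @inheritParams aac
#' @param k k-mer size.
#' @param grouped Use the 8-class grouped alphabet.
#' @return Named numeric vector of length `20^k` or `8^k`.
#' @export
kmer_composition <- function(seq, k = 3L, grouped = FALSE) {
  idx <- seq_index(seq)
  if (length(idx) < k) stop("sequence shorter than k = ", k, call. = FALSE)
  if (grouped) {
    idx <- grouped_mapping()[idx]
    a <- 8L
    letters <- paste0("G", 1:8)
  } else {
    a <- 20L
    letters <- AA_ALPHABET
  }
  codes <- kmer_codes(idx, a, k)
  setNames(tabulate(codes, nbins = a^k) / length(codes),
           kmer_labels(a, k, letters))
}

#' Composition of k-spaced (grouped) amino-acid pairs (CKSAAP)
#'
#' For every ordered residue pair (x, y), the frequency of positions `i`
#' with `seq[i] = x` and `seq[i + k + 1] = y` (i.e. `k` residues between
#' them), divided by the number of such positions `length - k - 1`.
#' Ungrouped length 400; grouped over the 8-class alphabet length 64.
#'
#' @inheritParams aac
#' @param k Gap size (number of residues between the pair); default 1.
#' @param grouped Use the 8-class grouped alphabet.
#' @return Named numeric vector of length 400 or 64; entries sum to 1.
#' @export
cks_pair <- function(seq, k = 1L, grouped = FALSE) {
  idx <- seq_index(seq)
  L <- length(idx)
  if (L < k + 2L) {
    stop("sequence of length ", L, " too short for gap k = ", k,
         call. = FALSE)
  }
  if (grouped) {
    idx <- grouped_mapping()[idx]
    a <- 8L
    letters <- paste0("G", 1:8)
  } else {
    a <- 20L
    letters <- AA_ALPHABET
  }
  n <- L - k - 1L
  first <- idx[seq_len(n)]
  second <- idx[seq.int(k + 2L, L)]
  code <- (first - 1L) * a + second
  setNames(tabulate(code, nbins = a * a) / n, kmer_labels(a, 2L, letters))
}

#' Dipeptide deviation from expected mean (DDE / GrpDDE)
#'
#' For each ordered dipeptide (i, j): the observed dipeptide fraction
#' `Dc = N_ij / (L - 1)` is standardized against the theoretical mean
#' `Tm = (C_i / C_N) (C_j / C_N)` and variance `Tv = Tm (1 - Tm) / (L - 1)`
#' derived from standard-code synonymous codon counts `C_i` (total
#' `C_N = 61`): `DDE = (Dc - Tm) / sqrt(Tv)`. The grouped variant uses
#' group dipeptides over the 8-class alphabet with `C_group` the sum of
#' the member residues' codon counts.
#'
#' @inheritParams aac
#' @param grouped Use the 8-class grouped alphabet.
#' @return Named numeric vector of length 400 (ungrouped) or 64 (grouped).
#' @export
dde <- function(seq, grouped = FALSE) {
  idx <- seq_index(seq)
  L <- length(idx)
  if (L < 2L) stop("sequence shorter than 2 residues", call. = FALSE)
  cc <- codon_counts()
  if (grouped) {
    map <- grouped_mapping()
    idx <- map[idx]
    a <- 8L
    letters <- paste0("G", 1:8)
    cvec <- as.numeric(tapply(cc, map[AA_ALPHABET], sum))
  } else {
    a <- 20L
    letters <- AA_ALPHABET
    cvec <- as.numeric(cc)
  }
  n <- L - 1L
  code <- (idx[seq_len(n)] - 1L) * a + idx[seq.int(2L, L)]
  Dc <- tabulate(code, nbins = a * a) / n
  Tm <- as.vector(outer(cvec / 61, cvec / 61))
  Tv <- Tm * (1 - Tm) / n
  setNames((Dc - Tm) / sqrt(Tv), kmer_labels(a, 2L, letters))
}

# residue -> class index matrix for the 7 CTD properties
ctd_class_matrix <- function() {
  if (is.null(the$ctd_classes)) {
    tb <- ctd_partitions()
    props <- sort(unique(tb$property))
    m <- sapply(props, function(p) {
      sub <- tb[tb$property == p, ]
      setNames(sub$class, sub$residue)[AA_ALPHABET]
    })
    rownames(m) <- AA_ALPHABET
    the$ctd_classes <- m
  }
  the$ctd_classes
}

#' Composition/transition/distribution (CTD) descriptors
#'
#' Three-class physicochemical encodings over seven properties
#' (hydrophobicity, normalized van der Waals volume, polarity,
#' polarizability, charge, secondary structure, solvent accessibility):
#'
#' * `ctdc()` — composition: fraction of residues in each class
#'   (7 x 3 = 21 features).
#' * `ctdt()` — transition: for each unordered class pair (a, b), the
#'   frequency of adjacent ab/ba pairs among the `L - 1` neighbours
#'   (7 x 3 = 21 features).
#' * `ctdd()` — distribution: for each class, the sequence positions (as
#'   percent of `L`) at which the 1st, 25%, 50%, 75% and 100% occurrences
#'   of that class fall, using occurrence index `max(1, round(q * n_c))`
#'   with half-up rounding; a class absent from the sequence yields five
#'   zeros (7 x 3 x 5 = 105 features).
#' * `ctd()` — the three blocks concatenated (147 features).
#'
#' @inheritParams aac
#' @return Named numeric vectors of length 21, 21, 105 and 147.
#' @export
ctdc <- function(seq) {
  idx <- seq_index(seq)
  cm <- ctd_class_matrix()
  unlist(lapply(colnames(cm), function(p) {
    comp_of_index(cm[idx, p], 3L, paste0(p, ".class", 1:3))
  }))
}

#' @rdname ctdc
#' @export
ctdt <- function(seq) {
  idx <- seq_index(seq)
  L <- length(idx)
  if (L < 2L) stop("transition needs at least 2 residues", call. = FALSE)
  cm <- ctd_class_matrix()
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  unlist(lapply(colnames(cm), function(p) {
    cl <- cm[idx, p]
    a <- cl[-L]
    b <- cl[-1]
    v <- apply(pairs, 1, function(pr) {
      sum((a == pr[1] & b == pr[2]) | (a == pr[2] & b == pr[1])) / (L - 1)
    })
    setNames(v, paste0(p, ".t", pairs[, 1], pairs[, 2]))
  }))
}

#' @rdname ctdc
#' @export
ctdd <- function(seq) {
  idx <- seq_index(seq)
  L <- length(idx)
  cm <- ctd_class_matrix()
  qs <- c(0, 0.25, 0.5, 0.75, 1)
  unlist(lapply(colnames(cm), function(p) {
    cl <- cm[idx, p]
    unlist(lapply(1:3, function(k) {
      pos <- which(cl == k)
      v <- if (length(pos) == 0L) {
        rep(0, 5)
      } else {
        occ <- pmax(1, round_half_up(qs * length(pos)))
        100 * pos[occ] / L
      }
      setNames(v, paste0(p, ".class", k, ".d", c("first", "25", "50", "75", "100")))
    }))
  }))
}

#' @rdname ctdc
#' @export
ctd <- function(seq) c(ctdc(seq), ctdt(seq), ctdd(seq))

# both distance matrices in the fixed block order used by the
# sequence-order descriptors
soc_matrices <- function() {
  list(sw = aa_distance_matrix("schneider_wrede"),
       grantham = aa_distance_matrix("grantham"))
}

soc_tau <- function(idx, m, nlag) {
  L <- length(idx)
  vapply(seq_len(nlag), function(d) {
    sum(m[cbind(idx[seq_len(L - d)], idx[seq.int(d + 1L, L)])]^2)
  }, numeric(1))
}

#' Sequence-order coupling numbers (SOCNumber)
#'
#' For each residue distance matrix `m` and each lag `d` in `1..nlag`, the
#' coupling number `tau_d = sum_i m(seq[i], seq[i+d])^2`. The two matrix
#' blocks (Schneider-Wrede-type, then Grantham) are concatenated; the
#' default `nlag = 30` gives the published length 60.
#'
#' @inheritParams aac
#' @param nlag Maximum lag; the sequence must be longer than `nlag`.
#' @return Named numeric vector of length `2 * nlag`.
#' @export
socnumber <- function(seq, nlag = 30L) {
  idx <- seq_index(seq)
  if (length(idx) <= nlag) {
    stop("sequence of length ", length(idx), " not longer than nlag = ",
         nlag, call. = FALSE)
  }
  ms <- soc_matrices()
  unlist(lapply(names(ms), function(nm) {
    setNames(soc_tau(idx, ms[[nm]], nlag), paste0(nm, ".tau", seq_len(nlag)))
  }))
}

#' Quasi-sequence-order descriptor (QSOrder)
#'
#' Per distance matrix, residue counts `f_r` and coupling numbers `tau_d`
#' are jointly normalized by `Z = sum(f) + w * sum(tau)`: the first 20
#' features are `f_r / Z`, the next `nlag` are `w * tau_d / Z`. The two
#' matrix blocks are concatenated; defaults `nlag = 5`, `w = 0.1` give the
#' published length `2 * (20 + 5) = 50`. Each block sums to 1.
#'
#' @inheritParams socnumber
#' @param w Weight of the sequence-order terms.
#' @return Named numeric vector of length `2 * (20 + nlag)`.
#' @export
qsorder <- function(seq, nlag = 5L, w = 0.1) {
  idx <- seq_index(seq)
  if (length(idx) <= nlag) {
    stop("sequence of length ", length(idx), " not longer than nlag = ",
         nlag, call. = FALSE)
  }
  f <- tabulate(idx, nbins = 20L)
  ms <- soc_matrices()
  unlist(lapply(names(ms), function(nm) {
    tau <- soc_tau(idx, ms[[nm]], nlag)
    Z <- sum(f) + w * sum(tau)
    setNames(c(f / Z, w * tau / Z),
             paste0(nm, ".", c(AA_ALPHABET, paste0("tau", seq_len(nlag)))))
  }))
}

#' Reduced-alphabet k-tuple composition (PseKRAAC-style engine)
#'
#' Maps the sequence into a reduced (clustered) amino-acid alphabet and
#' returns overlapping k-tuple frequencies normalized by
#' `length - k + 1`, in lexicographic tuple order over the *declared*
#' group count `g` (groups an artificial table declares but never
#' populates contribute structural zeros). Length is `g^k`: the bundled
#' tables reproduce the published 16 (`g4`, k = 2), 256 (`g16`, k = 2)
#' and 625 (`g25`, k = 2) vector lengths.
#'
#' @inheritParams aac
#' @param table A table name accepted by [reduced_alphabet()], or a list
#'   with elements `mapping` (named integer vector covering the 20
#'   residues) and `g` (declared group count).
#' @param k Tuple size.
#' @return Named numeric vector of length `g^k`.
#' @export
reduced_ktuple <- function(seq, table = "g4", k = 2L) {
  if (is.character(table)) table <- reduced_alphabet(table)
  mapping <- table$mapping[AA_ALPHABET]
  if (anyNA(mapping)) stop("reduced table must cover all 20 residues",
                           call. = FALSE)
  g <- as.integer(table$g)
  if (g < max(mapping)) stop("declared group count smaller than mapping",
                             call. = FALSE)
  idx <- mapping[seq_index(seq)]
  if (length(idx) < k) stop("sequence shorter than k = ", k, call. = FALSE)
  codes <- kmer_codes(idx, g, k)
  setNames(tabulate(codes, nbins = g^k) / length(codes),
           kmer_labels(g, k, paste0("G", seq_len(g))))
}

#' Lagged autocorrelation descriptors (AAutoCor)
#'
#' Encodes the sequence with one or more residue property scales
#' (standardized to mean 0, sd 1 over the 20 residues) and computes, for
#' each scale and lag `d` in `1..nlag`, the requested autocorrelation
#' statistics:
#'
#' * `moreau_broto` (normalized): `sum_i p_i p_{i+d} / (L - d)`
#' * `moran`: lagged covariance about the sequence mean over the sequence
#'   variance
#' * `geary`: half mean squared lagged difference over the (n-1)-normalized
#'   sequence variance
#'
#' A sequence with zero property variance (e.g. a homopolymer) yields zero
#' for the variance-normalized kinds by convention. Ordering is kind-major,
#' then property, then lag. The default 8 bundled scales with `nlag = 19`
#' and all 3 kinds give length `3 * 8 * 19 = 456`.
#'
#' @inheritParams aac
#' @param properties Named list of property scales (each a named numeric
#'   vector over the 20 residues); `NULL` uses the 8 bundled scales.
#' @param nlag Maximum lag; the sequence must be longer than `nlag`.
#' @param kinds Subset of `c("moreau_broto", "moran", "geary")`.
#' @return Named numeric vector of length
#'   `length(kinds) * length(properties) * nlag`.
#' @export
autocorrelation <- function(seq, properties = NULL, nlag = 19L,
                            kinds = c("moreau_broto", "moran", "geary")) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  if (is.null(properties)) properties <- aa_property_scales()
  idx <- seq_index(seq)
  L <- length(idx)
  if (L <= nlag) {
    stop("sequence of length ", L, " not longer than nlag = ", nlag,
         call. = FALSE)
  }
  unlist(lapply(kinds, function(kind) {
    unlist(lapply(names(properties), function(pn) {
      sc <- properties[[pn]][AA_ALPHABET]
      if (anyNA(sc)) stop("property scale '", pn,
                          "' must cover all 20 residues", call. = FALSE)
      sc <- as.numeric(scale(sc))  # standardized over the 20 residues
      p <- sc[idx]
      pbar <- mean(p)
      v <- switch(kind,
        moreau_broto = vapply(seq_len(nlag), function(d) {
          sum(p[seq_len(L - d)] * p[seq.int(d + 1L, L)]) / (L - d)
        }, numeric(1)),
        moran = {
          s2 <- sum((p - pbar)^2) / L
          if (s2 == 0) rep(0, nlag) else vapply(seq_len(nlag), function(d) {
            sum((p[seq_len(L - d)] - pbar) * (p[seq.int(d + 1L, L)] - pbar)) /
              (L - d) / s2
          }, numeric(1))
        },
        geary = {
          s2 <- sum((p - pbar)^2) / (L - 1)
          if (s2 == 0) rep(0, nlag) else vapply(seq_len(nlag), function(d) {
            sum((p[seq_len(L - d)] - p[seq.int(d + 1L, L)])^2) /
              (2 * (L - d)) / s2
          }, numeric(1))
        })
      setNames(v, paste0(kind, ".", pn, ".lag", seq_len(nlag)))
    }))
  }))
}

#' @rdname reference-tables
#' @export
aa_property_scales <- function() {
  tb <- read_extdata("aa_property_scales.tsv")
  out <- lapply(names(tb)[-1], function(p) setNames(tb[[p]], tb$residue))
  setNames(out, names(tb)[-1])
}
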