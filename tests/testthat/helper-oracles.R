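# Independent brute-force oracles. These deliberately share no code with
# the package: plain loops over positions, pairs and windows, written from
# the descriptor definitions, so that agreement is evidence rather than
# tautology.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_seq <- function(len, letters = AA) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

o_chars <- function(seq) strsplit(seq, "")[[1]]

# composition by direct counting
o_aac <- function(seq) {
  ch <- o_chars(seq)
  vapply(AA, function(a) sum(ch == a) / length(ch), numeric(1))
}

# overlapping k-mer frequencies by substring enumeration
o_kmer <- function(seq, k, mapping = NULL, g = 20) {
  ch <- o_chars(seq)
  if (!is.null(mapping)) ch <- as.character(mapping[ch])
  n <- length(ch) - k + 1
  words <- vapply(seq_len(n), function(i) {
    paste(ch[i:(i + k - 1)], collapse = "")
  }, character(1))
  syms <- if (is.null(mapping)) AA else as.character(sort(unique(mapping)))
  if (!is.null(mapping) && g > length(syms)) syms <- as.character(seq_len(g))
  all_words <- apply(expand.grid(rev(replicate(k, syms, simplify = FALSE)),
                                 stringsAsFactors = FALSE)[, k:1, drop = FALSE],
                     1, paste, collapse = "")
  vapply(all_words, function(w) sum(words == w) / n, numeric(1))
}

# k-spaced pair frequencies by position loop
o_cks <- function(seq, k, mapping = NULL) {
  ch <- o_chars(seq)
  if (!is.null(mapping)) ch <- as.character(mapping[ch])
  syms <- if (is.null(mapping)) AA else as.character(sort(unique(mapping)))
  n <- length(ch) - k - 1
  out <- setNames(numeric(length(syms)^2),
                  as.vector(t(outer(syms, syms, paste0))))
  for (i in seq_len(n)) {
    key <- paste0(ch[i], ch[i + k + 1])
    out[key] <- out[key] + 1
  }
  out / n
}

# dipeptide deviation from expected mean, direct formula evaluation
o_dde <- function(seq) {
  codons <- c(A=4,C=2,D=2,E=2,F=2,G=4,H=2,I=3,K=2,L=6,M=1,N=2,P=4,Q=2,
              R=6,S=6,T=4,V=4,W=1,Y=2)
  ch <- o_chars(seq)
  L <- length(ch)
  out <- numeric(0)
  for (a in AA) for (b in AA) {
    nab <- 0
    for (i in seq_len(L - 1)) if (ch[i] == a && ch[i + 1] == b) nab <- nab + 1
    Dc <- nab / (L - 1)
    Tm <- (codons[[a]] / 61) * (codons[[b]] / 61)
    Tv <- Tm * (1 - Tm) / (L - 1)
    out[paste0(a, b)] <- (Dc - Tm) / sqrt(Tv)
  }
  out
}

# CTD parts from a residue -> class vector
o_ctd_parts <- function(seq, classes) {
  ch <- o_chars(seq)
  cl <- classes[ch]
  L <- length(cl)
  C <- vapply(1:3, function(k) sum(cl == k) / L, numeric(1))
  Tn <- c(`12` = 0, `13` = 0, `23` = 0)
  for (i in seq_len(L - 1)) {
    pr <- sort(c(cl[i], cl[i + 1]))
    if (pr[1] != pr[2]) {
      key <- paste0(pr[1], pr[2])
      Tn[key] <- Tn[key] + 1
    }
  }
  D <- unlist(lapply(1:3, function(k) {
    pos <- which(cl == k)
    if (length(pos) == 0) return(rep(0, 5))
    idx <- pmax(1, floor(c(0, 0.25, 0.5, 0.75, 1) * length(pos) + 0.5))
    100 * pos[idx] / L
  }))
  list(C = C, T = Tn / (L - 1), D = D)
}

# sequence-order coupling numbers by explicit double indexing
o_soc <- function(seq, nlag, m) {
  ch <- o_chars(seq)
  L <- length(ch)
  vapply(seq_len(nlag), function(d) {
    s <- 0
    for (i in seq_len(L - d)) s <- s + m[ch[i], ch[i + d]]^2
    s
  }, numeric(1))
}

o_qso_block <- function(seq, nlag, w, m) {
  ch <- o_chars(seq)
  f <- vapply(AA, function(a) sum(ch == a), numeric(1))
  tau <- o_soc(seq, nlag, m)
  Z <- sum(f) + w * sum(tau)
  c(f / Z, w * tau / Z)
}

# pairwise-ordering AUC (ties count one half)
o_auc <- function(scores, pos) {
  ps <- scores[pos]
  ns <- scores[!pos]
  tot <- 0
  for (p in ps) for (q in ns) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(ps) * length(ns))
}

# direct evaluation of the five metric formulas
o_metrics <- function(tp, fp, tn, fn) {
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  list(acc = (tp + tn) / (tp + fp + tn + fn),
       precision = prec, recall = rec,
       f_measure = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0,
       mcc = if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0)
}

# miss counts recomputed row by row from a raw prediction log
o_tally <- function(log) {
  ids <- unique(log$id)
  vapply(ids, function(i) {
    sum(!log$correct[log$id == i])
  }, numeric(1))
}

# small labeled dataset for CV tests: two compositional classes
tiny_dataset <- function(n_per_class = 15, delta = 1, seed = 42,
                         len = 40) {
  withr::with_seed(seed, {
    mk <- function(lab, letters, i) {
      tibble::tibble(id = paste0(lab, i),
                     sequence = rand_seq(len, letters), label = lab)
    }
    dplyr::bind_rows(
      purrr::map_dfr(seq_len(n_per_class), function(i) {
        mk("MP", AA[1:10], i)
      }),
      purrr::map_dfr(seq_len(n_per_class), function(i) {
        mk("NONMP", AA[11:20], i)
      }))
  })
}
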