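# Worked hand-checkable cases first, then brute-force oracle agreement on
# random sequences, then the structural invariants shared by the
# composition-type descriptors.

pangram <- paste(AA, collapse = "")

test_that("composition descriptors match hand-worked cases", {
  expect_equal(unname(aac("AAAA")), c(1, rep(0, 19)))
  expect_equal(unname(aac(pangram)), rep(0.05, 20))
  expect_equal(unname(aac("AAC")[c("A", "C")]), c(2 / 3, 1 / 3))

  # near-equal parts, remainder to the front: "AAAAC" k=2 -> "AAA" | "AC"
  v <- aak_part_composition("AAAAC", k = 2)
  expect_equal(unname(v["part1.A"]), 1)
  expect_equal(unname(v[c("part2.A", "part2.C")]), c(0.5, 0.5))
  p <- aak_part_composition("AAACCCDDD", k = 3)
  expect_equal(unname(p[c("part1.A", "part2.C", "part3.D")]), c(1, 1, 1))

  # homogeneous terminal segments
  s <- saac("AAAAACCCCCDDDDD")
  expect_equal(unname(s[c("nterm.A", "middle.C", "cterm.D")]), c(1, 1, 1))
  # length-11 sequence: the middle segment is the single central residue
  s2 <- saac("AAAAACAAAAA")
  expect_equal(unname(s2["middle.C"]), 1)

  k <- kmer_composition("AAAA", k = 3)
  expect_equal(unname(k["AAA"]), 1)
  expect_equal(sum(k), 1)
  k2 <- kmer_composition("ACAC", k = 2)
  expect_equal(unname(k2[c("AC", "CA")]), c(2 / 3, 1 / 3))

  c0 <- cks_pair("ACAC", k = 0)
  expect_equal(unname(c0[c("AC", "CA")]), c(2 / 3, 1 / 3))
  c1 <- cks_pair("ACAC", k = 1)
  expect_equal(unname(c1[c("AA", "CC")]), c(0.5, 0.5))

  r <- reduced_ktuple(strrep("A", 10), table = "g4", k = 2)
  expect_equal(sum(r == 1), 1)
  expect_equal(sum(r), 1)
})

test_that("DDE matches its defining formulas", {
  v <- dde("AC")
  Tm <- (4 / 61) * (2 / 61)
  expect_equal(unname(v["AC"]), (1 - Tm) / sqrt(Tm * (1 - Tm) / 1))
  # dipeptides never observed score -Tm / sqrt(Tv)
  Tm_wc <- (1 / 61) * (2 / 61)
  expect_equal(unname(v["WC"]), -Tm_wc / sqrt(Tm_wc * (1 - Tm_wc) / 1))

  # monotone in the theoretical mean at fixed observed fraction: in
  # "ACDE" all three dipeptides have Dc = 1/3 but different Tm
  v2 <- dde("ACDE")
  # Tm(AC) = 8/61^2 > Tm(CD) = 4/61^2 -> lower standardized deviation
  expect_lt(v2[["AC"]], v2[["CD"]])
  expect_equal(v2[["CD"]], v2[["DE"]])  # equal Tm, equal Dc

  withr::with_seed(5, {
    for (s in replicate(5, rand_seq(30))) {
      expect_equal(max(abs(dde(s) - o_dde(s))), 0, tolerance = 1e-12)
    }
  })
})

test_that("CTD components match the stated percentile rule", {
  # homopolymer: one occupied class per property
  v <- ctdd(strrep("K", 10))
  parts <- ctd_partitions()
  for (p in unique(parts$property)) {
    k <- parts$class[parts$property == p & parts$residue == "K"]
    got <- v[paste0(p, ".class", k, ".d", c("first", "25", "50", "75", "100"))]
    expect_equal(unname(got), c(10, 30, 50, 80, 100))
    other <- setdiff(1:3, k)
    expect_true(all(v[grep(paste0(p, ".class", other[1]), names(v))] == 0))
  }
  cv <- ctdc(strrep("K", 10))
  expect_true(all(cv %in% c(0, 1)))
  expect_true(all(ctdt(strrep("K", 10)) == 0))

  # oracle agreement per property on random sequences
  cm <- sapply(unique(parts$property), function(p) {
    sub <- parts[parts$property == p, ]
    stats::setNames(sub$class, sub$residue)[AA]
  })
  withr::with_seed(6, {
    for (s in replicate(5, rand_seq(25))) {
      full <- ctd(s)
      for (p in colnames(cm)) {
        o <- o_ctd_parts(s, stats::setNames(cm[, p], AA))
        expect_equal(unname(full[paste0(p, ".class", 1:3)]), unname(o$C))
        expect_equal(unname(full[paste0(p, ".t", c("12", "13", "23"))]),
                     unname(o$T))
        expect_equal(
          unname(full[grep(paste0("^", p, "\\.class[123]\\.d"), names(full))]),
          unname(o$D))
      }
      # composition classes partition the residues
      expect_equal(as.numeric(tapply(ctdc(s), rep(1:7, each = 3), sum)),
                   rep(1, 7), tolerance = 1e-12)
    }
  })
})

test_that("sequence-order descriptors match direct summation", {
  hp <- strrep("A", 40)
  expect_true(all(socnumber(hp) == 0))        # d(a, a) = 0
  q <- qsorder(strrep("A", 10))
  expect_equal(unname(q[c("sw.A", "grantham.A")]), c(1, 1))
  expect_equal(sum(q[1:25]), 1)               # block normalization
  expect_equal(sum(q[26:50]), 1)

  sw <- aa_distance_matrix("schneider_wrede")
  gr <- aa_distance_matrix("grantham")
  expect_equal(unname(socnumber("AC", nlag = 1)),
               c(sw["A", "C"]^2, gr["A", "C"]^2))

  withr::with_seed(7, {
    for (s in replicate(4, rand_seq(45))) {
      expect_equal(unname(socnumber(s)),
                   unname(c(o_soc(s, 30, sw), o_soc(s, 30, gr))),
                   tolerance = 1e-9)
      expect_equal(unname(qsorder(s)),
                   unname(c(o_qso_block(s, 5, 0.1, sw),
                            o_qso_block(s, 5, 0.1, gr))),
                   tolerance = 1e-12)
    }
  })
  expect_error(socnumber(strrep("A", 30)), "nlag")
})

test_that("autocorrelation agrees with brute force and handles zero variance", {
  s <- strrep("AC", 10)
  scales <- aa_property_scales()
  p <- as.numeric(scale(scales[[1]][AA]))
  names(p) <- AA
  ch <- o_chars(s)
  L <- length(ch)
  brute <- sum(p[ch[1:(L - 1)]] * p[ch[2:L]]) / (L - 1)
  v <- autocorrelation(s, properties = scales[1], nlag = 1,
                       kinds = "moreau_broto")
  expect_equal(unname(v), brute)

  hp <- autocorrelation(strrep("K", 30), nlag = 2,
                        kinds = c("moran", "geary"))
  expect_true(all(hp == 0))
  expect_equal(length(autocorrelation(rand_seq(40), properties = scales[1],
                                      nlag = 2, kinds = "moran")), 2L)
})

test_that("counting descriptors equal brute-force enumeration on random sequences", {
  g8 <- aa_grouped_alphabet()
  gmap <- stats::setNames(g8$group, g8$residue)
  withr::with_seed(8, {
    for (s in replicate(20, rand_seq(sample(31:60, 1)))) {
      expect_equal(unname(aac(s)), unname(o_aac(s)), tolerance = 1e-12)
      expect_equal(unname(kmer_composition(s, 2)),
                   unname(o_kmer(s, 2)), tolerance = 1e-12)
      expect_equal(unname(kmer_composition(s, 3, grouped = TRUE)),
                   unname(o_kmer(s, 3, gmap, g = 8)), tolerance = 1e-12)
      expect_equal(unname(cks_pair(s, 1)), unname(o_cks(s, 1)),
                   tolerance = 1e-12)
      expect_equal(unname(cks_pair(s, 3, grouped = TRUE)),
                   unname(o_cks(s, 3, gmap)), tolerance = 1e-12)
    }
  })
})

test_that("permutation invariance holds exactly where expected and fails where not", {
  withr::with_seed(9, {
    s <- rand_seq(50)
    perm <- paste(sample(o_chars(s)), collapse = "")
    expect_equal(aac(s), aac(perm))
    expect_equal(kmer_composition(s, 1), kmer_composition(perm, 1))
    expect_equal(ctdc(s), ctdc(perm))
    # order-sensitive blocks must differ for a shuffled non-homopolymer
    expect_false(isTRUE(all.equal(socnumber(s), socnumber(perm))))
    expect_false(isTRUE(all.equal(qsorder(s)[21:25], qsorder(perm)[21:25])))
  })
})

test_that("extraction is deterministic, dimension-checked and id-attributed", {
  d <- worked_fixtures()
  d <- d[d$id %in% c("homoA", "pangram"), ]
  m1 <- extract_features(d, "SGAAC")
  m2 <- extract_features(d, "SGAAC")
  expect_identical(m1, m2)
  expect_equal(dim(m1), c(2L, 25L))
  expect_match(names(m1)[2], "^SGAAC\\.")

  expect_error(extract_features(d, "FOO"), "SAAC")  # lists registered names
  short <- tibble::tibble(id = "tiny", sequence = "ACD")
  expect_error(extract_features(short, "SOCNumber"), "tiny")
})
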