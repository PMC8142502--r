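test_that("FASTA records are parsed with ids, labels and case folding", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 sp|desc here", "ACDE", ">p2", "wywy"), fa)
  d <- read_fasta(fa, label = "MP")
  expect_equal(d$id, c("p1", "p2"))
  expect_equal(d$sequence, c("ACDE", "WYWY"))
  expect_equal(d$label, c("MP", "MP"))
  expect_equal(d$description[1], "sp|desc here")

  writeLines(c(">p1", "ACDE", ">p1", "WYWY"), fa)
  expect_error(read_fasta(fa, "MP"), "p1")
  expect_error(read_fasta(tempfile(), "MP"), "not found")
})

test_that("wrapped and two-file FASTA layouts round-trip exactly", {
  d <- generate_synthetic(synth_config(n_per_class = 5, seed = 3))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(d, fa, width = 37)  # deliberately awkward wrap
  back <- read_fasta(fa, "UNKNOWN")
  expect_equal(back$id, d$id)
  expect_equal(back$sequence, d$sequence)

  mp <- withr::local_tempfile(fileext = ".fasta")
  nonmp <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(d[d$label == "MP", ], mp)
  write_fasta(d[d$label == "NONMP", ], nonmp)
  both <- read_fasta_pair(mp, nonmp)
  cc <- class_counts(both)
  expect_equal(cc$n[cc$label == "MP"], sum(d$label == "MP"))
  expect_equal(cc$n[cc$label == "NONMP"], sum(d$label == "NONMP"))
})

test_that("sanitization policies behave per contract", {
  expect_equal(sanitize_sequence("AC DE\n", "strict"), "ACDE")
  expect_equal(sanitize_sequence("ACXDE", "drop"), "ACDE")
  expect_error(sanitize_sequence("ACXDE", "strict"), "X.*position 3")
  expect_equal(sanitize_sequence("ACBDE"), "ACNDE")   # B -> N
  expect_equal(sanitize_sequence("AZUOJX"), "AQCKLA") # full ambiguity map
  expect_error(sanitize_sequence("XXX", "drop"), "empty")
  expect_error(as_protein_dataset(
    tibble::tibble(id = "p", sequence = "ACXDE"), sanitize = NULL),
    "non-canonical")
})

test_that("feature tables round-trip at full precision and refuse NA", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  m <- tibble::tibble(id = c("p1", "p2"), f1 = c(1 / 3, 2.5e-17),
                      f2 = c(-1.2345678901234567, 0))
  write_feature_table(m, tf)
  back <- read_feature_table(tf)
  expect_equal(back$id, m$id)
  expect_equal(back$f1, m$f1, tolerance = 1e-15)
  expect_equal(names(back), names(m))

  empty <- m[0, ]
  write_feature_table(empty, tf)
  expect_equal(nrow(read_feature_table(tf)), 0L)

  m$f1[2] <- NaN
  expect_error(write_feature_table(m, tf), "row 2.*f1")
})
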