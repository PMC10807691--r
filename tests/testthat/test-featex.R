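test_that("amino acid composition follows the canonical ordering", {
  v <- aac("AAAA")
  expect_equal(unname(v[1]), 1)
  expect_equal(sum(v), 1)

  expect_equal(unname(aac("ARNDCEQGHILKMFPSTWYV")), rep(0.05, 20))

  v <- aac("MKKL")  # K is position 12, M 13, L 11
  expect_equal(unname(v["aac_12"]), 0.5)
  expect_equal(unname(v["aac_13"]), 0.25)
  expect_equal(unname(v["aac_11"]), 0.25)
})

test_that("dipeptide composition indexes ordered pairs", {
  v <- dipeptide("ACA")  # A=1, C=5: AC -> 20*0+5 = 5, CA -> 20*4+1 = 81
  expect_equal(unname(v["dipep_5"]), 0.5)
  expect_equal(unname(v["dipep_81"]), 0.5)
  expect_equal(sum(v), 1)

  expect_equal(unname(dipeptide("AAAA")["dipep_1"]), 1)
  expect_error(dipeptide("A"), "length")

  set.seed(21)
  for (L in c(2, 7, 30)) {
    s <- random_sequence(L)
    expect_equal(sum(dipeptide(s)) * (L - 1), L - 1)
  }
})

test_that("pseudo amino acid composition matches direct summation", {
  v <- pseaac(strrep("A", 12))
  expect_equal(unname(v[1]), 1)
  expect_equal(unname(v[-1]), rep(0, 29))

  expect_error(pseaac(strrep("A", 10)), "minimum")

  set.seed(22)
  for (i in 1:20) {
    s <- random_sequence(sample(15:40, 1))
    got <- pseaac(s)
    expect_length(got, 30)
    expect_equal(sum(got), 1, tolerance = 1e-12)
    expect_equal(unname(got), unname(oracle_pseaac(s)), tolerance = 1e-9)
  }
})

test_that("amphiphilic pseudo amino acid composition matches direct summation", {
  v <- apseaac(strrep("L", 15))
  expect_equal(unname(v[11]), 1)  # L is the 11th residue
  expect_equal(sum(abs(v[21:40])), 0)

  set.seed(23)
  for (i in 1:20) {
    s <- random_sequence(sample(15:40, 1))
    got <- apseaac(s)
    expect_length(got, 40)
    expect_true(all(got >= 0))
    expect_equal(sum(got), 1, tolerance = 1e-12)
    expect_equal(unname(got), unname(oracle_apseaac(s)), tolerance = 1e-9)
  }
})

test_that("CTD descriptors match a position-enumeration oracle", {
  # K and R are both in group 1 of the charge attribute (attribute 5) and
  # group 1 of the hydrophobicity attribute (attribute 1)
  v <- ctd("KRKRKR")
  expect_equal(unname(v["comp_1"]), 1)  # hydrophobicity group 1
  expect_equal(unname(v[c("comp_2", "comp_3")]), c(0, 0))
  expect_equal(unname(v[c("tran_1", "tran_2", "tran_3")]), c(0, 0, 0))

  set.seed(24)
  for (i in 1:20) {
    s <- random_sequence(sample(12:40, 1))
    got <- ctd(s)
    expect_length(got, 147)
    # per-attribute composition triples are partitions
    comp <- got[1:21]
    for (a in 1:7) expect_equal(sum(comp[(3 * a - 2):(3 * a)]), 1,
                                tolerance = 1e-12)
    expect_equal(unname(got), oracle_ctd(s), tolerance = 1e-9)
  }
})

test_that("secondary-structure features capture positions, runs and motifs", {
  v <- ss_features("HHHH")
  expect_equal(unname(v), c(0.625, 0, 0, 0, 1, 0))

  v <- ss_features("EHE")
  expect_equal(unname(v["ss_6"]), 1)
  expect_equal(unname(v["ss_4"]), 1 / 3)
  expect_equal(unname(v["ss_5"]), 1 / 3)

  v <- ss_features("CCHHHHECC")
  expect_equal(unname(v["ss_4"]), 1 / 9)
  expect_equal(unname(v["ss_5"]), 4 / 9)
  expect_equal(unname(v["ss_6"]), 0)  # collapsed non-coil string is "HE"

  expect_error(ss_features("HEX"), "X")

  # count mode counts overlapping motifs after collapsing
  cfg <- descriptor_config(ehe_mode = "count")
  expect_equal(unname(ss_features("EHEHE", cfg)["ss_6"]), 2)
  expect_equal(unname(ss_features("ECCHCCECHCE", cfg)["ss_6"]), 2)
})

test_that("sequence-order-coupling numbers match a double-loop oracle", {
  expect_equal(unname(socn(strrep("G", 25))), rep(0, 20))
  expect_error(socn(strrep("G", 20)), "21")

  set.seed(25)
  for (i in 1:20) {
    s <- random_sequence(sample(25:60, 1))
    got <- socn(s)
    expect_length(got, 20)
    expect_true(all(got >= 0))
    expect_equal(unname(got), oracle_socn(s), tolerance = 1e-9)
  }
})

test_that("quasi-sequence-order descriptors match the direct formula", {
  v <- qso(strrep("W", 25))  # W is the 18th residue
  expect_equal(unname(v[18]), 1)
  expect_equal(sum(v), 1)

  set.seed(26)
  for (i in 1:20) {
    s <- random_sequence(sample(25:60, 1))
    got <- qso(s)
    expect_length(got, 40)
    expect_equal(sum(got), 1, tolerance = 1e-12)
    expect_equal(unname(got), unname(oracle_qso(s)), tolerance = 1e-9)
  }
})

test_that("descriptors depend only on the sequence content", {
  set.seed(27)
  s <- random_sequence(30)
  fa1 <- withr::local_tempfile(fileext = ".fasta")
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(c(x1 = s), fa1, width = 60)
  write_fasta(c(renamed = s), fa2, width = 7)
  r1 <- read_fasta(fa1)
  r2 <- read_fasta(fa2)
  expect_equal(unname(aac(r1[[1]])), unname(aac(r2[[1]])))
  expect_equal(unname(qso(r1[[1]])), unname(qso(r2[[1]])))
})

test_that("the assembled matrix has the pinned 1,103-column schema", {
  fix <- generate_fixtures(fixture_config(3, 3, seed = 31))
  fm <- assemble_features(fix$dataset, fix$ss, fix$pssm)
  expect_equal(dim(fm$x), c(6L, 1103L))
  fam <- sub("_[0-9]+$", "", colnames(fm$x))
  expect_equal(as.vector(table(fam)[c("aac", "dipep", "pseudo",
                                      "amphipseudo", "comp", "tran", "dist",
                                      "ss", "socn", "qso", "pssm")]),
               c(20L, 400L, 30L, 40L, 21L, 21L, 105L, 6L, 20L, 40L, 400L))
  expect_true(all(is.finite(fm$x)))

  # schema determinism and per-family equality with single-record calls
  fm2 <- assemble_features(fix$dataset, fix$ss, fix$pssm)
  expect_identical(colnames(fm$x), colnames(fm2$x))
  id <- names(fix$dataset$sequences)[1]
  s <- fix$dataset$sequences[[id]]
  expect_equal(fm$x[id, 1:20], aac(s))
  expect_equal(fm$x[id, 21:420], dipeptide(s))
  expect_equal(fm$x[id, 704:1103], pssm_bigram(fix$pssm[[id]]))
})

test_that("assembly rejects incomplete or undersized inputs", {
  fix <- generate_fixtures(fixture_config(2, 2, seed = 32))
  expect_error(assemble_features(fix$dataset, fix$ss[-1], fix$pssm),
               names(fix$dataset$sequences)[1])
  expect_error(assemble_features(fix$dataset, fix$ss, fix$pssm[-2]),
               names(fix$dataset$sequences)[2])
  short <- labeled_dataset(c(tiny = strrep("A", 21)), 1L)
  expect_error(assemble_features(short, c(tiny = strrep("C", 21)),
                                 list(tiny = fix$pssm[[1]])), "22")
})

test_that("feature matrices round-trip through TSV", {
  fix <- generate_fixtures(fixture_config(2, 2, seed = 33))
  fm <- assemble_features(fix$dataset, fix$ss, fix$pssm)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(fm, tsv)
  back <- read_feature_tsv(tsv)
  expect_identical(colnames(back$x), colnames(fm$x))
  expect_equal(back$x, fm$x, tolerance = 1e-9)
  expect_equal(unname(back$labels), unname(fm$labels))
})

test_that("8-state secondary-structure input maps onto three states", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tGHIEBSTC", "b\tHEC"), tsv)
  ss <- read_ss_tsv(tsv)
  expect_identical(unname(ss["a"]), "HHHEECCC")
  expect_identical(unname(ss["b"]), "HEC")
})
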