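test_that("FASTA parsing normalizes case, strips stop symbols, keeps order", {
  p <- write_temp_fasta(c(">p1", "MGK"))
  rec <- parse_fasta(p, species = "sp")
  expect_equal(rec$id, "p1")
  expect_equal(rec$sequence, "MGK")
  expect_equal(rec$species, "sp")

  p2 <- write_temp_fasta(c(">p1 some annotation", "mgk*"))
  rec2 <- parse_fasta(p2)
  expect_equal(rec2$sequence, "MGK")
  expect_equal(rec2$annotation, "some annotation")

  p3 <- write_temp_fasta(c(">a", "MGK", ">b", "KR", "H"))
  rec3 <- parse_fasta(p3)
  expect_equal(rec3$id, c("a", "b"))
  expect_equal(rec3$sequence, c("MGK", "KRH"))
})

test_that("FASTA parsing rejects illegal characters, internal stops, empty files", {
  p <- write_temp_fasta(c(">p1", "MG1K"))
  expect_error(parse_fasta(p), "position 3")
  p2 <- write_temp_fasta(c(">p1", "MG*K"))
  expect_error(parse_fasta(p2), "position 3")
  p3 <- write_temp_fasta(character(0))
  expect_error(parse_fasta(p3), "no records|cannot read")
  expect_error(parse_fasta(tempfile()), "not found")
})

test_that("shipped property table reproduces the printed worked example exactly", {
  fa <- system.file("extdata", "example.fasta", package = "rama")
  rec <- parse_fasta(fa, species = "A. thaliana")
  expect_equal(nchar(rec$sequence), 62L)
  a <- compute_attributes(rec)
  printed <- c(aromatic = 0.048387, negatively_charged = 0.016129,
               nonpolar_aliphatic = 0.419355, polar_uncharged = 0.209677,
               positively_charged = 0.306452, hydrophobicity = -1.062903,
               molecular_mass = 129.112903, volume = 134.462903, length = 62)
  # equality at the six-decimal precision the values are reported at
  expect_identical(sprintf("%.6f", a[names(printed)]),
                   sprintf("%.6f", printed))
})

test_that("property table invariants hold and a broken table is rejected", {
  tab <- residue_properties()
  expect_equal(nrow(tab), 20L)
  expect_equal(as.integer(table(tab$group)[names(residue_groups())]),
               c(3L, 2L, 7L, 5L, 3L))
  bad <- as.data.frame(tab)
  bad$group[bad$residue == "K"] <- "aromatic"
  expect_error(rama:::validate_property_table(bad), "partition")
})

test_that("single-group and constant sequences behave as the group definitions say", {
  a <- compute_attributes("KRH")
  expect_equal(a[["positively_charged"]], 1)
  expect_equal(sum(a[c("aromatic", "negatively_charged", "nonpolar_aliphatic",
                       "polar_uncharged")]), 0)
  expect_equal(a[["length"]], 3)

  tab <- residue_properties()
  g <- compute_attributes("GGGG")
  expect_equal(g[["nonpolar_aliphatic"]], 1)
  expect_equal(g[["hydrophobicity"]], tab["G", "hydropathy"])
  expect_equal(g[["molecular_mass"]], tab["G", "mass"])
  expect_equal(g[["volume"]], tab["G", "volume"])
})

test_that("proportions sum to one for random standard-residue sequences", {
  set.seed(101)
  prop_cols <- c("aromatic", "negatively_charged", "nonpolar_aliphatic",
                 "polar_uncharged", "positively_charged")
  for (i in 1:200) {
    a <- compute_attributes(random_standard_sequence(sample(1:400, 1)))
    expect_lt(abs(sum(a[prop_cols]) - 1), 1e-9)
  }
})

test_that("attributes are additive under concatenation and order-blind", {
  set.seed(7)
  for (i in 1:25) {
    s1 <- random_standard_sequence(sample(5:120, 1))
    s2 <- random_standard_sequence(sample(5:120, 1))
    a1 <- compute_attributes(s1); a2 <- compute_attributes(s2)
    a12 <- compute_attributes(paste0(s1, s2))
    n1 <- a1[["length"]]; n2 <- a2[["length"]]
    expect_equal(a12[["length"]], n1 + n2)
    # every proportion and mean is the length-weighted mean of the parts
    expect_equal(a12[-9], (n1 * a1[-9] + n2 * a2[-9]) / (n1 + n2),
                 tolerance = 1e-12)
    shuffled <- paste(sample(strsplit(s1, "")[[1]]), collapse = "")
    expect_identical(compute_attributes(shuffled), a1)
  }
})

test_that("ambiguity codes count toward length but not toward groups or means", {
  a <- compute_attributes("MGKX")
  b <- compute_attributes("MGK")
  expect_equal(a[["length"]], 4)
  expect_equal(a[["positively_charged"]], 1 / 4)
  expect_equal(a[["hydrophobicity"]], b[["hydrophobicity"]])
  expect_equal(a[["molecular_mass"]], b[["molecular_mass"]])
  expect_error(compute_attributes("XXXX"), "no standard residue")
})

test_that("feature tables round-trip through TSV and ARFF", {
  p <- write_temp_fasta(c(">a first", "MGKVHGSLAR", ">b second", "KRHKRHWWDE"))
  rec <- parse_fasta(p, species = "sp1")
  tab <- attributes_to_table(rec)
  expect_equal(nrow(tab), 2L)
  expect_equal(names(tab), c("id", "species", attribute_names()))

  empty <- attributes_to_table(rec[0, , drop = FALSE])
  expect_equal(nrow(empty), 0L)
  expect_equal(names(empty), c("id", "species", attribute_names()))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(tab, tsv)
  back <- read_feature_tsv(tsv)
  for (nm in attribute_names())
    expect_equal(back[[nm]], tab[[nm]], tolerance = 5e-7)

  arff <- withr::local_tempfile(fileext = ".arff")
  tab$class <- c("RP", "NRP")
  write_feature_arff(tab[, c(attribute_names(), "class")], arff)
  back2 <- read_feature_arff(arff)
  expect_equal(as.character(back2$class), c("RP", "NRP"))
  expect_equal(back2$positively_charged, tab$positively_charged,
               tolerance = 1e-6)
})
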