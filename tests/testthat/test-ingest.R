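test_that("parse_ki_table maps fields, drops malformed rows, counts drops", {
  path <- write_tsv_fixture(c(
    "drug\treceptor\tspecies\tki_nM\tsource_id",
    "Clozapine\tDRD2\tHUMAN\t150\ts1",
    "clozapine\tHTR2A\thuman\t12.5\ts2",
    "olanzapine\tDRD2\trat\t30\ts3",
    "olanzapine\tHTR2A\thuman\t-3\ts4",     # non-positive Ki
    "quetiapine\tDRD2\thuman\tnot_a_number\ts5",
    "quetiapine\tHTR2A\thuman\t88\ts6",
    "risperidone\tDRD2\thuman\t5\ts7",
    "risperidone\tHTR2A\thuman\t0\ts8",     # zero Ki
    "haloperidol\tDRD2\thuman\t2\ts9",
    "haloperidol\tHTR2A\thuman\t60\ts10"))
  rec <- suppressMessages(parse_ki_table(path))
  expect_equal(nrow(rec), 7L)
  expect_equal(attr(rec, "n_dropped"), 3L)
  expect_equal(rec$drug[1], "clozapine")        # lowercased
  expect_equal(rec$species[1], "human")
  expect_equal(rec$ki_nM[1], 150)
  expect_error(parse_ki_table(tempfile()), "no such file")
  bad <- write_tsv_fixture(c("a\tb", "1\t2"))
  expect_error(parse_ki_table(bad), "schema")
})

test_that("parse_ki_table honours a custom column mapping and CSV input", {
  path <- write_tsv_fixture(
    c("ligand,target,organism,affinity_nm",
      "pimozide,DRD2,Human,1.2"), ext = ".csv")
  rec <- parse_ki_table(path, col_map = c(drug = "ligand", receptor = "target",
                                          species = "organism",
                                          ki_nM = "affinity_nm"))
  expect_equal(rec$drug, "pimozide")
  expect_equal(rec$ki_nM, 1.2)
  expect_true(is.na(rec$source_id))
})

test_that("filter_human keeps exactly the human records, case-insensitively", {
  rec <- make_records(c("a", "a", "b", "b"), c("r1", "r1", "r1", "r2"),
                      c(1, 2, 3, 4),
                      species = c("human", "rat", "HUMAN", " Human "))
  expect_equal(nrow(filter_human(rec)), 3L)
  all_rat <- make_records("a", "r1", 1, species = "rat")
  expect_equal(nrow(filter_human(all_rat)), 0L)
})

test_that("ki_to_pki follows the molar log identity and rejects bad input", {
  expect_equal(ki_to_pki(1), 9)
  expect_equal(ki_to_pki(100000), 4)        # 100 uM, the floor of the scale
  expect_equal(ki_to_pki(2512), 9 - log10(2512), tolerance = 1e-12)
  expect_equal(ki_to_pki(2512), 5.600, tolerance = 1e-3)
  expect_equal(ki_to_pki(1e-9, unit = "M"), 9)
  expect_error(ki_to_pki(0), "positive")
  expect_error(ki_to_pki(-5), "positive")
  # strictly decreasing in Ki
  ki <- sort(10^runif(50, -1, 5))
  expect_true(all(diff(ki_to_pki(ki)) < 0))
})

test_that("build_affinity_matrix aggregates replicates by median Ki", {
  rec <- make_records(rep("a", 3), rep("r1", 3), c(10, 100, 1000))
  m <- build_affinity_matrix(rec, min_drugs_per_receptor = 1,
                             min_receptors_per_drug = 1,
                             drop_constant = FALSE)
  expect_equal(unname(m$values["a", "r1"]), 7)   # median 100 nM -> pKi 7
  expect_equal(unname(m$provenance["a", "r1"]), 3L)
  # permutation invariance of record order
  m2 <- build_affinity_matrix(rec[c(3, 1, 2), ],
                              min_drugs_per_receptor = 1,
                              min_receptors_per_drug = 1,
                              drop_constant = FALSE)
  expect_identical(m$values, m2$values)
})

test_that("minimum-data filters remove sparse receptors then sparse drugs", {
  # 6 drugs x 6 receptors fully observed except receptor r6 observed for
  # only 4 drugs and drug d6 observed at only 4 receptors -> 5 x 5
  drugs <- paste0("d", 1:6); recs <- paste0("r", 1:6)
  grid <- expand.grid(drug = drugs, receptor = recs,
                      stringsAsFactors = FALSE)
  grid <- grid[!(grid$receptor == "r6" & grid$drug %in% c("d1", "d2")), ]
  grid <- grid[!(grid$drug == "d6" & grid$receptor %in% c("r4", "r5")), ]
  set.seed(1)
  rec <- make_records(grid$drug, grid$receptor, 10^runif(nrow(grid), 0, 3))
  m <- build_affinity_matrix(rec)
  expect_equal(dim(m$values), c(5L, 5L))
  expect_false("r6" %in% m$receptors)
  expect_false("d6" %in% m$drugs)
  # filter idempotence: re-filtering the retained cells changes nothing
  keep <- rec$drug %in% m$drugs & rec$receptor %in% m$receptors
  m3 <- build_affinity_matrix(rec[keep, ])
  expect_identical(m$values, m3$values)
})

test_that("constant receptor columns are removed", {
  drugs <- paste0("d", 1:5)
  rec <- rbind(
    make_records(drugs, "rconst", rep(50, 5)),
    make_records(rep(drugs, 5), rep(paste0("r", 1:5), each = 5),
                 10^runif(25, 0, 3)))
  m <- build_affinity_matrix(rec)
  expect_false("rconst" %in% m$receptors)
  expect_equal(ncol(m$values), 5L)
})

test_that("degenerate record sets raise errors", {
  expect_error(build_affinity_matrix(make_records(character(0),
                                                  character(0), numeric(0))),
               "no records")
  sparse <- make_records(c("a", "b"), c("r1", "r2"), c(1, 2))
  expect_error(build_affinity_matrix(sparse), "removed")
})

test_that("parse_clinical_table builds a masked profile with effect kinds", {
  eff <- names(clinical_effect_schema())
  hdr <- paste(c("drug", eff), collapse = "\t")
  row1 <- paste(c("clozapine", round(seq_len(16) / 4, 2)), collapse = "\t")
  vals2 <- as.character(round(seq_len(16) / 8, 2)); vals2[3] <- ""
  row2 <- paste(c("haloperidol", vals2), collapse = "\t")
  cp <- parse_clinical_table(write_tsv_fixture(c(hdr, row1, row2)))
  expect_s3_class(cp, "clinical_profile")
  expect_equal(dim(cp$scores), c(2L, 16L))
  expect_true(is.na(cp$scores["haloperidol", eff[3]]))
  expect_equal(sum(cp$effect_kind == "efficacy"), 3L)
  dup <- write_tsv_fixture(c("drug\tweight_gain", "a\t1", "a\t2"))
  expect_error(parse_clinical_table(dup), "duplicated")
  odd <- write_tsv_fixture(c("drug\tnot_an_effect", "a\t1"))
  expect_error(parse_clinical_table(odd, strict = TRUE), "schema")
  expect_silent(parse_clinical_table(odd))
})

test_that("parse_grouping counts categories and rejects duplicates", {
  p3 <- write_tsv_fixture(c("drug\tcategory",
                            paste0("d", 1:27, "\t",
                                   rep(c("typical", "atypical", "partial_agonist"),
                                       each = 9))))
  g <- parse_grouping(p3, "typical_atypical_pa")
  expect_equal(g$n_categories, 3L)
  expect_equal(length(g$assignment), 27L)
  p1 <- write_tsv_fixture(c("drug\tcategory", "a\tx", "b\tx"))
  expect_equal(parse_grouping(p1, "one")$n_categories, 1L)
  dup <- write_tsv_fixture(c("drug\tcategory", "a\tx", "a\ty"))
  expect_error(parse_grouping(dup, "dup"), "twice")
})

test_that("agonism tables validate modes", {
  expect_error(agonism_table("a", "r1", "inverse_agonist"), "unknown mode")
  at <- agonism_table(c("a", "b"), c("r1", "r2"),
                      c("agonist", "partial_agonist"))
  expect_equal(nrow(at), 2L)
})

test_that("affinity TSV export round-trips, with empty strings for missing", {
  v <- matrix(c(5, NA, 6.5, 7), 2, 2,
              dimnames = list(c("a", "b"), c("r1", "r2")))
  path <- tempfile(fileext = ".tsv")
  write_affinity_tsv(make_affinity(v), path)
  back <- apclust:::read_matrix_tsv(path)
  expect_equal(back, v)
  expect_true(any(grepl("\t\t|\t$", readLines(path))))  # empty field present
})
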