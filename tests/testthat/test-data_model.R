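test_that("lake reader validates and preserves row order", {
  path <- write_temp_csv(data.frame(
    lake_id = c("b", "a"), catchment = c("Po", "Rhône"),
    area_km2 = c(2.5, 1.0)), name = "lakes_ok.csv")
  lk <- read_lakes(path)
  expect_equal(lk$lake_id, c("b", "a"))
  expect_equal(lk$catchment, c("Po", "Rhone"))  # accent normalised
  expect_equal(lk$area_km2, c(2.5, 1.0))

  one <- read_lakes(write_temp_csv(data.frame(
    lake_id = "x", catchment = "Rhine", area_km2 = 1.0),
    name = "lakes_one.csv"))
  expect_equal(nrow(one), 1)
  expect_equal(one$area_km2, 1.0)
})

test_that("lake reader rejects bad tables with row-naming errors", {
  expect_error(read_lakes(write_temp_csv(data.frame(
    lake_id = "x", area_km2 = 1), name = "lakes_m.csv")),
    "missing required column")
  expect_error(read_lakes(write_temp_csv(data.frame(
    lake_id = c("ok", "zeroarea"), catchment = "Rhine",
    area_km2 = c(1, 0)), name = "lakes_z.csv")),
    "zeroarea")
  expect_error(read_lakes(write_temp_csv(data.frame(
    lake_id = c("dup", "dup"), catchment = "Rhine", area_km2 = 1),
    name = "lakes_d.csv")), "duplicate lake_id")
  expect_error(read_lakes(write_temp_csv(data.frame(
    lake_id = "x", catchment = "Amazon", area_km2 = 1),
    name = "lakes_c.csv")), "Amazon")
})

test_that("occurrence reader validates origins, duplicates and ids", {
  toy <- data.frame(
    lake_id = c("constance", "constance", "thun"),
    species_id = c("sp1", "alien1", "sp2"),
    origin = c("native", "introduced", "native"),
    extirpated = c("false", "false", "false"))
  occ <- read_occurrences(write_temp_csv(toy, name = "occ_ok.csv"),
    species = toy_species(), lakes = toy_lakes())
  expect_equal(as.vector(table(occ$origin)[c("native", "introduced")]),
    c(2L, 1L))
  expect_type(occ$extirpated, "logical")

  bad <- toy; bad$origin[2] <- "alien"
  expect_error(read_occurrences(write_temp_csv(bad, name = "occ_b.csv")),
    "native, translocated, introduced")
  dup <- rbind(toy, toy[1, ])
  expect_error(read_occurrences(write_temp_csv(dup, name = "occ_d.csv")),
    "duplicate record")
  ghost <- toy; ghost$species_id[1] <- "nothere"
  expect_error(read_occurrences(write_temp_csv(ghost, name = "occ_g.csv"),
    species = toy_species()), "nothere")
})

test_that("community metrics match hand counts on the toy archipelago", {
  met <- community_metrics(toy_occurrences(), toy_species(), toy_lakes())
  const <- met[met$lake_id == "constance", ]
  # 4 natives of which 1 single-lake endemic -> TNSR 4, PEnS 0.25
  expect_equal(const$tnsr, 4L)
  expect_equal(const$n_endemic, 1L)
  expect_equal(const$pens, 0.25)
  expect_equal(const$nssr, 2L)        # sp2 + end1 are native salmonids
  expect_equal(const$n_nonnative, 1L)
  expect_equal(const$n_extirpated, 1L)
  # lake with no occurrence rows gets all-zero metrics
  empty <- met[met$lake_id == "pond_a", ]
  expect_equal(unlist(empty[c("tnsr", "pens", "nssr", "richness")],
    use.names = FALSE), c(0, 0, 0, 0))
})

test_that("scenario richness identities hold lake-wise", {
  occ <- toy_occurrences(); lakes <- toy_lakes(); sp <- toy_species()
  rich <- function(sc) scenario_richness(occ, lakes, sc)$richness
  met <- community_metrics(occ, sp, lakes)
  expect_equal(rich("OC"), met$tnsr)
  expect_equal(rich("OC"), rich("OC_minus_Ext") + met$n_extirpated)
  expect_equal(rich("CC"),
    rich("OC") - met$n_extirpated +
      (met$n_nonnative - met$n_extirpated_nonnative))
  expect_true(all(rich("OC_plus_Int") >= rich("OC")))
  expect_true(all(rich("OC") >= rich("OC_minus_Ext")))
})

test_that("metrics are invariant to row order and survive a CSV round trip", {
  occ <- toy_occurrences(); lakes <- toy_lakes(); sp <- toy_species()
  met <- community_metrics(occ, sp, lakes)

  perm <- occ[rev(seq_len(nrow(occ))), ]
  expect_equal(community_metrics(perm, sp, lakes), met)

  dir <- file.path(tempdir(), "roundtrip")
  write_dataset_csv(list(lakes = lakes, species = sp, occurrences = occ), dir)
  lk2 <- read_lakes(file.path(dir, "lakes.csv"))
  sp2 <- read_species(file.path(dir, "species.csv"))
  oc2 <- read_occurrences(file.path(dir, "occurrences.csv"), sp2, lk2)
  expect_equal(community_metrics(oc2, sp2, lk2), met)
})

test_that("supplementary-sheet converter remaps columns and writes CSVs", {
  lakes_sheet <- write_temp_csv(data.frame(
    Lake = c("l1", "l2"), Basin = c("Rhine", "Po"),
    `Surface.area` = c(10, 2), check.names = FALSE),
    name = "sheet_lakes.csv")
  occ_sheet <- write_temp_csv(data.frame(
    Lake = c("l1", "l1", "l2"), Species = c("s1", "s2", "s1"),
    Status = c("native", "introduced", "native"),
    Family = c("Percidae", "Gobiidae", "Percidae")),
    name = "sheet_occ.csv")
  out <- file.path(tempdir(), "converted")
  ds <- convert_supplementary(lakes_sheet, occ_sheet, out,
    map = list(lake_id = "Lake", catchment = "Basin",
      area_km2 = "Surface.area", species_id = "Species",
      origin = "Status", family = "Family"))
  expect_true(all(file.exists(file.path(out,
    c("lakes.csv", "species.csv", "occurrences.csv")))))
  expect_equal(nrow(ds$lakes), 2)
  expect_equal(sort(unique(ds$occurrences$origin)),
    c("introduced", "native"))
  expect_equal(ds$species$pool_origin[ds$species$species_id == "s2"],
    "out_of_basin")
})
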