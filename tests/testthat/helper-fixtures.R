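# Small in-code fixtures shared across test files.

toy_lakes <- function() {
  validate_lakes(data.frame(
    lake_id = c("constance", "thun", "pond_a", "pond_b"),
    catchment = c("Rhine", "Rhine", "Po", "Danube"),
    area_km2 = c(536, 47.7, 1.2, 0.3),
    max_depth_m = c(251, 217, 8, 3),
    stringsAsFactors = FALSE))
}

toy_species <- function() {
  validate_species(data.frame(
    species_id = c("sp1", "sp2", "sp3", "sp4", "end1", "alien1"),
    family = c("Cyprinidae", "Salmonidae", "Percidae", "Salmonidae",
      "Salmonidae", "Centrarchidae"),
    endemism_class = c("none", "none", "none", "none", "single_lake",
      "none"),
    pool_origin = c(rep("in_basin", 5), "out_of_basin"),
    stringsAsFactors = FALSE))
}

# constance: 4 natives (one single-lake endemic), 1 extirpated native,
# 1 introduced; thun: 2 natives; pond_a: empty; pond_b: 1 native
toy_occurrences <- function() {
  validate_occurrences(data.frame(
    lake_id = c(rep("constance", 5), "thun", "thun", "pond_b"),
    species_id = c("sp1", "sp2", "sp3", "end1", "alien1", "sp2", "sp4",
      "sp1"),
    origin = c("native", "native", "native", "native", "introduced",
      "native", "native", "native"),
    extirpated = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE), species = toy_species(), lakes = toy_lakes())
}

write_temp_csv <- function(df, dir = tempdir(), name = "tmp.csv") {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}
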