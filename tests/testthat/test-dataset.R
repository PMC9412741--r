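test_that("build_manifest lists class-labeled folders and skips non-images", {
  td <- withr::local_tempdir()
  specs <- make_species_spec(6, 2)
  generate_dataset(specs, 3, file.path(td, "root"), seed = 2,
                   image_size = c(96, 128))
  writeLines("not an image", file.path(td, "root", "SYN01", "notes.txt"))
  expect_warning(man <- build_manifest(file.path(td, "root")), "skipping")
  expect_equal(nrow(man), 6)
  expect_equal(species_levels(man), c("SYN01", "SYN02"))
  expect_false(any(duplicated(man$image_id)))
  # masks are paired, not listed as images
  expect_true(all(!is.na(man$mask_path)))

  dir.create(file.path(td, "empty_root"))
  expect_error(build_manifest(file.path(td, "empty_root")),
               class = "elytra_malformed_dataset")
  dir.create(file.path(td, "root2", "SYNX"), recursive = TRUE)
  expect_error(suppressWarnings(build_manifest(file.path(td, "root2"))),
               class = "elytra_malformed_dataset")
})

test_that("blind split follows the 4:1 arithmetic and is deterministic", {
  man <- tibble::tibble(
    image_id = sprintf("im%03d", 1:60),
    species_id = rep(c("A", "B", "C"), each = 20))
  sp <- blind_split(man, 0.2, seed = 4)
  tab <- table(sp$species_id, sp$partition)
  expect_true(all(tab[, "test"] == 4))
  expect_true(all(tab[, "train"] == 16))
  expect_setequal(sp$image_id, man$image_id)
  expect_identical(sp, blind_split(man, 0.2, seed = 4))
  expect_false(identical(sp$partition, blind_split(man, 0.2, seed = 5)$partition))

  man5 <- tibble::tibble(image_id = sprintf("x%d", 1:5), species_id = "A")
  sp5 <- blind_split(man5, 0.2, seed = 1)
  expect_equal(sum(sp5$partition == "test"), 1)
  expect_equal(sum(sp5$partition == "train"), 4)

  man1 <- tibble::tibble(image_id = "only", species_id = "A")
  expect_error(blind_split(man1, 0.2, seed = 1), class = "elytra_invalid_dataset")
})

test_that("count-only arithmetic reproduces the study geometry", {
  man <- tibble::tibble(
    image_id = sprintf("im%04d", 1:540),
    species_id = rep(sprintf("SP%02d", 1:27), each = 20))
  counts <- count_split_tiles(blind_split(man, 0.2, seed = 9), 100)
  expect_equal(sum(counts$n_tiles[counts$partition == "test"]), 10800)
  expect_equal(sum(counts$n_tiles[counts$partition == "train"]), 43200)
  expect_equal(sum(counts$n_tiles), 540 * 100)
})

test_that("tile export is leak-free, conserves counts, and records exclusions", {
  td <- withr::local_tempdir()
  specs <- make_species_spec(8, 2)
  generate_dataset(specs, 4, file.path(td, "root"), seed = 3,
                   image_size = c(96, 128))
  # inject an all-white image that must fail border detection
  png::writePNG(array(1, c(96, 128, 3)), file.path(td, "root", "SYN01", "blank.png"))
  man <- build_manifest(file.path(td, "root"))
  expect_equal(nrow(man), 9)
  split <- blind_split(man, 0.25, seed = 7)
  ex <- export_split_tiles(man, split, file.path(td, "tiles"),
                           tiles_per_image = 5, tile_size = 32, seed = 11)
  expect_s3_class(ex$summary, "tbl_df")
  expect_equal(nrow(ex$exclusions), 1)
  expect_equal(ex$exclusions$image_id, "blank")
  # count conservation: exported + excluded*n = images*n
  expect_equal(nrow(ex$index) + nrow(ex$exclusions) * 5, 9 * 5)
  expect_true(assert_leak_free(ex))
  # tiles inherit the source image's partition
  joined <- merge(ex$index, split, by = "image_id")
  expect_true(all(joined$partition.x == joined$partition.y))
  # tile files exist under partition/species trees
  expect_true(all(file.exists(ex$index$path)))
  expect_true(file.exists(file.path(td, "tiles", "tile_index.csv")))
})

test_that("leak check trips on a contaminated index", {
  bad <- tibble::tibble(image_id = c("a", "a"), partition = c("train", "test"))
  expect_error(assert_leak_free(bad), class = "elytra_leak_error")
})
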