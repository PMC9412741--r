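test_that("species specs are deterministic in the seed and sensitive to it", {
  a <- make_species_spec(7, 3)
  b <- make_species_spec(7, 3)
  expect_identical(a, b)
  c1 <- make_species_spec(7, 1)
  c2 <- make_species_spec(8, 1)
  expect_true(any(unlist(c1[1, -1]) != unlist(c2[1, -1])))
  expect_error(make_species_spec(7, 0), class = "elytra_invalid_argument")
})

test_that("27 specs render pairwise-distinct textures", {
  specs <- make_species_spec(7, 27)
  expect_equal(length(unique(specs$species_id)), 27)
  imgs <- lapply(seq_len(27), function(s) {
    render_elytra_image(specs[s, ], variation_profile(), c(64, 96), seed = 1)$pixels
  })
  for (i in 1:26) {
    for (j in (i + 1):27) {
      expect_gt(mean(abs(imgs[[i]] - imgs[[j]])), 0)
    }
  }
})

test_that("rendering is a pure function of its arguments", {
  spec <- make_species_spec(3, 1)
  a <- render_elytra_image(spec, variation_profile(), c(96, 128), seed = 11)
  b <- render_elytra_image(spec, variation_profile(), c(96, 128), seed = 11)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$truth_mask, b$truth_mask)
  d <- render_elytra_image(spec, variation_profile(), c(96, 128), seed = 12)
  expect_gt(mean(abs(a$pixels - d$pixels)), 0)
})

test_that("rendered images satisfy the mask and background contracts", {
  specs <- make_species_spec(5, 3)
  for (s in 1:3) {
    img <- render_elytra_image(specs[s, ], variation_profile(), c(120, 160),
                               seed = s)
    bg <- img$pixels[, , 1][!img$truth_mask]
    expect_gte(mean(bg), 0.95)
    # single connected region
    lab <- EBImage::bwlabel(img$truth_mask * 1)
    expect_equal(max(lab), 1)
    # elytron darker than background
    expect_lt(mean(img$pixels[, , 1][img$truth_mask]), mean(bg))
  }
  expect_error(render_elytra_image(specs[1, ], variation_profile(), c(8, 8)),
               class = "elytra_invalid_argument")
})

test_that("the zero profile leaves the texture unchanged and modes act as documented", {
  spec <- make_species_spec(9, 1)
  base <- render_elytra_image(spec, variation_profile(0, 0, 0), c(160, 224), seed = 2)
  # variegation spreads local pattern contrast across the elytron
  vimg <- render_elytra_image(spec, variation_profile(variegation = 1),
                              c(160, 224), seed = 2)
  expect_gt(blockwise_contrast_sd(vimg), blockwise_contrast_sd(base))
  # fibrous background raises background variability
  fimg <- render_elytra_image(spec, variation_profile(background_fiber = 1),
                              c(160, 224), seed = 2)
  expect_gt(stats::sd(fimg$pixels[, , 1][!fimg$truth_mask]),
            stats::sd(base$pixels[, , 1][!base$truth_mask]))
  # maturity darkens the foreground
  mimg <- render_elytra_image(spec, variation_profile(maturity_darkening = 1),
                              c(160, 224), seed = 2)
  expect_lt(mean(mimg$pixels[, , 1][mimg$truth_mask]),
            mean(base$pixels[, , 1][base$truth_mask]))
})

test_that("inter-species texture distance exceeds intra-species distance", {
  set <- render_image_set(3, 2, seed = 21, image_size = c(120, 160))
  tiles <- harvest_tiles(set$images, tiles_per_image = 4, tile_size = 32, seed = 5)
  n <- dim(tiles$x)[4]
  dist_ij <- function(i, j) mean(abs(tiles$x[, , , i] - tiles$x[, , , j]))
  inter <- c(); intra <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (tiles$species[i] == tiles$species[j]) intra <- c(intra, dist_ij(i, j))
      else inter <- c(inter, dist_ij(i, j))
    }
  }
  expect_gt(mean(inter), mean(intra))
})

test_that("generate_dataset writes the expected records and is byte-reproducible", {
  td <- withr::local_tempdir()
  specs <- make_species_spec(2, 2)
  man <- generate_dataset(specs, 3, file.path(td, "a"), seed = 5,
                          image_size = c(96, 128))
  expect_equal(nrow(man), 6)
  expect_equal(length(unique(man$species_id)), 2)
  expect_true(all(file.exists(man$path)))
  expect_true(all(file.exists(man$mask_path)))
  # single spec, single image
  man1 <- generate_dataset(specs[1, ], 1, file.path(td, "b"), seed = 5,
                           image_size = c(96, 128))
  expect_equal(nrow(man1), 1)
  # same seed twice: byte-identical files
  man2 <- generate_dataset(specs, 3, file.path(td, "c"), seed = 5,
                           image_size = c(96, 128))
  expect_identical(unname(tools::md5sum(man$path)),
                   unname(tools::md5sum(man2$path)))
})
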