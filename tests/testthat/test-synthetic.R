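test_that("degenerate parameters give a constant image", {
  p <- tissue_params("Cartilage", noise_sd = 0, lacuna_spacing = Inf,
                     lacuna_radius_range = c(0, 0), base_intensity = 100)
  img <- gen_cartilage_image(128, p, seed = 1)
  # the low-frequency field is the only variation left; it is bounded at 8%
  px <- img$pixels
  expect_lte(diff(range(px)), ceiling(2 * 0.08 * 100) + 1)
  pb <- tissue_params("Bone", noise_sd = 0, fiber_count = 0)
  expect_lte(diff(range(gen_bone_image(128, pb, seed = 1)$pixels)),
             ceiling(2 * 0.08 * 90) + 1)
})

test_that("generation is byte-identical per seed and varies across seeds", {
  a <- gen_cartilage_image(256, seed = 5)
  b <- gen_cartilage_image(256, seed = 5)
  c <- gen_cartilage_image(256, seed = 6)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, c$pixels))
  # same summary statistics within tolerance across seeds
  expect_lt(abs(mean(a$pixels) - mean(c$pixels)), 5)
  expect_lt(abs(sd(a$pixels) - sd(c$pixels)), 5)
})

test_that("lacuna coverage tracks the analytic area fraction", {
  p <- tissue_params("Cartilage")
  fracs <- sapply(1:5, function(s)
    mean(attr(gen_cartilage_image(512, p, seed = s), "lacuna_mask")))
  # jittered lattice: (512 / 60)^2 sites-ish, mean ellipse area
  # pi * E[a] * E[b] with a ~ U(8, 14), b = a * U(0.7, 1)
  n_sites <- length(seq(30, 512, by = 60))^2
  ea <- mean(c(8, 14)); eab <- (8^2 + 8 * 14 + 14^2) / 3 * mean(c(0.7, 1))
  expected <- n_sites * pi * eab / 512^2
  expect_lt(abs(mean(fracs) - expected) / expected, 0.2)
  # dark pixels in the mask really are near zero
  img <- gen_cartilage_image(512, p, seed = 1)
  expect_lt(mean(img$pixels[attr(img, "lacuna_mask")]), 10)
})

test_that("bone is brighter than cartilage and less homogeneous", {
  bone <- gen_bone_image(512, seed = 8)
  cart <- gen_cartilage_image(512, seed = 8)
  expect_gt(mean(bone$pixels), mean(cart$pixels))
  mean_asm <- function(img) {
    f <- sapply(extract_patches(img, grid_step = 64), function(pt)
      mean(roi_param_map(pt, "asm", 0)))
    mean(f)
  }
  expect_lt(mean_asm(bone), mean_asm(cart))
})

test_that("aligned fibers make contrast anisotropic", {
  # horizontal fibers (band mode fixes orientation at 0 degrees):
  # contrast along the fibers (theta = 0) < across them (theta = 90)
  p <- tissue_params("Bone", fiber_orientation_spread = 0, noise_sd = 0,
                     band_fraction = 0.99)
  img <- gen_bone_image(256, p, seed = 3)
  con <- function(theta) {
    mean(sapply(extract_patches(img, grid_step = 64), function(pt)
      mean(roi_param_map(pt, "contrast", theta))))
  }
  expect_lt(con(0), con(90))
})

test_that("fibrous images confine fibers to the surface band", {
  p <- tissue_params("Fibrous", noise_sd = 0, lacuna_spacing = Inf,
                     lacuna_radius_range = c(0, 0))
  img <- gen_fibrous_image(256, p, seed = 4)
  band <- round(256 * p$band_fraction)
  base <- tissue_params("Cartilage", noise_sd = 0, lacuna_spacing = Inf,
                        lacuna_radius_range = c(0, 0))$base_intensity
  top <- img$pixels[1:band, ]
  bottom <- img$pixels[(band + 10):256, ]
  expect_gt(mean(top), mean(bottom))         # bright fibers in the band
  expect_lt(max(bottom), base * 1.1 + 2)     # none below it
})

test_that("gen_dataset writes files, manifest, and round-trips", {
  dir <- withr::local_tempdir()
  ds <- gen_dataset(3, c("Cartilage", "Bone"), size = 128, seed = 12,
                    dir = dir)
  expect_length(ds$images, 6)
  expect_equal(as.vector(table(ds$labels)), c(3, 3))
  expect_equal(nrow(ds$manifest), 6)
  expect_setequal(list.files(dir, pattern = "\\.tif$"),
                  paste0(ds$ids, ".tif"))
  back <- load_dataset(dir)
  expect_equal(back$labels, ds$labels)
  for (i in seq_along(ds$images))
    expect_identical(back$images[[i]]$pixels, ds$images[[i]]$pixels)
  # regeneration from the same master seed is identical
  ds2 <- gen_dataset(3, c("Cartilage", "Bone"), size = 128, seed = 12)
  expect_identical(ds2$images[[4]]$pixels, ds$images[[4]]$pixels)
})

test_that("default images pass the signal filters nearly everywhere", {
  ds <- gen_dataset(2, c("Cartilage", "Bone", "Fibrous"), size = 256,
                    seed = 15)
  patches <- unlist(lapply(ds$images, extract_patches, grid_step = 64),
                    recursive = FALSE)
  kept <- filter_signal_patches(patches)
  expect_gt(length(kept) / length(patches), 0.95)
  expect_length(filter_signal_images(ds$images), length(ds$images))
})

test_that("class ASM / contrast distributions separate at alpha = 0.01", {
  # precondition for the classification benchmarks: per-patch means of the
  # texture parameters differ between classes under the default generator
  ds <- fixture_dataset("mini2", 4, c("Cartilage", "Bone"), size = 192,
                        seed = 77)
  patch_stat <- function(img, param) {
    sapply(extract_patches(img, grid_step = 64), function(pt)
      mean(roi_param_map(pt, param, 0)))
  }
  asm_c <- unlist(lapply(ds$images[ds$labels == "Cartilage"], patch_stat,
                         "asm"))
  asm_b <- unlist(lapply(ds$images[ds$labels == "Bone"], patch_stat, "asm"))
  expect_lt(wilcox.test(asm_c, asm_b, exact = FALSE)$p.value, 0.01)
  con_c <- unlist(lapply(ds$images[ds$labels == "Cartilage"], patch_stat,
                         "contrast"))
  con_b <- unlist(lapply(ds$images[ds$labels == "Bone"], patch_stat,
                         "contrast"))
  expect_lt(wilcox.test(con_c, con_b, exact = FALSE)$p.value, 0.01)
})

test_that("invalid geometry is rejected", {
  expect_error(tissue_params("Cartilage", lacuna_spacing = 20,
                             lacuna_radius_range = c(8, 14)),
               class = "shgbof_invalid_parameter")
  expect_error(tissue_params("Cartilage", base_intensity = 300),
               class = "shgbof_invalid_parameter")
})
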