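test_that("phantom generation is deterministic and covers every class", {
  spec <- phantom_spec(image_size = 48, n_organs = 4)
  a <- generate_phantom(spec, seed = 11)
  b <- generate_phantom(spec, seed = 11)
  expect_identical(a, b)
  expect_identical(sort(unique(as.vector(a$label))), 0:4)
  expect_true(all(a$image >= 0 & a$image <= 1))
  c3 <- generate_phantom(phantom_spec(image_size = 48, n_organs = 3),
                         seed = 5)
  expect_identical(sort(unique(as.vector(c3$label))), 0:3)
  expect_error(phantom_spec(n_organs = 2), "3..8")
  expect_error(
    generate_phantom(phantom_spec(image_size = 24,
                                  organ_axis_frac = c(0.45, 0.49)), 1),
    "generation failed")
})

test_that("noiseless rendering is inverted exactly by intensity thresholding", {
  spec <- phantom_spec(image_size = 48, n_organs = 4, organ_texture_sd = 0,
                       noise_sd = 0)
  ph <- generate_phantom(spec, seed = 21)
  expect_identical(oracle_segmenter(ph$image, spec), ph$label)
  r <- evaluate_case(oracle_segmenter(ph$image, spec), ph$label, 5L)
  expect_equal(r$mean_dsc, 1)
})

test_that("mean visible organ fraction stays inside the spec's size band", {
  spec <- phantom_spec(image_size = 48, n_organs = 4)
  fracs <- matrix(0, 200, 4)
  for (i in 1:200) {
    lab <- generate_phantom(spec, seed = 1000 + i)$label
    for (k in 1:4) fracs[i, k] <- mean(lab == k)
  }
  lo <- pi * spec$organ_axis_frac[1]^2 * 0.8
  hi <- pi * spec$organ_axis_frac[2]^2 * 1.2
  m <- colMeans(fracs)
  expect_true(all(m >= lo & m <= hi))
})

test_that("augmentation applies paired transforms and keeps labels closed", {
  spec48 <- phantom_spec(image_size = 48)
  ph <- generate_phantom(spec48, seed = 31)
  # no flips, zero rotation: exact identity
  id_spec <- augment_spec(p_hflip = 0, p_vflip = 0, rotation_deg = c(0, 0))
  out <- augment(ph$image, ph$label, id_spec, seed = 1)
  expect_identical(out$image, ph$image)
  expect_identical(out$label, ph$label)
  # a certain horizontal flip applied twice is the identity
  hf <- augment_spec(p_hflip = 1, p_vflip = 0, rotation_deg = c(0, 0))
  once <- augment(ph$image, ph$label, hf, seed = 2)
  expect_false(identical(once$label, ph$label))
  twice <- augment(once$image, once$label, hf, seed = 3)
  expect_identical(twice$image, ph$image)
  expect_identical(twice$label, ph$label)
  # asymmetric ranges are rejected
  expect_error(augment_spec(rotation_deg = c(-5, 10)), "symmetric")
  # nearest-neighbour labels never invent classes (100 seeds)
  cls <- sort(unique(as.vector(ph$label)))
  for (s in 1:100) {
    aug <- augment(ph$image, ph$label, augment_spec(), seed = s)
    expect_true(all(unique(as.vector(aug$label)) %in% c(0L, cls)))
    expect_identical(dim(aug$image), dim(ph$image))
  }
})

test_that("datasets round-trip through the manifest, PNGs and RDS bundle", {
  dir <- file.path(tempdir(), "ds10")
  unlink(dir, recursive = TRUE)
  spec <- phantom_spec(image_size = 32, n_organs = 3)
  man <- make_dataset(10, spec, seed = 9, out_dir = dir)
  expect_identical(length(man$items), 10L)
  splits <- vapply(man$items, function(it) it$split, "")
  expect_identical(as.vector(table(factor(splits,
                                          c("train", "val", "test")))),
                   c(7L, 1L, 2L))
  # RDS path is exact
  ds <- read_dataset(dir, exact = TRUE)
  ph1 <- generate_phantom(spec, man$items[[1]]$seed)
  expect_identical(ds$images[[1]], ph1$image)
  expect_identical(ds$labels[[1]], ph1$label)
  # PNG path: labels lossless, images exact at 8-bit quantisation
  dp <- read_dataset(dir, exact = FALSE)
  expect_identical(dp$labels[[1]], ph1$label)
  expect_lt(max(abs(dp$images[[1]] - ph1$image)), 1 / 255)
  # regeneration reproduces identical files
  dir2 <- file.path(tempdir(), "ds10b")
  unlink(dir2, recursive = TRUE)
  make_dataset(10, spec, seed = 9, out_dir = dir2)
  expect_identical(readRDS(file.path(dir, "bundle.rds")),
                   readRDS(file.path(dir2, "bundle.rds")))
  # split filter
  tr <- read_dataset(dir, split = "train")
  expect_identical(length(tr$images), 7L)
})
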