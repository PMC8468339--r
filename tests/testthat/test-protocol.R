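minimal_doc <- function(...) {
  list(name = "doc", entries = list(list(
    name = "e1",
    geometry = list(orientation = "axial", matrix = 32, fov = 200,
                    thickness = 7),
    sequence = list(family = "SE", te = 20, tr = 500), ...)))
}

test_that("a minimal protocol document resolves with documented defaults", {
  p <- validate_protocol(minimal_doc())
  expect_s3_class(p, "mri_protocol")
  e <- p$entries[[1]]
  expect_equal(e$geometry$n_slices, 1L)
  expect_equal(e$geometry$phase_oversampling, 1)
  expect_equal(e$geometry$slice_separation, 7)
  expect_equal(e$sequence$family, "SE")
  expect_equal(e$artifacts$thermal_sigma, 0)
  expect_equal(p$coil$kind, "homogeneous")
})

test_that("protocol problems come back as an itemized error list", {
  doc <- minimal_doc()
  doc$entries[[1]]$sequence$te <- 600      # te >= tr
  errs <- validate_protocol(doc)
  expect_s3_class(errs, "protocol_errors")
  expect_match(errs, "entries\\[1\\].sequence", all = FALSE)
  expect_match(errs, "tr .* must exceed te", all = FALSE)

  doc2 <- minimal_doc()
  doc2$entries[[1]]$sequence$family <- "TURBOFLASH"
  errs2 <- validate_protocol(doc2)
  expect_length(errs2, 1L)
  expect_match(errs2, "allowed: SE, FSE, GRE_SPOILED, IR_SE")

  expect_s3_class(validate_protocol(list(name = "empty")), "protocol_errors")
})

test_that("protocol JSON files round-trip through validation", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(minimal_doc(), f, auto_unbox = TRUE)
  p <- validate_protocol(f)
  expect_s3_class(p, "mri_protocol")
  expect_equal(p$entries[[1]]$name, "e1")
})

test_that("an artifact-free SE scan of a homogeneous phantom is flat", {
  m <- uniform_phantom(pd = 0.9, t1 = 800, t2 = 90)
  g <- simple_geometry(nf = 32, np = 32, fov = 120)
  prot <- mri_protocol("flat", list(list(
    name = "se", geometry = g,
    sequence = sequence_params("SE", te = 15, tr = 600))))
  img <- run_protocol(m, prot, seed = 1)$images$se[, , 1]
  interior <- img[8:24, 8:24]
  expect_lt(diff(range(interior)) / mean(interior), 1e-6)
  expected <- signal_se(0.9, 800, 90, 15, 600)
  expect_equal(mean(interior), expected, tolerance = 1e-6)
})

test_that("identical model, protocol and seed give bit-identical sessions", {
  m <- two_tissue_phantom(dim = c(16, 16, 16))
  g <- simple_geometry(nf = 24, np = 24, fov = 120)
  prot <- mri_protocol("noisy", list(list(
    name = "se", geometry = g,
    sequence = sequence_params("SE", te = 15, tr = 600),
    artifacts = artifact_config(thermal_sigma = 0.05,
                                motion = list(amplitude_mm = 1,
                                              period_lines = 4)))))
  s1 <- run_protocol(m, prot, seed = 9)
  s2 <- run_protocol(m, prot, seed = 9)
  expect_identical(s1$images, s2$images)
  s3 <- run_protocol(m, prot, seed = 10)
  expect_false(identical(s1$images, s3$images))
})

test_that("TE weighting separates long- and short-T2 tissues", {
  m <- two_tissue_phantom()          # outer t2 = 90, inner t2 = 2000
  g <- simple_geometry(nf = 32, np = 32, fov = 220)
  prot <- mri_protocol("tes", list(
    list(name = "te20", geometry = g,
         sequence = sequence_params("SE", te = 20, tr = 3000)),
    list(name = "te100", geometry = g,
         sequence = sequence_params("SE", te = 100, tr = 3000))))
  s <- run_protocol(m, prot, seed = 1)
  rs <- reslice(m, g)
  lab <- rs$slices[[1]]$labels
  ratio <- function(l) {
    sel <- lab == l & rs$slices[[1]]$pd > 0.5
    mean(s$images$te100[, , 1][sel]) / mean(s$images$te20[, , 1][sel])
  }
  expect_gt(ratio(2), ratio(1))      # long-T2 core retains more signal
  # oracle: the closed-form signal ratios
  expect_equal(ratio(2), signal_se(1, 4000, 2000, 100, 3000) /
                 signal_se(1, 4000, 2000, 20, 3000), tolerance = 0.05)
})

test_that("stage errors surface with the entry name", {
  m <- uniform_phantom(dim = c(16, 16, 16))
  g <- simple_geometry(nf = 16, np = 16, fov = 100)
  bad <- mri_protocol("bad", list(list(
    name = "broken", geometry = g,
    sequence = sequence_params("SE", te = 15, tr = 600),
    artifacts = artifact_config(spikes = list(list(location = c(99, 0),
                                                   amplitude = 1))))))
  expect_error(run_protocol(m, bad, seed = 1), "entry 'broken'")
})

test_that("written sessions carry the plan's spatial metadata", {
  m <- uniform_phantom(dim = c(16, 16, 16))
  g <- simple_geometry(nf = 16, np = 16, fov = 100, n_slices = 3)
  prot <- mri_protocol("io", list(list(
    name = "se", geometry = g,
    sequence = sequence_params("SE", te = 15, tr = 600))))
  s <- run_protocol(m, prot, seed = 1)
  d <- withr::local_tempdir()
  write_session(s, d, dump_kspace = TRUE)
  expect_true(file.exists(file.path(d, "se.nii.gz")))
  expect_true(file.exists(file.path(d, "provenance.json")))
  expect_true(file.exists(file.path(d, "se_kspace_slice02.txt")))
  img <- RNifti::readNifti(file.path(d, "se.nii.gz"))
  expect_equal(dim(img), c(16L, 16L, 3L))
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  expect_equal(unname(sqrt(colSums(aff[1:3, 1:3]^2))), c(100 / 16, 100 / 16, 5),
               tolerance = 1e-6)
  prov <- jsonlite::read_json(file.path(d, "provenance.json"))
  expect_equal(prov$seed, 1L)
})

test_that("a routine multi-slice scan completes at interactive speed", {
  m <- head_phantom(dim = c(32, 32, 32), spacing = c(7, 7, 7))
  g <- canonical_plan("axial", m, matrix = 256, fov = 240, thickness = 5,
                      n_slices = 10)
  prot <- mri_protocol("perf", list(list(
    name = "se", geometry = g,
    sequence = sequence_params("SE", te = 15, tr = 500))))
  elapsed <- system.time(run_protocol(m, prot, seed = 1))["elapsed"]
  expect_lt(elapsed, 6)    # soft bound around the ~2 s interactive design target
})
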