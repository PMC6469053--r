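test_that("stack generation is deterministic given the seed", {
  s1 <- generate_stack(stack_gen_spec(seed = 5))
  s2 <- generate_stack(stack_gen_spec(seed = 5))
  s3 <- generate_stack(stack_gen_spec(seed = 6))
  expect_identical(s1$sections, s2$sections)
  expect_false(identical(s1$sections, s3$sections))
  ## spacing is exactly 0.5 mm and indices strictly increasing
  z <- unique(s1$sections[, c("section", "z")])
  expect_true(all(diff(z$section) == 1))
  expect_close(diff(z$z), rep(0.5, nrow(z) - 1), 1e-12)
})

test_that("landmark ordering in the generator spec is enforced", {
  expect_error(stack_gen_spec(crista_index = 23, tibial_trough_index = 15,
                              fibular_trough_index = 31),
               class = "mpsjc_spec_error")
})

test_that("a noiseless stack yields exact landmark sections and round-trips", {
  st <- generate_stack(stack_gen_spec(noise_sigma = 0, seed = 1))
  ## crista section fits a circle essentially exactly
  pts <- as.matrix(st$sections[st$sections$section == 23, c("x", "y")])
  f <- fit_circle(pts)
  expect_lt(f$rms_residual, 1e-9)
  expect_close(f$radius, 11, 1e-9)
  lm <- locate_landmarks(st)
  expect_identical(lm$crista_index, 23L)
  expect_identical(lm$tibial_trough_index, 31L)
  expect_identical(lm$fibular_trough_index, 15L)
})

test_that("landmarks are recovered at the default noise level", {
  st <- generate_stack(stack_gen_spec(seed = 11))
  lm <- locate_landmarks(st)
  expect_identical(lm$crista_index, 23L)
  expect_identical(lm$tibial_trough_index, 31L)
  expect_identical(lm$fibular_trough_index, 15L)
})

test_that("a sphere stack without grooves reports missing landmarks", {
  st <- generate_stack(stack_gen_spec(tibial_flattening = 0,
                                      fibular_flattening = 0, seed = 2))
  expect_error(locate_landmarks(st), class = "mpsjc_missing_landmark")
})

test_that("landmark recovery accuracy does not improve with more noise", {
  sig_levels <- c(0, 0.0025, 0.005, 0.01) * 11
  n_seeds <- 8
  errs <- vapply(sig_levels, function(sig) {
    tot <- 0
    for (s in seq_len(n_seeds)) {
      st <- generate_stack(stack_gen_spec(noise_sigma = sig, seed = 100 + s))
      lm <- tryCatch(locate_landmarks(st), error = function(e) NULL)
      tot <- tot + if (is.null(lm)) 10 else {
        abs(lm$crista_index - 23) + abs(lm$tibial_trough_index - 31) +
          abs(lm$fibular_trough_index - 15)
      }
    }
    tot
  }, numeric(1))
  ## total landmark error is non-decreasing in noise, up to small ties
  expect_true(all(diff(errs) >= -1))
})

test_that("stack_to_model recovers the head radius within 1%", {
  for (s in c(3, 13)) {
    st <- generate_stack(stack_gen_spec(seed = s))
    rec <- stack_to_model(st)
    expect_lt(abs(rec$crista_fit$radius - 11) / 11, 0.01)
    expect_identical(nrow(validate_model(recovered_joint_model(rec))), 0L)
  }
})

test_that("a noiseless stack reconstructs the generating geometry closely", {
  st <- generate_stack(stack_gen_spec(noise_sigma = 0, seed = 1))
  rec <- stack_to_model(st)
  expect_lt(abs(rec$crista_fit$radius - 11), 1e-6)
  ## trough planes: fitted profiles reproduce the section contours
  expect_lt(rec$tibial_fit$rms_residual, 5e-3)
  expect_lt(rec$fibular_fit$rms_residual, 5e-3)
  ## trough sits on the correct side of each groove (tibial proximal,
  ## fibular distal)
  expect_lt(rec$tibial_fit$trough_frac, 0.5)
  expect_gt(rec$fibular_fit$trough_frac, 0.5)
})

test_that("recovered models reproduce the generating shift directions", {
  hits <- 0; n_seeds <- 6
  for (s in seq_len(n_seeds)) {
    res <- tryCatch({
      st <- generate_stack(stack_gen_spec(seed = 300 + s))
      rec <- stack_to_model(st)
      m <- recovered_joint_model(rec)
      sw <- sweep_joint(m, sweep_spec(15, 70, 60, warn = FALSE))
      classify_shift(sw, "tibial")$direction == "proximal" &&
        classify_shift(sw, "fibular")$direction == "distal"
    }, error = function(e) FALSE)
    if (isTRUE(res)) hits <- hits + 1
  }
  expect_gte(hits, n_seeds - 1)
})

test_that("stacks round-trip through per-section CSV files", {
  st <- generate_stack(stack_gen_spec(n_sections = 10, crista_index = 5,
                                      tibial_trough_index = 8,
                                      fibular_trough_index = 2, seed = 4))
  dir <- tempfile("stack")
  write_stack_csv(st, dir)
  st2 <- read_stack_csv(dir)
  expect_identical(sort(unique(st2$sections$section)),
                   sort(unique(st$sections$section)))
  a <- st$sections[st$sections$section == 5, c("x", "y")]
  b <- st2$sections[st2$sections$section == 5, c("x", "y")]
  expect_lt(max(abs(as.matrix(a) - as.matrix(b))), 1e-6)
  unlink(dir, recursive = TRUE)
})
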