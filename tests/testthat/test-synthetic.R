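# Synthetic stack generator: texture contracts, stack assembly, cohorts.

small_spec <- function(seed = 1, ...) {
  synthetic_stack_spec(width_px = 80, height_px = 80,
                       thicknesses = c(SC = 3, VE = 4, DEJ = 3, PD = 3),
                       rng_seed = seed, ...)
}

test_that("stratum textures carry their diagnostic structure", {
  spec <- small_spec()
  # viable epidermis: bright honeycomb borders over dark cell interiors
  ve <- with_seed(70, render_stratum_texture("VE", spec, return_masks = TRUE))
  m <- attr(ve, "masks")
  expect_gt(mean(ve[m$border]) - mean(ve[m$interior]), 0.2)
  # dermal-epidermal junction: bright papilla annuli around dark centres
  dej <- with_seed(71, render_stratum_texture("DEJ", spec, return_masks = TRUE))
  md <- attr(dej, "masks")
  expect_gt(mean(dej[md$annulus]), mean(dej[md$disc_centre]))
  # all textures live in [0, 1]
  for (st in strata_levels()) {
    img <- with_seed(72, render_stratum_texture(st, spec))
    expect_true(all(img >= 0 & img <= 1))
    expect_equal(dim(img), c(80, 80))
  }
  expect_error(render_stratum_texture("XX", spec), "unknown stratum")
})

test_that("stack generation is seeded with known labels and interfaces", {
  spec <- synthetic_stack_spec(width_px = 64, height_px = 64,
                               thicknesses = c(10, 15, 12, 13), rng_seed = 3)
  g <- generate_stack(spec)
  expect_equal(n_sections(g$stack), 50)
  expect_equal(unclass(g$interfaces),
               c(sc_ve_um = 20, ve_dej_um = 50, dej_pd_um = 74))
  expect_equal(as.character(g$labels$stratum),
               rep(c("SC", "VE", "DEJ", "PD"), times = c(10, 15, 12, 13)))
  expect_false(is.unsorted(as.integer(g$labels$stratum)))

  # determinism and seed sensitivity (pixels differ, labels identical)
  g2 <- generate_stack(spec)
  expect_identical(g$stack$sections, g2$stack$sections)
  spec9 <- synthetic_stack_spec(width_px = 64, height_px = 64,
                                thicknesses = c(10, 15, 12, 13), rng_seed = 9)
  g3 <- generate_stack(spec9)
  expect_false(identical(g$stack$sections[[1]], g3$stack$sections[[1]]))
  expect_equal(as.character(g3$labels$stratum), as.character(g$labels$stratum))

  expect_error(synthetic_stack_spec(thicknesses = c(0, 5, 5, 5)), ">= 1")
})

test_that("furrows mix deeper-stratum texture into superficial sections", {
  base <- small_spec(seed = 5)
  furrowed <- small_spec(seed = 5, furrow_depth_sections = 4)
  gb <- generate_stack(base)
  gf <- generate_stack(furrowed)
  # labels unchanged; pixel content differs near interfaces
  expect_equal(as.character(gf$labels$stratum), as.character(gb$labels$stratum))
  sec_near_interface <- 2  # SC section 2 sections above the SC/VE interface
  expect_false(identical(gf$stack$sections[[sec_near_interface + 1]],
                         gb$stack$sections[[sec_near_interface + 1]]))
})

test_that("cohorts share parameters within participants and expose metadata", {
  coh <- generate_cohort(10, stacks_per_participant = 2, rng_seed = 6,
                         width_px = 48, height_px = 48,
                         spec_ranges = list(sc_thickness = c(2, 4),
                                            ve_thickness = c(2, 4),
                                            dej_thickness = c(2, 4),
                                            pd_thickness = c(2, 4)))
  expect_length(coh$stacks, 20)
  expect_equal(length(unique(coh$metadata$participant_id)), 10)
  expect_equal(sort(unique(coh$metadata$body_site)), c("dorsal", "volar"))
  # both of a participant's stacks share thicknesses (participant-level draw)
  for (pid in unique(coh$metadata$participant_id)) {
    sids <- coh$metadata$stack_id[coh$metadata$participant_id == pid]
    ints <- coh$interfaces[match(sids, coh$interfaces$stack_id), -1]
    expect_equal(ints[1, ], ints[2, ], ignore_attr = TRUE)
  }
  # degenerate ranges pin every stack to the same thicknesses
  fixed <- generate_cohort(3, 1, rng_seed = 2, width_px = 48, height_px = 48,
                           spec_ranges = list(sc_thickness = c(3, 3),
                                              ve_thickness = c(3, 3),
                                              dej_thickness = c(3, 3),
                                              pd_thickness = c(3, 3)))
  expect_equal(unique(fixed$interfaces$sc_ve_um), 6)
  expect_true(all(vapply(fixed$stacks, n_sections, integer(1)) == 12))

  # holdout on the cohort yields disjoint participant sets
  sp <- holdout_split(coh$metadata$participant_id, coh$metadata$age_group,
                      c("20-30" = 2, "50-70" = 2), rng_seed = 1)
  expect_length(intersect(sp$train, sp$test), 0)

  expect_error(generate_cohort(1, 1), "at least 2")
  expect_error(generate_cohort(4, 1, spec_ranges = list(sc_thickness = c(5, 2))),
               "invalid range")
})

test_that("the four strata produce distinguishable mean encodings", {
  # measured at the generator's native working scale (250 px) with a
  # vocabulary adequate to the texture diversity (2 x 10 = 100 words);
  # low-contrast background patches spread uniformly over the vocabulary,
  # so their shared contribution to the class means dilutes as K grows
  stacks <- list(); labels <- list(); x <- NULL; y <- NULL
  for (s in 1:3) {
    g <- generate_stack(
      synthetic_stack_spec(thicknesses = c(4, 4, 4, 4), rng_seed = 100 + s),
      stack_id = paste0("s", s), participant_id = paste0("p", s))
    stacks[[g$stack$stack_id]] <- g$stack
    labels[[s]] <- g$labels
  }
  labels <- do.call(rbind, labels)
  pool <- with_seed(110, do.call(rbind, lapply(stacks, function(stk) {
    do.call(rbind, lapply(stk$sections, extract_random_patches,
                          n_patches = 100, patch_size = 7, rng_seed = NULL))
  })))
  pool <- normalize_patches(pool, 1)
  wm <- fit_whitening(pool)
  dict <- learn_dictionary(apply_whitening(wm, pool), n_levels = 2,
                           n_splits = 10, rng_seed = 111)
  for (sid in names(stacks)) {
    e <- encode_stack(stacks[[sid]], wm, dict, stride = 2, pool = TRUE)
    lab <- labels[labels$stack_id == sid, ]
    x <- rbind(x, e$x)
    y <- c(y, as.character(lab$stratum[match(e$meta$section_index,
                                             lab$section_index)]))
  }
  means <- t(vapply(strata_levels(),
                    function(s) colMeans(x[y == s, , drop = FALSE]),
                    numeric(ncol(x))))
  means <- means / sqrt(rowSums(means^2))
  cosims <- means %*% t(means)
  expect_lt(max(cosims[upper.tri(cosims)]), 0.95)
})
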