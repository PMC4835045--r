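# Seeded synthetic RCM-like depth stacks. Each stratum gets a simple
# parametric texture echoing its clinical appearance — bright corneum
# speckle, keratinocyte honeycomb, papillae rings, fibrillar dermis — so the
# whole pipeline can be exercised end to end with known labels and known
# interface depths. The goal is pipeline verification, not photorealism.

#' Specification of one synthetic depth stack
#'
#' @param width_px,height_px section size in pixels (default 250x250, the
#'   working scale of the pipeline; use 1000x1000 to exercise the
#'   down-sampling path).
#' @param spacing_um vertical section spacing in micrometres (default 2).
#' @param thicknesses integer section counts per stratum in order SC, VE,
#'   DEJ, PD (each >= 1); their sum is the stack length.
#' @param noise_sigma standard deviation of additive Gaussian pixel noise.
#' @param furrow_depth_sections if positive, a localized furrow region shows
#'   the texture of the stratum this many sections deeper, emulating skin
#'   furrows that push deeper strata into superficial sections (0 = none).
#' @param cell_diameter_px honeycomb cell diameter of the viable epidermis.
#' @param papilla_radius_px,n_papillae radius and number of dermal papillae
#'   rings at the dermal-epidermal junction.
#' @param fibril_wavelength_px,fibril_orientation_deg,fibril_angle_bw
#'   wavelength, dominant orientation and angular bandwidth (radians) of the
#'   papillary-dermis fibrillar texture.
#' @param speckle_grain_px grain size of the stratum corneum speckle.
#' @param rng_seed seed making the stack reproducible.
#' @return Object of class `synthetic_stack_spec`.
#' @export
synthetic_stack_spec <- function(width_px = 250, height_px = 250,
                                 spacing_um = 2,
                                 thicknesses = c(SC = 10, VE = 15,
                                                 DEJ = 12, PD = 13),
                                 noise_sigma = 0.05,
                                 furrow_depth_sections = 0,
                                 cell_diameter_px = 14,
                                 papilla_radius_px = 14,
                                 n_papillae = 22,
                                 fibril_wavelength_px = 11,
                                 fibril_orientation_deg = 30,
                                 fibril_angle_bw = 0.25,
                                 speckle_grain_px = 2,
                                 rng_seed = 1) {
  thicknesses <- stats::setNames(as.integer(thicknesses), strata_levels())
  if (any(thicknesses < 1)) stop("every stratum thickness must be >= 1")
  structure(as.list(environment()), class = "synthetic_stack_spec")
}

# distance-to-two-nearest-seeds field of a jittered lattice (vectorised over
# the 3x3 neighbouring lattice cells); the basis of the honeycomb texture
nearest_two_seed_distances <- function(h, w, cell) {
  ny <- ceiling(h / cell) + 4L
  nx <- ceiling(w / cell) + 4L
  origin <- -2 * cell
  jy <- matrix(stats::runif(ny * nx, -0.42, 0.42) * cell, ny, nx)
  jx <- matrix(stats::runif(ny * nx, -0.42, 0.42) * cell, ny, nx)
  sy <- origin + (row(jy) - 0.5) * cell + jy
  sx <- origin + (col(jx) - 0.5) * cell + jx
  Y <- matrix(seq_len(h), h, w)
  X <- matrix(seq_len(w), h, w, byrow = TRUE)
  iy <- pmin(pmax(floor((Y - origin) / cell) + 1L, 2L), ny - 1L)
  ix <- pmin(pmax(floor((X - origin) / cell) + 1L, 2L), nx - 1L)
  d1 <- matrix(Inf, h, w)
  d2 <- matrix(Inf, h, w)
  for (di in -1:1) for (dj in -1:1) {
    idx <- cbind(as.vector(iy + di), as.vector(ix + dj))
    dd <- matrix((as.vector(Y) - sy[idx])^2 + (as.vector(X) - sx[idx])^2, h, w)
    closer <- dd < d1
    d2 <- ifelse(closer, d1, pmin(d2, dd))
    d1 <- pmin(d1, dd)
  }
  list(d1 = sqrt(d1), d2 = sqrt(d2))
}

honeycomb_field <- function(h, w, cell, border_width = 2,
                            bright = 0.85, dark = 0.2) {
  d <- nearest_two_seed_distances(h, w, cell)
  border <- (d$d2 - d$d1) < border_width
  img <- ifelse(border, bright, dark)
  list(img = img, border = border,
       interior = (d$d2 - d$d1) > cell / 3)
}

oriented_bandpass_noise <- function(h, w, wavelength, orientation_deg,
                                    angle_bw = 0.35) {
  fy <- c(0:floor(h / 2), -(ceiling(h / 2) - 1):-1)[1:h] / h
  fx <- c(0:floor(w / 2), -(ceiling(w / 2) - 1):-1)[1:w] / w
  FY <- matrix(fy, h, w)
  FX <- matrix(fx, h, w, byrow = TRUE)
  fr <- sqrt(FY^2 + FX^2)
  f0 <- 1 / wavelength
  theta <- orientation_deg * pi / 180
  # orientation difference wrapped to [0, pi/2]
  ang <- atan2(FY, FX) - theta
  ang <- abs(((ang + pi / 2) %% pi) - pi / 2)
  mask <- exp(-(fr - f0)^2 / (2 * (f0 / 2.5)^2)) *
    exp(-ang^2 / (2 * angle_bw^2))
  z <- matrix(stats::rnorm(h * w), h, w)
  scale01(Re(stats::fft(stats::fft(z) * mask, inverse = TRUE)) / (h * w))
}

#' Render one stratum's synthetic texture
#'
#' Generates a `[0, 1]` grayscale texture emulating the clinical appearance
#' of the requested stratum: `SC` — bright high-variance speckle blotches;
#' `VE` — honeycomb of bright cell borders around dark keratinocytes; `DEJ` —
#' dark papilla centres ringed by bright basal-cell annuli over a dimmed
#' honeycomb background; `PD` — oriented fibrillar band-pass noise. Pixel
#' content is drawn from the current RNG stream (seed at the stack level).
#'
#' @param stratum one of `"SC"`, `"VE"`, `"DEJ"`, `"PD"`.
#' @param spec a [synthetic_stack_spec()].
#' @param return_masks also attach the generator's own ground-truth masks
#'   (e.g. honeycomb border/interior, papilla disc/annulus) as the `"masks"`
#'   attribute.
#' @return Numeric matrix in `[0, 1]` (noise-free; stack assembly adds
#'   noise).
#' @export
render_stratum_texture <- function(stratum, spec, return_masks = FALSE) {
  stopifnot(inherits(spec, "synthetic_stack_spec"))
  h <- spec$height_px; w <- spec$width_px
  masks <- NULL
  img <- switch(as.character(as_stratum(stratum)),
    SC = {
      # bright isotropic granules (keratin speckle) over broad blotches
      speck <- scale01(blur_fft(matrix(stats::rnorm(h * w), h, w),
                                spec$speckle_grain_px))
      blotch <- scale01(blur_fft(matrix(stats::rnorm(h * w), h, w),
                                 max(h, w) / 12))
      granule <- speck > 0.55
      masks <- list(granule = granule)
      clip01(0.3 + 0.12 * speck + 0.55 * granule * (0.6 + 0.4 * blotch))
    },
    VE = {
      hc <- honeycomb_field(h, w, spec$cell_diameter_px)
      masks <- hc[c("border", "interior")]
      hc$img
    },
    DEJ = {
      # basal-cell background: a finer, dimmer honeycomb than the spinous
      # layer (basal keratinocytes are roughly half the size)
      bg <- honeycomb_field(h, w, 0.5 * spec$cell_diameter_px,
                            bright = 0.55, dark = 0.15)$img
      r <- spec$papilla_radius_px
      cx <- stats::runif(spec$n_papillae, r + 4, w - r - 4)
      cy <- stats::runif(spec$n_papillae, r + 4, h - r - 4)
      Y <- matrix(seq_len(h), h, w)
      X <- matrix(seq_len(w), h, w, byrow = TRUE)
      dmin <- matrix(Inf, h, w)
      for (k in seq_len(spec$n_papillae)) {
        dmin <- pmin(dmin, sqrt((Y - cy[k])^2 + (X - cx[k])^2))
      }
      disc <- dmin < r
      annulus <- dmin >= r & dmin < r + 3
      img <- bg
      img[disc] <- 0.08
      img[annulus] <- 0.92
      masks <- list(disc = disc, annulus = annulus,
                    disc_centre = dmin < 0.6 * r)
      img
    },
    PD = {
      # interwoven collagen meshwork: locally oriented bright fibrils whose
      # orientation drifts across the section (domains around the base
      # orientation), so every section shows fibres in many directions
      angles <- spec$fibril_orientation_deg + c(0, 45, 90, 135)
      fields <- lapply(angles, function(a) {
        oriented_bandpass_noise(h, w, spec$fibril_wavelength_px, a,
                                spec$fibril_angle_bw)
      })
      pref <- lapply(angles, function(a) {
        blur_fft(matrix(stats::rnorm(h * w), h, w), max(h, w) / 10)
      })
      pick <- matrix(1L, h, w)
      best <- pref[[1]]
      for (k in 2:4) {
        better <- pref[[k]] > best
        pick[better] <- k
        best <- pmax(best, pref[[k]])
      }
      f <- fields[[1]]
      for (k in 2:4) f[pick == k] <- fields[[k]][pick == k]
      f <- scale01(f)
      strand <- f > 0.65
      masks <- list(strand = strand)
      clip01(0.1 + 0.2 * f + 0.55 * strand)
    })
  if (return_masks) attr(img, "masks") <- masks
  img
}

#' Generate one synthetic depth stack with known truth
#'
#' Assembles sections ordered SC -> VE -> DEJ -> PD with the spec's
#' thicknesses, adds Gaussian pixel noise, and (optionally) carves a furrow:
#' a localized region in which each section shows the texture of the stratum
#' `furrow_depth_sections` deeper, so superficial sections mix strata as real
#' furrowed stacks do. Returns the stack together with its label table and
#' the true interface depths implied by the thicknesses.
#'
#' @param spec a [synthetic_stack_spec()].
#' @param stack_id,participant_id,body_site,age_group,phototype metadata
#'   stored in the stack.
#' @return List with `stack` ([depth_stack()]), `labels` (`label_table`) and
#'   `interfaces` ([estimate_interfaces()] of the true labels).
#' @export
generate_stack <- function(spec, stack_id = "stk1", participant_id = "p1",
                           body_site = "dorsal", age_group = "20-30",
                           phototype = "II") {
  stopifnot(inherits(spec, "synthetic_stack_spec"))
  th <- spec$thicknesses
  strata_seq <- rep(strata_levels(), times = th)
  n <- length(strata_seq)
  with_seed(spec$rng_seed, {
    furrow <- NULL
    if (spec$furrow_depth_sections > 0) {
      R <- min(spec$width_px, spec$height_px) / 5
      cx <- stats::runif(1, R, spec$width_px - R)
      cy <- stats::runif(1, R, spec$height_px - R)
      Y <- matrix(seq_len(spec$height_px), spec$height_px, spec$width_px)
      X <- matrix(seq_len(spec$width_px), spec$height_px, spec$width_px,
                  byrow = TRUE)
      furrow <- stats::plogis((R - sqrt((Y - cy)^2 + (X - cx)^2)) / 2)
    }
    sections <- vector("list", n)
    for (i in seq_len(n)) {
      img <- render_stratum_texture(strata_seq[i], spec)
      if (!is.null(furrow)) {
        deeper <- strata_seq[min(i + spec$furrow_depth_sections, n)]
        if (deeper != strata_seq[i]) {
          img <- img * (1 - furrow) +
            render_stratum_texture(deeper, spec) * furrow
        }
      }
      if (spec$noise_sigma > 0) {
        img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sigma),
                            nrow(img))
      }
      sections[[i]] <- clip01(img)
    }
    labels <- label_table(data.frame(
      stack_id = stack_id, section_index = seq_len(n) - 1L,
      stratum = strata_seq, stringsAsFactors = FALSE))
    list(stack = depth_stack(sections, spacing_um = spec$spacing_um,
                             stack_id = stack_id,
                             participant_id = participant_id,
                             body_site = body_site, age_group = age_group,
                             phototype = phototype),
         labels = labels,
         interfaces = estimate_interfaces(strata_seq, spec$spacing_um))
  })
}

default_cohort_ranges <- function() {
  list(sc_thickness = c(6, 12), ve_thickness = c(10, 16),
       dej_thickness = c(8, 14), pd_thickness = c(8, 14),
       cell_diameter_px = c(11, 17), papilla_radius_px = c(11, 17),
       fibril_wavelength_px = c(9, 14), fibril_orientation_deg = c(0, 180),
       speckle_grain_px = c(1.5, 2.5))
}

runif1 <- function(rg) stats::runif(1, rg[1], rg[2])

#' Generate a synthetic participant cohort
#'
#' Draws per-participant texture parameters and strata thicknesses from the
#' given ranges; all of one participant's stacks share the participant-level
#' parameters (each stack still has its own seed, so pixel content differs).
#' This makes participant-partitioned cross-validation meaningful: held-out
#' participants genuinely differ from training participants. Participants are
#' split evenly between the `"20-30"` and `"50-70"` age groups, stacks
#' alternate dorsal/volar body sites, and phototypes I-III are assigned
#' cyclically.
#'
#' @param n_participants number of participants (>= 2).
#' @param stacks_per_participant stacks generated per participant.
#' @param spec_ranges named list of `c(min, max)` ranges overriding (a subset
#'   of) the defaults: `sc_thickness`, `ve_thickness`, `dej_thickness`,
#'   `pd_thickness` (sections), `cell_diameter_px`, `papilla_radius_px`,
#'   `fibril_wavelength_px`, `fibril_orientation_deg`, `speckle_grain_px`.
#'   A degenerate range `c(v, v)` fixes the value.
#' @param rng_seed cohort seed.
#' @param width_px,height_px,spacing_um,noise_sigma,furrow_depth_sections
#'   fixed stack parameters (see [synthetic_stack_spec()]).
#' @return List with `stacks` (list of [depth_stack()]), `labels` (combined
#'   `label_table`), `metadata` (per-stack data frame), and `interfaces`
#'   (per-stack true interface depths, as [interface_table()]).
#' @export
generate_cohort <- function(n_participants, stacks_per_participant = 2,
                            spec_ranges = list(), rng_seed = 1,
                            width_px = 250, height_px = 250, spacing_um = 2,
                            noise_sigma = 0.05, furrow_depth_sections = 0) {
  if (n_participants < 2) stop("need at least 2 participants")
  rg <- utils::modifyList(default_cohort_ranges(), spec_ranges)
  bad <- names(rg)[!vapply(rg, function(v)
    is.numeric(v) && length(v) == 2 && v[2] >= v[1], logical(1))]
  if (length(bad)) stop("invalid range(s): ", paste(bad, collapse = ", "))
  with_seed(rng_seed, {
    stacks <- list(); labels <- list(); meta <- list(); truth <- list()
    for (p in seq_len(n_participants)) {
      pid <- sprintf("p%02d", p)
      age <- if (p <= ceiling(n_participants / 2)) "20-30" else "50-70"
      photo <- c("I", "II", "III")[(p - 1) %% 3 + 1]
      th <- c(SC = round(runif1(rg$sc_thickness)),
              VE = round(runif1(rg$ve_thickness)),
              DEJ = round(runif1(rg$dej_thickness)),
              PD = round(runif1(rg$pd_thickness)))
      pars <- list(cell_diameter_px = runif1(rg$cell_diameter_px),
                   papilla_radius_px = runif1(rg$papilla_radius_px),
                   fibril_wavelength_px = runif1(rg$fibril_wavelength_px),
                   fibril_orientation_deg = runif1(rg$fibril_orientation_deg),
                   speckle_grain_px = runif1(rg$speckle_grain_px))
      for (s in seq_len(stacks_per_participant)) {
        sid <- sprintf("%s_s%d", pid, s)
        site <- if (s %% 2 == 1) "dorsal" else "volar"
        spec <- do.call(synthetic_stack_spec, c(
          list(width_px = width_px, height_px = height_px,
               spacing_um = spacing_um, thicknesses = th,
               noise_sigma = noise_sigma,
               furrow_depth_sections = furrow_depth_sections,
               rng_seed = stats::runif(1, 1, 2^30)),
          pars))
        g <- generate_stack(spec, stack_id = sid, participant_id = pid,
                            body_site = site, age_group = age,
                            phototype = photo)
        stacks[[sid]] <- g$stack
        labels[[sid]] <- g$labels
        meta[[sid]] <- data.frame(stack_id = sid, participant_id = pid,
                                  body_site = site, age_group = age,
                                  phototype = photo, stringsAsFactors = FALSE)
        truth[[sid]] <- data.frame(
          stack_id = sid, sc_ve_um = g$interfaces[["sc_ve_um"]],
          ve_dej_um = g$interfaces[["ve_dej_um"]],
          dej_pd_um = g$interfaces[["dej_pd_um"]], stringsAsFactors = FALSE)
      }
    }
    lab <- do.call(rbind, c(labels, list(make.row.names = FALSE)))
    class(lab) <- c("label_table", "data.frame")
    list(stacks = stacks, labels = lab,
         metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
         interfaces = do.call(rbind, c(truth, list(make.row.names = FALSE))))
  })
}
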