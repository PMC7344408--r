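#' Specification for a synthetic dermoscopy fixture
#'
#' Describes a dark, irregular lesion on lighter skin: the lesion boundary is
#' a radial harmonic perturbation of a circle,
#' `r(theta) = r0 * (1 + a * sum_k c_k * cos(k * theta + phi_k))`, colors blend
#' from lesion core to skin through a smoothstep sigmoid of the signed
#' distance to the boundary, and optional dark hair strokes, Gaussian pixel
#' noise and a dark corner vignette emulate the acquisition artifacts of real
#' dermoscopy (hair, poor illumination, the field edge of the dermoscope).
#'
#' The default colors put skin above 128 and the lesion core below 128 in all
#' three channels — the contrast regime in which most-significant-bit slicing
#' carries the lesion/skin distinction. They are fixture choices emulating
#' typical pigmented-lesion images, not measured values.
#'
#' @param size Image side length in pixels (square image; default 256).
#' @param center Lesion center `(row, col)`; default the image center.
#' @param radius Base lesion radius `r0` in pixels (default 60); must be less
#'   than half the image side.
#' @param harmonics Number of radial harmonics `K` (default 5).
#' @param irregularity Amplitude scale `a` as a fraction of the radius
#'   (default 0.15); must be small enough that the boundary cannot
#'   self-intersect.
#' @param skin_color,lesion_color RGB triples in 0--255 (defaults
#'   `(200,160,140)` and `(90,60,50)`).
#' @param transition Skin-to-lesion transition width in pixels (default 4).
#' @param noise_sd Additive Gaussian noise standard deviation in intensity
#'   units (default 10), applied per channel and clipped (not wrapped) to
#'   `[0, 255]` so noise cannot flip the MSB by wrap-around.
#' @param n_hairs Number of dark hair strokes (default 3).
#' @param hair_darkness Hair intensity in 0--255 (default 40).
#' @param hair_width Stroke width, 1 or 2 pixels (default 1).
#' @param vignette Corner-darkening radius as a fraction of half the image
#'   side; 0 (the default) disables the vignette.
#' @param seed Integer seed fixing all randomness of the fixture.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(size = 256L,
                           center = NULL,
                           radius = 60,
                           harmonics = 5L,
                           irregularity = 0.15,
                           skin_color = c(200, 160, 140),
                           lesion_color = c(90, 60, 50),
                           transition = 4,
                           noise_sd = 10,
                           n_hairs = 3L,
                           hair_darkness = 40,
                           hair_width = 1L,
                           vignette = 0,
                           seed = 0L) {
  size <- as.integer(size)
  if (length(size) != 1L || size < 16L) stop("`size` must be >= 16", call. = FALSE)
  if (is.null(center)) center <- c((size + 1) / 2, (size + 1) / 2)
  if (radius >= size / 2) {
    stop("`radius` must be less than half the image side", call. = FALSE)
  }
  if (irregularity < 0 || irregularity >= 1) {
    stop("`irregularity` must lie in [0, 1)", call. = FALSE)
  }
  for (col in list(skin_color, lesion_color)) {
    if (length(col) != 3L || any(col < 0) || any(col > 255)) {
      stop("colors must be RGB triples in [0, 255]", call. = FALSE)
    }
  }
  if (!hair_width %in% c(1L, 2L)) stop("`hair_width` must be 1 or 2", call. = FALSE)
  structure(
    list(size = size, center = center, radius = radius,
         harmonics = as.integer(harmonics), irregularity = irregularity,
         skin_color = skin_color, lesion_color = lesion_color,
         transition = transition, noise_sd = noise_sd,
         n_hairs = as.integer(n_hairs), hair_darkness = hair_darkness,
         hair_width = as.integer(hair_width), vignette = vignette,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# internal: run expr under a fixed seed, restoring the caller's RNG state
with_fixed_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Generate one synthetic dermoscopy image with exact ground truth
#'
#' Pixels strictly inside the sampled boundary curve form the truth mask.
#' Rendering order: color blend, hair strokes, additive Gaussian noise,
#' vignette, then clipping to `[0, 255]` and rounding. An identical spec
#' (including seed) always yields a bit-identical fixture.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `image` ([rgb_image()]), `truth` (0/1 integer matrix)
#'   and `boundary` (tibble of the analytic boundary polygon, columns
#'   `theta`, `r`, `row`, `col`).
#' @export
generate_fixture <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_fixed_seed(spec$seed, {
    h <- w <- spec$size
    K <- spec$harmonics
    ck <- if (K > 0) runif(K, -1, 1) / seq_len(K) else numeric(0)
    phik <- if (K > 0) runif(K, 0, 2 * pi) else numeric(0)

    rowm <- matrix(seq_len(h), h, w)
    colm <- matrix(seq_len(w), h, w, byrow = TRUE)
    dy <- rowm - spec$center[1L]
    dx <- colm - spec$center[2L]
    theta <- atan2(dy, dx)
    rho <- sqrt(dx^2 + dy^2)
    pert <- matrix(0, h, w)
    for (k in seq_len(K)) {
      pert <- pert + spec$irregularity * ck[k] * cos(k * theta + phik[k])
    }
    rtheta <- spec$radius * (1 + pert)
    d <- rho - rtheta
    truth <- matrix(as.integer(d < 0), h, w)

    if (spec$transition > 0) {
      u <- pmin(pmax(0.5 - d / spec$transition, 0), 1)
      f <- u^2 * (3 - 2 * u)
    } else {
      f <- as.numeric(d < 0)
    }
    arr <- array(0, dim = c(h, w, 3L))
    for (ci in 1:3) {
      arr[, , ci] <- f * spec$lesion_color[ci] + (1 - f) * spec$skin_color[ci]
    }

    if (spec$n_hairs > 0L) {
      for (hh in seq_len(spec$n_hairs)) {
        r0 <- runif(1, 1, h)
        c0 <- runif(1, 1, w)
        ang <- runif(1, 0, 2 * pi)
        len <- runif(1, 0.4, 0.8) * spec$size
        curv <- runif(1, -0.003, 0.003)
        tt <- seq(0, len, by = 0.5)
        rr <- round(r0 + cumsum(c(0, diff(tt)) * sin(ang + curv * tt)))
        cc <- round(c0 + cumsum(c(0, diff(tt)) * cos(ang + curv * tt)))
        pts <- cbind(rr, cc)
        if (spec$hair_width == 2L) {
          pts <- rbind(pts, cbind(rr + round(sin(ang + pi / 2)),
                                  cc + round(cos(ang + pi / 2))))
        }
        ok <- pts[, 1L] >= 1 & pts[, 1L] <= h & pts[, 2L] >= 1 & pts[, 2L] <= w
        pts <- pts[ok, , drop = FALSE]
        for (ci in 1:3) arr[cbind(pts[, 1L], pts[, 2L], ci)] <- spec$hair_darkness
      }
    }

    if (spec$noise_sd > 0) {
      arr <- arr + array(rnorm(h * w * 3L, 0, spec$noise_sd), dim = dim(arr))
    }

    if (spec$vignette > 0) {
      R0 <- spec$vignette * min(h, w) / 2
      dc <- sqrt((rowm - (h + 1) / 2)^2 + (colm - (w + 1) / 2)^2)
      s <- pmin(pmax((dc - R0) / (0.3 * R0), 0), 1)
      fade <- 1 - 0.85 * s^2 * (3 - 2 * s)
      for (ci in 1:3) arr[, , ci] <- arr[, , ci] * fade
    }

    arr <- round(pmin(pmax(arr, 0), 255))
    thg <- seq(0, 2 * pi, length.out = 721L)[-721L]
    pg <- rep(0, length(thg))
    for (k in seq_len(K)) {
      pg <- pg + spec$irregularity * ck[k] * cos(k * thg + phik[k])
    }
    rg <- spec$radius * (1 + pg)
    boundary <- tibble::tibble(
      theta = thg, r = rg,
      row = spec$center[1L] + rg * sin(thg),
      col = spec$center[2L] + rg * cos(thg)
    )
    list(image = rgb_image(arr), truth = truth, boundary = boundary)
  })
}

#' Generate a deterministic suite of synthetic fixtures
#'
#' Derives one sub-seed per image from `master_seed` and randomizes lesion
#' center (within 10 px of the image center), base radius (0.8--1.1 of the
#' base spec's), irregularity (0.08--0.18) and harmonic count (3--6) across
#' images; all other parameters come from `base_spec`. Identifiers are
#' `"synth_000"`, `"synth_001"`, ...
#'
#' @param n Number of fixtures (>= 1).
#' @param base_spec A [synthetic_spec()] providing the non-randomized fields.
#' @param master_seed Integer seed for the whole suite.
#' @return A list of cases, each with `image`, `truth`, `id`, `spec`;
#'   directly consumable by [evaluate_dataset()].
#' @export
generate_suite <- function(n, base_spec = synthetic_spec(), master_seed = 0L) {
  if (length(n) != 1L || is.na(n) || n < 1L) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  with_fixed_seed(master_seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    params <- lapply(seq_len(n), function(i) {
      list(
        seed = seeds[i],
        radius = base_spec$radius * runif(1, 0.8, 1.1),
        center = c(
          (base_spec$size + 1) / 2 + runif(1, -10, 10),
          (base_spec$size + 1) / 2 + runif(1, -10, 10)
        ),
        irregularity = runif(1, 0.08, 0.18),
        harmonics = sample(3:6, 1L)
      )
    })
    lapply(seq_len(n), function(i) {
      sp <- base_spec
      sp[names(params[[i]])] <- params[[i]]
      class(sp) <- "synthetic_spec"
      fx <- generate_fixture(sp)
      list(image = fx$image, truth = fx$truth,
           id = sprintf("synth_%03d", i - 1L), spec = sp)
    })
  })
}
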