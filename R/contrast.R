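# Quadratic HU transfer curve: the scanner-specific HU of the two phantom
# materials are rescaled to tissue-like values with the unique degree <= 2
# polynomial through three anchor pairs, keeping the background fixed.

#' Contrast-remap specification
#'
#' Three anchor pairs (old HU -> new HU): the background (a fixed point by
#' construction of the study), material 1 (clay / soft material) and
#' material 2 (glass / dense material). The three old values must be
#' pairwise distinct for the interpolation to be well posed.
#'
#' @param material1,material2 length-2 numeric `c(old, new)` anchor pairs.
#' @param background length-2 numeric anchor, by default a fixed point at
#'   -1000 HU (air).
#' @return A list of class `contrast_spec`.
#' @export
contrast_spec <- function(material1, material2,
                          background = c(-1000, -1000)) {
  anchors <- rbind(background = as.numeric(background),
                   material1 = as.numeric(material1),
                   material2 = as.numeric(material2))
  if (ncol(anchors) != 2L || any(!is.finite(anchors)))
    stop("parameter error: anchors must be finite c(old, new) pairs",
         call. = FALSE)
  if (anyDuplicated(anchors[, 1]))
    stop("parameter error: the three old-HU anchors must be pairwise distinct",
         call. = FALSE)
  structure(list(anchors = anchors), class = "contrast_spec")
}

#' The three study contrast levels
#'
#' Named list of [contrast_spec()]s remapping clay/glass to: muscle/bone
#' 30/1000 HU (`"30_1000"`), fat/muscle -100/40 HU (`"-100_40"`) and two
#' soft tissues 10/50 HU (`"10_50"`), with the background fixed.
#'
#' @param hu_clay,hu_glass raw material HU being remapped (defaults match
#'   [bending_phantom_spec()]).
#' @return Named list of three `contrast_spec` objects.
#' @export
study_contrast_levels <- function(hu_clay = 150, hu_glass = 2300) {
  list(
    "30_1000" = contrast_spec(c(hu_clay, 30), c(hu_glass, 1000)),
    "-100_40" = contrast_spec(c(hu_clay, -100), c(hu_glass, 40)),
    "10_50"   = contrast_spec(c(hu_clay, 10), c(hu_glass, 50))
  )
}

# coefficients of the unique degree <= 2 polynomial through the anchors
# (Lagrange form collected into c0 + c1 v + c2 v^2)
contrast_poly <- function(spec) {
  x <- spec$anchors[, 1]; y <- spec$anchors[, 2]
  c2 <- y[1] / ((x[1] - x[2]) * (x[1] - x[3])) +
        y[2] / ((x[2] - x[1]) * (x[2] - x[3])) +
        y[3] / ((x[3] - x[1]) * (x[3] - x[2]))
  c1 <- -(y[1] * (x[2] + x[3]) / ((x[1] - x[2]) * (x[1] - x[3])) +
          y[2] * (x[1] + x[3]) / ((x[2] - x[1]) * (x[2] - x[3])) +
          y[3] * (x[1] + x[2]) / ((x[3] - x[1]) * (x[3] - x[2])))
  c0 <- y[1] * x[2] * x[3] / ((x[1] - x[2]) * (x[1] - x[3])) +
        y[2] * x[1] * x[3] / ((x[2] - x[1]) * (x[2] - x[3])) +
        y[3] * x[1] * x[2] / ((x[3] - x[1]) * (x[3] - x[2]))
  c(c0, c1, c2)
}

#' Remap image contrast with a quadratic HU transfer curve
#'
#' Every voxel value `v` is replaced by `q(v)`, where `q` is the unique
#' polynomial of degree <= 2 through the three anchor pairs of `spec`
#' (Lagrange interpolation). With the default background anchor the
#' background value maps to itself.
#'
#' @param volume `dirqa_volume`.
#' @param spec [contrast_spec()].
#' @return A remapped `dirqa_volume` on the same grid.
#' @export
remap_contrast <- function(volume, spec) {
  cf <- contrast_poly(spec)
  v <- volume$voxels
  image_volume(cf[1] + v * (cf[2] + v * cf[3]), volume$spacing, volume$origin)
}

#' Add reproducible Gaussian image noise
#'
#' @param volume `dirqa_volume`.
#' @param sigma noise standard deviation in HU (>= 0).
#' @param seed integer seed; the same seed always yields the same noise.
#' @return A `dirqa_volume` with i.i.d. N(0, sigma^2) noise added.
#' @export
add_noise <- function(volume, sigma, seed = 1L) {
  if (!is.finite(sigma) || sigma < 0)
    stop("parameter error: sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(volume)
  rng <- local_rng(seed)
  noise <- rng(stats::rnorm(length(volume$voxels), sd = sigma))
  image_volume(volume$voxels + array(noise, dim = dim(volume$voxels)),
               volume$spacing, volume$origin)
}

# run `expr` under a private RNG state seeded with `seed`, restoring the
# caller's state afterwards
local_rng <- function(seed) {
  function(expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed) %% .Machine$integer.max)
    expr
  }
}
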