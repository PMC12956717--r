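# Shared fixtures, built in code at test time.

# uniform-HU volume
const_volume <- function(hu, dim = c(8, 8, 8), spacing = c(1, 1, 1)) {
  ct_volume(array(hu, dim), spacing = spacing)
}

# full-grid binary mask
full_mask <- function(dim = c(8, 8, 8), spacing = c(1, 1, 1)) {
  label_mask(array(TRUE, dim), spacing = spacing)
}

# random binary mask with given foreground probability
random_mask <- function(dim = c(6, 6, 6), p = 0.3) {
  label_mask(array(stats::runif(prod(dim)) < p, dim))
}

# a small phantom reused across end-to-end tests (cached per session)
small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom(phantom_spec(seed = 7))
    cache
  }
})

# airway measurements constructed so sqrt(WA) = intercept + slope * Pi exactly
collinear_airways <- function(pis, slope, intercept) {
  lapply(pis, function(p) {
    r_l <- p / (2 * pi)
    wa <- (intercept + slope * p)^2
    r_o <- sqrt(wa / pi + r_l^2)
    airway_measurement(r_l, r_o - r_l)
  })
}
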