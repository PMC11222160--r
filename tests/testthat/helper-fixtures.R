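# Shared fixtures for the test suite. Everything is generated in code; the
# only on-disk fixtures are the tiny dual-format coordinate models under
# inst/extdata.

# One default-profile template bank, built once per test run.
test_bank <- local({
  bank <- NULL
  function() {
    if (is.null(bank))
      bank <<- make_template_bank(n_templates = 21, length = 400,
                                  image_size = 128, pixel_size = 4)
    bank
  }
})

# Coarse bank for detection tests (matched over rotations, so few kappas).
detect_bank <- local({
  bank <- NULL
  function() {
    if (is.null(bank))
      bank <<- make_template_bank(n_templates = 5, length = 300,
                                  image_size = 96, pixel_size = 4)
    bank
  }
})

# A single-segment synthetic class average with known ground truth.
make_average <- function(kappa = 0, theta = 0, centre = c(0, 0),
                         snr = Inf, seed = 1, image_size = 160,
                         pixel_size = 4, length = 400) {
  seg <- ground_truth_segment(centre = centre, theta = theta, kappa = kappa,
                              length = length)
  spec <- sim_spec_2d(
    image_size = image_size, pixel_size = pixel_size, segments = list(seg),
    noise_model = if (is.finite(snr)) "gaussian" else "none",
    snr = if (is.finite(snr)) snr else 1, seed = seed)
  list(image = simulate_micrograph(spec)$image, segment = seg)
}

# Random 3D rotation matrix from a seed.
random_rotation <- function(seed) {
  set.seed(seed)
  a <- stats::rnorm(4)
  a <- a / sqrt(sum(a^2))
  q0 <- a[1]; q1 <- a[2]; q2 <- a[3]; q3 <- a[4]
  matrix(c(1 - 2 * (q2^2 + q3^2), 2 * (q1 * q2 - q0 * q3), 2 * (q1 * q3 + q0 * q2),
           2 * (q1 * q2 + q0 * q3), 1 - 2 * (q1^2 + q3^2), 2 * (q2 * q3 - q0 * q1),
           2 * (q1 * q3 - q0 * q2), 2 * (q2 * q3 + q0 * q1), 1 - 2 * (q1^2 + q2^2)),
         3, 3, byrow = TRUE)
}

extdata <- function(name) {
  path <- system.file("extdata", name, package = "cryomem")
  if (path == "") path <- file.path("..", "..", "inst", "extdata", name)
  path
}
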