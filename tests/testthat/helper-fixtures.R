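# Shared fixtures, built once per test run. Phantom generation is cheap but
# not free; the cache keeps the suite fast without files on disk.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# noise-free default head phantom: analytic oracles apply exactly
clean_phantom <- function() fixture("clean", make_head_phantom(phantom_spec()))

# mildly noisy phantom: the realistic case
noisy_phantom <- function() {
  fixture("noisy", make_head_phantom(phantom_spec(noise_sigma = 2)))
}

# a geometrically distinct head: different skull size, thickness, sinus and
# target layout ("different patient" comparisons)
other_phantom <- function() {
  fixture("other", make_head_phantom(phantom_spec(
    skull_outer_radii = c(75, 98, 68), skull_thickness = 9,
    air_cavity = list(center = c(0, -50, -30), radius = 15),
    targets = list(target(c(-15, 20, 5), 6)), noise_sigma = 2, seed = 99)))
}

# closed-form distance from `from` along unit `dir` to the ellipsoid
# x^2/a^2 + y^2/b^2 + z^2/c^2 = 1 (the independent ray-trace oracle)
ray_ellipsoid_distance <- function(from, dir, semi) {
  a <- sum((dir / semi)^2)
  b <- 2 * sum(from * dir / semi^2)
  cc <- sum((from / semi)^2) - 1
  (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
}

# inner-skull semi-axes of the default phantom spec
inner_semi_axes <- function(spec = phantom_spec()) {
  spec$skull_outer_radii - spec$skull_thickness
}

# translation magnitude and largest rotation angle of a residual transform
transform_error <- function(T_est, T_true) {
  resid <- compose_transform(T_est, T_true)
  list(t_mm = sqrt(resid$tx^2 + resid$ty^2 + resid$tz^2),
       rot_deg = max(abs(c(resid$roll, resid$pitch, resid$yaw))))
}

# small smooth random dose pair on a tiny grid for gamma oracle testing
random_dose_pair <- function(seed, n = 14) {
  set.seed(seed)
  idx <- (seq_len(n) - (n + 1) / 2)^2
  base <- 20 * exp(-outer(outer(idx, idx, `+`), idx, `+`) / 30)
  mk <- function() volume_image(array(base + stats::rnorm(n^3, 0, 0.15),
                                      c(n, n, n)),
                                c(1, 1, 1), c(0, 0, 0), "DOSE")
  list(ref = mk(), ev = mk())
}
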