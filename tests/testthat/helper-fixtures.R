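# Shared fixtures, built once per test run and cached in this environment.
# Everything is generated in code; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_montage <- function() fx_get("montage", function() {
  fit_sphere(generate_montage(204, 90, seed = 1))
})

fx_head <- function() fx_get("head", function() head_model())

fx_grid <- function() fx_get("grid", function() build_grid(fx_head()))

fx_leadfield <- function() fx_get("leadfield", function() {
  compute_leadfield(fx_montage(), fx_grid(), fx_head(), n_terms = 60)
})

fx_wmn <- function() fx_get("wmn", function() wmn_operator(fx_leadfield()))

fx_templates <- function() fx_get("templates", function() {
  generate_templates(7, fx_leadfield(), fx_grid(), seed = 5)
})

# A small evoked object holding the given channels x samples matrix at 250 Hz
# with onset at sample 51 (epoch -200..748 ms).
toy_evoked <- function(data, sfreq = 250, t0_index = 51, ...) {
  evoked(data, sfreq, t0_index, n_epochs = 1,
         labels = paste0("E", seq_len(nrow(data))), ...)
}

# Noise-free study-shaped evoked data built from templates on the default
# timeline; returns list(data, ground_truth, spec, montage, templates).
fx_study <- function(noise_sd = 0, seed = 42, jitter = 0) {
  tpl <- fx_templates()
  spec <- simulation_spec(noise_sd = noise_sd, seed = seed,
                          subject_jitter_sd = jitter)
  sim <- simulate_study(spec, tpl, fx_montage())
  c(sim, list(spec = spec, templates = tpl))
}

# Independent homogeneous-sphere scalp potential for a dipole (closed-form
# Legendre series evaluated with pracma's associated Legendre functions) --
# the analytic oracle for the equal-conductivity limit of the lead field.
hom_sphere_potential <- function(elec, rd, mom, R, sigma, nmax = 150) {
  b <- sqrt(sum(rd^2))
  rdu <- if (b > 0) rd / b else c(0, 0, 1)
  ru <- elec / sqrt(rowSums(elec^2))
  x <- as.vector(ru %*% rdu)
  mr <- sum(mom * rdu)
  tang <- mom - mr * rdu
  sg <- sqrt(pmax(0, 1 - x^2))
  ev <- ru - outer(x, rdu)
  mt_cos <- ifelse(sg > 1e-12, as.vector(ev %*% tang) / sg, 0)
  v <- numeric(nrow(elec))
  for (n in 1:nmax) {
    Pn <- pracma::legendre(n, x)
    v <- v + (2 * n + 1) / n * (b / R)^(n - 1) / R^2 *
      (n * mr * Pn[1, ] + (-Pn[2, ]) * mt_cos)
  }
  v / (4 * pi * sigma)
}
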