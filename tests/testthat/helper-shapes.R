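# random but realistic dimensionless shapes, in the range of the
# published series (growth much faster than lifespan, finite decline)
random_shape <- function() {
  imap_shape(
    alpha0_star = stats::runif(1, 5, 200),
    alphar_star = stats::runif(1, 5, 100),
    betar_star = stats::runif(1, 0.5, 15),
    td = stats::runif(1, 2, 150),
    scale_inf = stats::runif(1, 0.5, 20)
  )
}

random_siler_set <- function() {
  list(a1 = stats::runif(1, 0.01, 5), b1 = stats::runif(1, 0.01, 2),
       a3 = stats::runif(1, 0.001, 1), b3 = stats::runif(1, 0.01, 1))
}

# noise-free envelope on an age grid strictly inside (0, td)
exact_envelope <- function(shape, n = 100, span = c(0.01, 0.8)) {
  simulate_envelope(shape,
                    ages = seq(span[1] * shape$td, span[2] * shape$td,
                               length.out = n),
                    noise_scale = 0, seed = 1)
}
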