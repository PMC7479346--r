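# Shared fixtures and seeded samplers for the test suite.

fig2_params <- function() params2(rho = 1, psi = 15, phi = 2,
                                  eps1 = 0.4, eps2 = 1)

fig3_params <- function() params3(rho = 0.61, psi = 1, beta = 7,
                                  eta = 0.01, phi = 1.4, phi1 = 0.02,
                                  eps1 = 0.12, eps2 = 0.43, eps3 = 0.06)

fig5_params <- function() params2(rho = 1, psi = 50, phi = 0.02,
                                  eps1 = 0, eps2 = 0)

# Draw n valid two-species parameter bundles (moderate, biologically
# sensible ranges around the benchmark fixtures).
sample_params2 <- function(n, seed = 1) {
  set.seed(seed)
  replicate(n, params2(rho = runif(1, 0.5, 2), psi = runif(1, 5, 30),
                       phi = runif(1, 0.5, 3), eps1 = runif(1, 0, 0.5),
                       eps2 = runif(1, 0, 1.5)),
            simplify = FALSE)
}

sample_params3 <- function(n, seed = 1) {
  set.seed(seed)
  replicate(n, params3(rho = runif(1, 0.3, 2), psi = runif(1, 0.5, 5),
                       beta = runif(1, 1, 10), eta = runif(1, 0.005, 0.1),
                       phi = runif(1, 0.2, 3), phi1 = runif(1, 0.01, 0.5),
                       eps1 = runif(1, 0, 0.4), eps2 = runif(1, 0.2, 1.5),
                       eps3 = runif(1, 0.02, 0.5)),
            simplify = FALSE)
}

# Random spectra without zero eigenvalues (conjugate pairs plus reals).
sample_spectrum <- function() {
  k <- sample(1:2, 1)
  eig <- complex(0)
  for (i in seq_len(k)) {
    if (runif(1) < 0.5) {
      re <- rnorm(1); im <- abs(rnorm(1)) + 1e-3
      eig <- c(eig, complex(real = re, imaginary = c(im, -im)))
    } else {
      re <- rnorm(1)
      if (abs(re) < 1e-6) re <- re + sign(re + 1e-9) * 1e-3
      eig <- c(eig, complex(real = re, imaginary = 0))
    }
  }
  eig
}
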