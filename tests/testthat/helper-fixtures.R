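# shared fixture builders and small utilities

r2_of <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)

# Gaussian-bump profile on a uniform grid, written in one line of base R so
# it is independent of the package's own generator
gaussian_profile <- function(n = 51, mu = 0, sd = 0.006, area = 80,
                             name = "gauss") {
  sigma <- seq(-0.025, 0.025, length.out = n)
  dens <- dnorm(sigma, mu, sd)
  sigma_profile(sigma, area * dens / sum(dens), name = name)
}

# descriptor vector with small integer areas for hand arithmetic
toy_descriptors <- function(S, name = "toy") descriptor_vector(S, name = name)

toy_constituent <- function(name, mass, S, role = "HBD") {
  constituent(name, role = role, molar_mass = mass,
              descriptors = toy_descriptors(S, name = name))
}

write_profile_file <- function(lines, path = tempfile(fileext = ".txt")) {
  writeLines(lines, path)
  path
}
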