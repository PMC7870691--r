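# Reduced grids for fast unit tests; physics parameters unchanged.
fast_params <- function() {
  p <- default_params()
  p$geometry$n_theta <- 24
  p$geometry$n_r <- 2
  p$geometry$n_theta_lumen <- 801
  p
}

# random incompressible diagonal stretch (r, t, z), moderate range
random_stretch3 <- function() {
  lt <- runif(1, 0.8, 1.3)
  lz <- runif(1, 0.8, 1.3)
  stretch3(lt, lz)
}

# random Hai-Murphy rate set
random_rates <- function() {
  r <- as.list(runif(7, 0.01, 1))
  names(r) <- paste0("k", 1:7)
  r$k6 <- r$k1
  r$k5 <- r$k2
  r
}
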