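# Shared fixtures: calibrated instrument, reference species, small scans.

test_instrument <- function() default_instrument()

# monodisperse bright population: every particle is a 50 nm sphere, so all
# spots are bright and identically sized (useful for detection/recovery)
bright_population <- function() size_population(50, 0, 1)

# count truth particles recovered by a fit table, by centre proximity
count_recovered <- function(spots, truth, tol_nm = 200) {
  if (nrow(spots) == 0 || nrow(truth) == 0) return(0L)
  sum(vapply(seq_len(nrow(truth)), function(i) {
    any((spots$x_nm - truth$x_nm[i])^2 +
          (spots$y_nm - truth$y_nm[i])^2 < tol_nm^2)
  }, TRUE))
}

# minimum centre-to-centre distance of each truth particle to the others
nearest_neighbour_nm <- function(truth) {
  n <- nrow(truth)
  if (n < 2) return(rep(Inf, n))
  vapply(seq_len(n), function(i) {
    d2 <- (truth$x_nm[-i] - truth$x_nm[i])^2 +
      (truth$y_nm[-i] - truth$y_nm[i])^2
    sqrt(min(d2))
  }, 0)
}
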