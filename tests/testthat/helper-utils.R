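# Small independent helpers used as oracles in the tests (deliberately not
# the package's internal routines).

trapz_ <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# a minimal density-profile-shaped data.frame for feeding analysis functions
new_density_profile_ <- function(df) {
  class(df) <- c("density_profile", "data.frame")
  df
}
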