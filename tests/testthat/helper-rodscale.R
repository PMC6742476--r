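# relative-error expectation used throughout
expect_rel <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}

# small valid shape table used by several files
tiny_shape_table <- function() {
  data.frame(
    condition = c("a", "a", "b"),
    length_um = c(4, 3.2, NA),
    width_um = c(1, 0.8, NA),
    growth_rate_per_h = c(1, 1, 0.5),
    surface_um2 = c(NA, NA, 10),
    volume_um3 = c(NA, NA, 2),
    geometry = c("rod", "rod", NA)
  )
}
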