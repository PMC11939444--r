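# shared fixtures

# amplitude-ordered exposure ladder (control excluded, increasing amplitude)
amplitude_ladder <- c("-40dBm", "-30dBm", "-20dBm", "-10dBm", "0dBm",
                      "+10dBm")

# one unit in the last digit of a value printed to `sig` significant figures
printed_ulp <- function(x, sig = 2) 10^(floor(log10(abs(x))) - (sig - 1))

expect_within_printed <- function(computed, printed, sig = 2) {
  expect_lte(abs(computed - printed), printed_ulp(printed, sig) + 1e-15)
}

# tiny field map with every pixel inside the Petri mask (big dish)
tiny_map <- function(power = NULL, e = NULL, h = NULL, n = 2) {
  field_map(power = power, e = e, h = h, pixel_size_m = 1e-3,
            petri_diameter_m = 1)
}

cplx <- function(m) matrix(as.complex(m), nrow = nrow(m))
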