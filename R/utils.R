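# Internal helpers shared across modules.

# Round half away from zero (the convention used for all printed percentages;
# base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Percentage of count/denom at a given printed precision; 0/0 -> 0.
pct <- function(count, denom, digits = 1) {
  p <- 100 * count / denom
  p[!is.finite(p)] <- 0
  round_half_up(p, digits)
}

abort_zf <- function(msg, class) {
  rlang::abort(msg, class = c(class, "zfsurvey_error"))
}
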