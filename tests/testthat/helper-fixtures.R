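# Shared fixture builders. Everything is generated in code; no data files.

# EEM whose emission spectrum is I(em) = em/1000 at every excitation.
linear_emission_eem <- function(em = 300:600, ex = seq(250, 500, 10)) {
  new_eem(matrix(rep(em / 1000, length(ex)), ncol = length(ex)), em, ex,
          sample_id = "linear")
}

uniform_eem <- function(value = 1, em = 300:600, ex = seq(250, 500, 10)) {
  new_eem(matrix(value, length(em), length(ex)), em, ex,
          sample_id = "uniform")
}

# Two-Gaussian mixture used across modules: long-emission component with
# amplitude 2 (em 510/60), short with amplitude 1 (em 400/40), both with
# flat-enough excitation profiles centered at 320 nm.
example_components <- function() {
  dplyr::bind_rows(
    fluor_component(2, ex_mean = 320, ex_sd = 60, em_mean = 510, em_sd = 60),
    fluor_component(1, ex_mean = 320, ex_sd = 60, em_mean = 400, em_sd = 40))
}

# Sample table lying exactly on DOC = b0 + b1*A254 + b2*A254*P.
exact_arint_table <- function(n = 50, b0 = 1, b1 = 0.5, b2 = -0.2,
                              p_range = c(0.2, 1)) {
  p <- seq(p_range[1], p_range[2], length.out = n)
  a254 <- seq(2, 30, length.out = n)
  tibble::tibble(sample_id = as.character(seq_len(n)),
                 arix = p, a254 = a254,
                 doc = b0 + b1 * a254 + b2 * a254 * p)
}
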