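# shared fixtures, built once per test run

base_params <- load_parameters()

# deterministic life tables for analytic checks
flat_lifetable <- function(q_annual) {
  tibble::tibble(age = 0:110, qx_male = q_annual, qx_female = q_annual)
}

zero_mortality_params <- function(...) {
  nbd_parameters(..., lifetable = flat_lifetable(0))
}

# a tiny mapping model with known level probabilities for every dimension:
# wraps fixed probability rows in the eq5d_mapping degenerate-free interface
fixed_prob_mapping <- function(prob_rows) {
  # prob_rows: 5 x 5 matrix (dimension x level)
  fits <- lapply(seq_len(5), function(d) {
    list(type = "fixed", probs = prob_rows[d, ], levels = 1:5, converged = TRUE)
  })
  names(fits) <- c("mo", "sc", "ua", "pd", "ad")
  structure(list(dimensions = fits, reference = "fixed"), class = "eq5d_mapping")
}
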