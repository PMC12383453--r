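# small planted regression cohort for pipeline tests
planted_rows <- function(n = 300, noise = 1, seed = 41) {
  set.seed(seed)
  x1 <- runif(n); x2 <- runif(n); x3 <- runif(n)
  data.frame(arc_id = sprintf("A%04d", seq_len(n)),
             treatment_date = as.Date("2021-01-01") + seq_len(n),
             f1 = x1, f2 = x2, f3 = x3,
             measured_gpr = pmin(100, pmax(70, 97 - 8 * x1 + 3 * x2 +
                                             rnorm(n, 0, noise))),
             stringsAsFactors = FALSE)
}

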