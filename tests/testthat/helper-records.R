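# Build a minimal valid incubation record for unit tests.
make_record <- function(c0 = 1000, n0 = natural_abundance(),
                        ct = NULL, nt = NULL,
                        ci = 20, spike = 20, f15 = NULL,
                        t_h = 12, light = "dark", depth_m = 25,
                        replicate = 1L) {
  if (is.null(f15)) {
    f15 <- (ci * natural_abundance() + spike * 0.98) / (ci + spike)
  }
  if (is.null(ct)) ct <- c0
  if (is.null(nt)) nt <- n0
  tibble::tibble(
    depth_m = depth_m, light = light, replicate = replicate, t_h = t_h,
    c0_product = c0, n0_product = n0, ct_product = ct, nt_product = nt,
    ci_substrate = ci, ct_tracer = spike, n_substrate = f15
  )
}

# Random-but-physical records for property tests (call set.seed first).
random_records <- function(n) {
  f15 <- stats::runif(n, 0.05, 0.95)
  n0 <- natural_abundance()
  tibble::tibble(
    depth_m = stats::runif(n, 5, 150),
    light = sample(c("light", "dark"), n, replace = TRUE),
    replicate = seq_len(n),
    t_h = stats::runif(n, 2, 24),
    c0_product = stats::runif(n, 50, 5000),
    n0_product = n0,
    ct_product = stats::runif(n, 50, 5000),
    nt_product = stats::runif(n, n0, 0.05),
    ci_substrate = stats::runif(n, 1, 500),
    ct_tracer = stats::runif(n, 0, 100),
    n_substrate = f15
  )
}
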