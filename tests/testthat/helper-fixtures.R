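# Shared fixtures, built once per test run and cached. The heavy
# JSTA-vs-watershed comparison (three simulated replicates) backs several
# acceptance properties, so it is computed lazily and reused.

fixture_env <- new.env(parent = emptyenv())

# a small, fast tissue for unit tests
small_tissue <- function() {
  if (is.null(fixture_env$small)) {
    tax <- sample_reference_cells(synthetic_taxonomy(6, 20, seed = 42),
                                  40, seed = 7)
    fixture_env$small <- simulate_tissue(
      tax, sim_params(extent = c(30, 30, 12), seed = 11))
  }
  fixture_env$small
}

# three desk-scale replicates: 60 x 60 x 20 um, 1 um pixels, 6 types,
# 20 genes, the simulation EM schedule (5 training rounds x 5 iterations)
accept_replicates <- function() {
  if (is.null(fixture_env$accept)) {
    fixture_env$accept <- lapply(1:3, function(r) {
      tax <- sample_reference_cells(synthetic_taxonomy(6, 20, seed = 100 + r),
                                    50, seed = 200 + r)
      tt <- simulate_tissue(tax, sim_params(extent = c(60, 60, 20),
                                            seed = 300 + r))
      st <- run_jsta(tt$spots, tt$nuclei, tax, pixel_size = 1,
                     params = reassignment_params("simulation",
                                                  seed = 400 + r))
      wb <- watershed_baseline(st$grid, tt$nuclei, st$E_p)
      list(truth = tt, jsta = st, watershed = wb,
           acc_jsta = assignment_accuracy(st, tt),
           acc_watershed = assignment_accuracy(wb, tt))
    })
  }
  fixture_env$accept
}

# brute-force two-pass z-score, written independently of the package
oracle_harmonize <- function(E) {
  z1 <- t(apply(E, 1, function(v) {
    s <- sqrt(mean((v - mean(v))^2)); if (s == 0) s <- 1
    (v - mean(v)) / s
  }))
  apply(z1, 2, function(v) {
    s <- sqrt(mean((v - mean(v))^2)); if (s == 0) s <- 1
    (v - mean(v)) / s
  })
}

# brute-force Benjamini-Hochberg, independent of stats::p.adjust
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}
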