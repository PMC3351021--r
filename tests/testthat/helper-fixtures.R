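# shared fixtures, built once per test run and memoized

.fixture_env <- new.env()

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# two well-separated gaussian blobs, for forest contract tests
blob_xy <- function(n_per = 100, p = 5, shift = 4, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = shift), n_per, p))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = rep(c("a", "b"), each = n_per))
}

# feature table where exactly one column carries the class signal
planted_signal_xy <- function(n_per = 150, p_noise = 30, shift = 3,
                              seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  x <- matrix(rnorm(n * p_noise), n, p_noise)
  signal <- c(rnorm(n_per, 0), rnorm(n_per, shift))
  x <- cbind(x, signal)
  colnames(x) <- c(paste0("noise", seq_len(p_noise)), "signal")
  list(x = x, y = rep(c("a", "b"), each = n_per))
}

# small strong-preset world with features, shared across cascade/eval tests
small_strong <- function() {
  memo("small_strong", {
    spec <- separability_preset("strong", seqs_per_sub = 30L,
                                non_enzyme_n = 120L, seed = 5L)
    dat <- generate_synthetic(spec)
    x <- extract_table(dat$records)
    list(x = x, labels = dat$records$label, spec = spec,
         records = dat$records)
  })
}

random_seq <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"),
               len, replace = TRUE), collapse = "")
}

write_tmp_fasta <- function(text) {
  f <- tempfile(fileext = ".fasta")
  writeLines(text, f)
  f
}
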