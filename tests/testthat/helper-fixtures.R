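# Shared fixture builders for the test suite. All fixtures are generated in
# code under fixed seeds; heavy simulation batches are cached per session.

random_freq_table <- function(n = 50, K = 3, chroms = c("2L", "2R"),
                              depth = TRUE, seed = 1) {
  set.seed(seed)
  chrom <- sort(sample(chroms, n, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n), chrom), function(i) {
    sort(sample.int(1e6, length(i)))
  }), use.names = FALSE)
  f <- matrix(runif(n * K), n, K)
  d <- if (depth) matrix(sample(20:200, n * K, replace = TRUE), n, K) else NULL
  freq_table(as.character(sort(chrom)), pos, f, d,
             t_labels = paste0("t", seq_len(K) - 1))
}

write_sync_lines <- function(lines) {
  path <- tempfile(fileext = ".sync")
  writeLines(lines, path)
  path
}

# session cache for expensive simulation batches shared across test blocks
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# one desk-scale replicate batch per regime; replicate k gets chromosome
# label repk so block bootstraps never span replicates
regime_batch <- function(regime, n_reps, seed_base, ...) {
  cached(paste0(regime, "_", n_reps, "_", seed_base), {
    lapply(seq_len(n_reps), function(k) {
      run_regime(desk_params(regime, seed = seed_base + k, ...),
                 chrom = paste0("rep", k))
    })
  })
}

pool_tables <- function(batch) {
  tabs <- lapply(batch, `[[`, "table")
  df <- do.call(rbind, lapply(tabs, as.data.frame))
  structure(df, t_labels = t_labels(tabs[[1]]),
            class = c("freq_table", "data.frame"))
}
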