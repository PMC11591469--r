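# Shared fixtures.  The default synthetic dataset and the expensive trained
# fits are computed once per test run and cached in this environment.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

default_fixture <- function() {
  cached("fixture", simulate_mda_data(synthetic_spec()))
}

# Small dataset for fast end-to-end tests.
tiny_dataset <- function(seed = 7L) {
  cached(paste0("tiny", seed),
         simulate_mda_data(synthetic_spec(m = 20, n = 15, rank = 3,
                                          density = 0.15, seed = seed)))
}

# Compact configuration for fast training tests; the vignette documents the
# reduced problem sizes used by the checks.
fast_config <- function(...) {
  args <- utils::modifyList(list(dim = 8L, heads = 2L, max_epochs = 40L,
                                 patience = 15L, refit_epochs = 30L,
                                 n_init = 1L), list(...))
  do.call(mda_config, args)
}

# The configuration used for the synthetic-recovery and ablation checks.
recovery_config <- function(...) {
  mda_config(dim = 32L, heads = 4L, max_epochs = 100L, patience = 30L, ...)
}

recovery_fits <- function() {
  cached("recovery_fits", {
    dat <- default_fixture()
    lapply(1:3, function(s) {
      train_mda(dat$assoc, dat$m_sim, dat$d_sim, config = recovery_config(),
                seed = s)
    })
  })
}

edge_df <- function(...) {
  m <- rbind(...)
  data.frame(mirna = m[, 1], disease = m[, 2], stringsAsFactors = FALSE)
}
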