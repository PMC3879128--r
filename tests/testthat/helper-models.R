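# Shared model fixtures, built once per test run. Keys name the study
# condition; every parameter choice is explicit.

.model_cache <- new.env(parent = emptyenv())

cached_model <- function(key, params) {
  mod <- get0(key, envir = .model_cache, inherits = FALSE)
  if (is.null(mod)) {
    mod <- build_model(params)
    assign(key, mod, envir = .model_cache)
  }
  mod
}

# single motor, noiseless, zero load: closed-form regime
model_m1 <- function() cached_model("m1", motor_params(m_bar = 1, sigma_th = 0))

# two motors, thermal noise, reference sub-stall load for step statistics
model_m2 <- function() cached_model("m2", motor_params(m_bar = 2, F_load = 0.003))

# two motors, thermal noise, zero load (oracle comparisons)
model_m2f0 <- function() cached_model("m2f0", motor_params(m_bar = 2))

# three motors, thermal noise, zero load (steady-state checks)
model_m3 <- function() cached_model("m3", motor_params(m_bar = 3))

# brute-force count of relative configurations: multisets of m motor
# positions drawn from sites 1..n that contain site 1 (independent of the
# package's recursive enumeration)
brute_force_count <- function(m_bar, n) {
  total <- 0L
  for (m in seq_len(m_bar)) {
    grids <- expand.grid(rep(list(seq_len(n)), m))
    keys <- unique(apply(as.matrix(grids), 1, function(r) paste(sort(r), collapse = ",")))
    total <- total + sum(vapply(strsplit(keys, ","), function(k) k[1] == "1", NA))
  }
  total + 1L
}
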