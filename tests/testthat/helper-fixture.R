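# Shared fixtures, memoised so expensive pieces are built once per test run.
.fx_cache <- new.env(parent = emptyenv())

fx_params <- function() {
  if (is.null(.fx_cache$p)) .fx_cache$p <- prepare_parameters(fixture_parameters())
  .fx_cache$p
}

fx_profile <- function() {
  if (is.null(.fx_cache$profile))
    .fx_cache$profile <- derive_renal_age_profiles(fx_params(), 5000, seed = 42)
  .fx_cache$profile
}

fx_population <- function(n = 5000, seed = 42) {
  key <- paste0("pop_", n, "_", seed)
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- init_population(n, fx_params(), fx_profile(), seed)
  .fx_cache[[key]]
}

# a minimal hand-built population for deterministic unit checks
mini_population <- function(n, age = 50L, sex = "F", gfr = 100, alb = 0L) {
  pop <- sample_age_sex(n, fx_params(), seed = 1)
  pop$age <- rep_len(as.integer(age), n)
  pop$sex <- rep_len(sex, n)
  pop$bmi_sds <- 0; pop$bmi <- 25
  pop$sbp_sds <- 0; pop$sbp <- 120
  pop$gfr <- rep_len(gfr, n)
  pop$albuminuria <- rep_len(as.integer(alb), n)
  pop$gfr_loss_factor <- 1
  pop
}
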