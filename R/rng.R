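# Deterministic substream scheme for common random numbers.
#
# Every stochastic step draws a full-length vector of uniforms for ALL
# individuals (dead or alive) from a seed derived from (master seed, a named
# stream, the cycle index). Because the derivation never involves the
# scenario arm, every arm sees the same per-individual uniforms at the same
# step of the same cycle: arms diverge only where their states make a draw
# land on a different side of a probability threshold.

.stream_registry <- c(
  age_sex = 1L, bmi = 2L, sbp = 3L, ht_drug = 4L, diabetes_prev = 5L,
  gfr_init = 6L, alb_init = 7L, loss_factor = 8L, adherence_init = 9L,
  diabetes_inc = 10L, alb_onset = 11L, alb_prog = 12L, mortality = 13L,
  test1 = 14L, test2 = 15L, adherence = 16L, new_ht_drug = 17L,
  profile = 18L, calibration = 19L
)

substream_seed <- function(master, stream, cycle = 0L) {
  id <- .stream_registry[[stream]]
  if (is.null(id)) stop("unknown random stream: ", stream)
  m <- 2147483647
  s <- (as.double(master %% m) * 48271 + as.double(id) * 16807 +
          as.double(cycle) * 69621) %% m
  as.integer(s %% (m - 2L)) + 1L
}

# Uniform draws for n individuals on a named (stream, cycle) substream.
stream_unif <- function(n, master, stream, cycle = 0L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(master, stream, cycle))
  stats::runif(n)
}

# Standard-normal draws on a substream (inverse-CDF of the uniforms, so a
# stream yields the same individuals' quantiles whether used as U or Z).
stream_norm <- function(n, master, stream, cycle = 0L) {
  stats::qnorm(stream_unif(n, master, stream, cycle))
}
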