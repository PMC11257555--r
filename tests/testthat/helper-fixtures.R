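# One shared synthetic cohort per test session (generation is seeded and
# deterministic, so every file reusing it sees identical inputs).

.fixture_env <- new.env(parent = emptyenv())

fixture_cohort <- function() {
  if (is.null(.fixture_env$gen)) {
    dir <- file.path(tempdir(), "ssub-fixture")
    .fixture_env$gen <- generateCohort(dir, seed = 20260928)
  }
  .fixture_env$gen
}

fixture_pipeline <- function() {
  if (is.null(.fixture_env$res)) {
    g <- fixture_cohort()
    out <- file.path(tempdir(), "ssub-fixture-out")
    .fixture_env$res <- suppressWarnings(runPipeline(g$dir, out))
    .fixture_env$outdir <- out
  }
  .fixture_env$res
}
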