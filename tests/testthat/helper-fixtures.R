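# Shared fixtures. The desk-scale preset runs (200 transcripts) are needed
# by several end-to-end checks; they are computed once per test session and
# cached in this environment.

.fixture_env <- new.env(parent = emptyenv())

# default study-condition preset: 200 transcripts, ~12% seen, 20% planted
# unobservable; fixed seeds
preset_data <- function() {
  if (is.null(.fixture_env$data)) {
    .fixture_env$data <- gen_dataset(generator_config(seed = 11L))
  }
  .fixture_env$data
}

preset_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    d <- preset_data()
    .fixture_env$fit <- suppressWarnings(
      synev(d$catalog, d$features, d$curated_keys,
            config = pul_config(seed = 5L)))
  }
  .fixture_env$fit
}

strong_data <- function() {
  if (is.null(.fixture_env$strong_data)) {
    .fixture_env$strong_data <-
      gen_dataset(generator_config(seed = 11L, preset = "strong_signal"))
  }
  .fixture_env$strong_data
}

strong_fit <- function() {
  if (is.null(.fixture_env$strong_fit)) {
    d <- strong_data()
    .fixture_env$strong_fit <- suppressWarnings(
      synev(d$catalog, d$features, d$curated_keys,
            config = pul_config(seed = 5L)))
  }
  .fixture_env$strong_fit
}

# a small transcript set with annotations for mid-weight tests
small_world <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- generator_config(n_transcripts = 12L, seed = 33L)
    trs <- gen_transcripts(cfg)
    catalog <- enumerate_catalog(trs)
    ann <- gen_annotations(trs, cfg, catalog = catalog)
    ref <- build_reference(trs, ann$expression)
    .fixture_env$small <- list(cfg = cfg, transcripts = trs,
                               catalog = catalog, annotations = ann,
                               reference = ref)
  }
  .fixture_env$small
}
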