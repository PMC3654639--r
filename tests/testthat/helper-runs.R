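# Shared tiny-3d simulations, computed once per test session. The normal run
# is long enough to hold two beats; the infarct runs hold one full beat.

.run_cache <- new.env(parent = emptyenv())

cached_tiny_run <- function(name = c("normal", "anterior", "inferior")) {
  name <- match.arg(name)
  if (!is.null(.run_cache[[name]])) return(.run_cache[[name]])
  cfg <- make_fixture("tiny-3d")
  cfg$solver$duration <- if (name == "normal") 1.8 else 0.9
  if (name == "anterior") cfg$lesions <- list("anterior-MI")
  if (name == "inferior") cfg$lesions <- list("inferior-MI")
  res <- run_simulation(cfg)
  .run_cache[[name]] <- res
  res
}
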