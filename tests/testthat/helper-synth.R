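# Shared small synthetic bundle, generated once per test run.
.fixtures <- new.env(parent = emptyenv())

small_bundle <- function() {
  if (is.null(.fixtures$bundle)) {
    cfg <- synthetic_config(n_sites = 4, trees_surviving = 6, trees_dead = 4,
                            seed = 101)
    .fixtures$bundle <- suppressWarnings(
      generate_dataset(cfg, file.path(tempdir(), "synth-fixture")))
    .fixtures$config <- cfg
  }
  .fixtures$bundle
}

small_config <- function() {
  small_bundle()
  .fixtures$config
}

# One site's climate and SPEI grid, cached.
site1_grid <- function() {
  if (is.null(.fixtures$grid)) {
    cl <- generate_climate(small_config(), 1)
    .fixtures$climate1 <- cl
    .fixtures$grid <- spei_grid(cl, "N")
  }
  .fixtures$grid
}

site1_climate <- function() {
  site1_grid()
  .fixtures$climate1
}
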