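# Shared fixtures, built once per test run. Everything is generated in code;
# the small 48-voxel phantom grid keeps each construction under a second.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

small_phantom <- function(seed = 1, ...) {
  fixture(paste0("phantom_", seed, "_", paste(c(...), collapse = "_")), function()
    make_phantom(phantom_spec(shape = c(48, 48, 48), seed = seed, ...)))
}

# ten jittered 64-voxel cases used by the training tests
phantom_cohort <- function() {
  fixture("cohort64", function() make_dataset(10, base_seed = 100,
                                              shape = c(64, 64, 64)))
}

# couch-removed diagnostic volume of a case
couchless_dct <- function(case) {
  remove_couch(case$dct, segment_body(case$dct))
}
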