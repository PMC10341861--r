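# Memoized default synthetic study + pipeline run, shared by the
# acceptance tests (and any module test that wants realistic inputs)
# so the expensive end-to-end computation happens once per suite run.

.study_cache <- new.env(parent = emptyenv())

default_study <- function() {
  if (is.null(.study_cache$study)) {
    dir <- file.path(tempdir(), "dmrlinc_default_study")
    unlink(dir, recursive = TRUE)
    .study_cache$study <- generate_study(sim_config(seed = 424242L), dir)
    .study_cache$study_dir <- dir
  }
  .study_cache$study
}

default_run <- function() {
  if (is.null(.study_cache$run)) {
    default_study()
    .study_cache$elapsed <- system.time(
      .study_cache$run <- run_all(.study_cache$study_dir,
                                  out_dir = file.path(tempdir(),
                                                      "dmrlinc_default_out"),
                                  seed = 171L)
    )[["elapsed"]]
  }
  .study_cache$run
}

# a small, fast study for tests that only need plumbing; ... overrides
# any default
small_config <- function(seed = 5L, ...) {
  args <- list(n_case = 5L, n_control = 5L, genome = c(chr1 = 12e6),
               n_cpg = 1200L, n_planted_dmrs = 5L, n_lnc_linked = 5L,
               n_lnc_decoy = 20L, n_prot_linked = 5L, n_prot_decoy = 20L,
               seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
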