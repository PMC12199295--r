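# shared fixtures, built once per test run

fixture_lib <- local({
  lib <- NULL
  function(n_reactions = 3L, spc = 6L, seed = 7L) {
    key <- paste(n_reactions, spc, seed)
    if (is.null(lib[[key]])) {
      lib[[key]] <<- suppressMessages(
        make_fixture_library(n_reactions, spc, seed = seed))
    }
    lib[[key]]
  }
})

# a fingerprint object with prescribed on-bits, for similarity unit tests
fp_of <- function(bits, n_bits = 1024L) {
  structure(list(bits = as.integer(sort(bits)), n_bits = n_bits),
            class = "rx_fp")
}

amide_rxn <- function() {
  rx_reaction("amide",
    "[C:1](=[O:2])[OX2H1].[NX3;H2,H1:3]>>[C:1](=[O:2])[N:3]")
}
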