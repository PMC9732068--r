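# Simulations reused across test files; cached so each (seed, duration) is
# run once per test session.
.simCache <- new.env(parent = emptyenv())

cachedSim <- function(seed, durationMin) {
    key <- sprintf("s%d_d%g", seed, durationMin)
    if (is.null(.simCache[[key]]))
        .simCache[[key]] <- simulateNetwork(buildNetwork(seed = seed),
                                            durationMin, seed = seed)
    .simCache[[key]]
}
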