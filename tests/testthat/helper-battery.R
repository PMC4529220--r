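# Desk-scale evolution battery shared across test files: 1500 generations,
# 20 agents, 5 independent seeds per architecture (seeds fixed as
# 100 * architecture-index + 1..5), VG training. Computed once per session.
desk_battery <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      archs <- c(FF = 1L, FB = 2L, LAT = 3L, FBLAT = 4L)
      cache <<- lapply(names(archs), function(a) {
        run_population(a, ea_config(generations = 1500L),
                       seeds = 100L * archs[[a]] + 1:5)
      })
      names(cache) <<- names(archs)
    }
    cache
  }
})
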