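## build the demo dataset once per test run and reuse it across files
.demoCache <- new.env(parent = emptyenv())

demoDir <- function(seed = 1L) {
  key <- paste0("d", seed)
  if (is.null(.demoCache[[key]])) {
    dir <- file.path(tempdir(), paste0("spatialTLS_demo_", seed))
    unlink(dir, recursive = TRUE)
    simulateDemo(dir, seed = seed)
    .demoCache[[key]] <- dir
  }
  .demoCache[[key]]
}
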