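# A reduced phantom used throughout the module tests: same anatomy as the
# default (ILM at row 30, RNFL band, RPE at row 90, excavated disk), but
# small enough that a full pipeline run takes about a second.
small_spec <- function(...) {
  args <- list(volume_dims = c(200L, 96L, 32L),
               ilm_base_row = 30,
               rnfl_thickness_um = 100,
               rpe_depth_row = 90,
               disk_center = c(48, 16),
               disk_radius_px = 10,
               cup_center = c(48, 16),
               cup_radius_px = 5,
               cup_depth_um = 350,
               disk_excavation_um = 400)
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_spec, args)
}

surface_abs_error <- function(detected, truth) {
  abs(unclass(detected) - unclass(truth))
}

# share one analyzed small phantom across tests in a file
analyzed_small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- generate_phantom(small_spec(cup_center = c(50, 16)))
      res <- suppressMessages(onh_analyze(ph$volume))
      cache <<- list(phantom = ph, analysis = res)
    }
    cache
  }
})
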