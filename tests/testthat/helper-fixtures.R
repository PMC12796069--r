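# Shared fixtures, built lazily and cached for the whole test run. The
# study phantom (64^3 at 3 mm, 192 mm field of view) keeps per-test cost
# low; the acceptance tests use the full-resolution 96^3 phantom.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

studySchedule <- function() defaultFrameSchedule()

studyPhantom <- function() fixture("studyPhantom", function() {
  generatePhantom(phantomSpec(grid_shape = c(64, 64, 64), voxel_size = 3,
                              noise_scale = 0))
})

studyPipeline <- function() fixture("studyPipeline", function() {
  suppressWarnings(runPipeline(studyPhantom()$series))
})

rotatedPhantom <- function() fixture("rotatedPhantom", function() {
  generatePhantom(phantomSpec(grid_shape = c(64, 64, 64), voxel_size = 3,
                              noise_scale = 0, rotation_deg = 30))
})

rotatedPipeline <- function() fixture("rotatedPipeline", function() {
  suppressWarnings(runPipeline(rotatedPhantom()$series))
})

fullPhantom <- function() fixture("fullPhantom", function() {
  generatePhantom(phantomSpec(noise_scale = 0))
})

fullPipeline <- function() fixture("fullPipeline", function() {
  suppressWarnings(runPipeline(fullPhantom()$series))
})

# flat voxel x frame matrix of a series
seriesMatrix <- function(series) {
  d <- dim(seriesData(series))
  matrix(seriesData(series), prod(d[1:3]), d[4])
}

# median of a parametric map over a ground-truth structure mask
structureMedian <- function(map, mask) median(map[mask], na.rm = TRUE)
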