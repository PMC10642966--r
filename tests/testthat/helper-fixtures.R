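# Shared fixtures, built once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# flat, uncurled, ungyrified sheet with uniform 2 mm thickness
flatSlabPhantom <- function() fixture("flat_slab", function()
  generatePhantom(phantomParams(curl_angle_rad = 1e-9, n_gyri = 0L,
                                gyral_amplitude_mm = 0,
                                thickness_profile = rep(2, 5))))

flatSlabCoords <- function() fixture("flat_slab_coords", function()
  computeCoordinates(flatSlabPhantom()$labels))

flatSlabGrid <- function() fixture("flat_slab_grid", function()
  extractMidthicknessGrid(flatSlabCoords(), flatSlabPhantom()$labels,
                          shape = c(64, 32), extent = c(40, 20)))

# default curled, gyrified phantom
defaultPhantom <- function() fixture("default_phantom", function()
  generatePhantom(phantomParams(), seed = 1))

defaultCoords <- function() fixture("default_coords", function()
  computeCoordinates(defaultPhantom()$labels))

defaultGrid <- function() fixture("default_grid", function()
  extractMidthicknessGrid(defaultCoords(), defaultPhantom()$labels,
                          shape = c(64, 32), extent = c(40, 20)))

defaultStack <- function() fixture("default_stack", function() {
  ph <- defaultPhantom()
  co <- defaultCoords()
  g <- defaultGrid()
  suppressWarnings(prepareFeatureStack(list(
    thickness = computeThickness(co, g, ph$labels),
    gyrification = computeGyrification(g),
    curvature = computeCurvature(g, co, ph$labels))))
})

dispMagnitude <- function(t) {
  sqrt(Reduce(`+`, lapply(forwardDisplacement(t), function(u) u^2)))
}

makeDiffeoForTest <- function(shape, dx) {
  new("DiffeoTransform", velocity = list(),
      disp = list(array(dx, shape), array(0, shape)),
      shape = as.integer(shape), spacing = c(1, 1), kind = "disp")
}
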