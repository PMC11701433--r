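test_that("cell tables read, validate and round-trip", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell_id,x_um,y_um,CD8,CD20",
               "a,0.5,1.5,1,0", "b,10.0,1.5,0,1", "c,20.0,3.0,0,0"), tmp)
  ct <- readCellTable(tmp, sampleId = "s")
  expect_equal(nCells(ct), 3L)
  expect_setequal(markerNames(ct), c("CD8", "CD20"))

  ## duplicate id cited by name
  writeLines(c("cell_id,x_um,y_um", "a,0,0", "a,1,1"), tmp)
  expect_error(readCellTable(tmp), "duplicate cell_id 'a'")
  ## missing column named
  writeLines(c("cell_id,x_um", "a,0"), tmp)
  expect_error(readCellTable(tmp), "y_um")
  ## non-numeric coordinate names row and column
  writeLines(c("cell_id,x_um,y_um", "a,0,0", "b,oops,1"), tmp)
  expect_error(readCellTable(tmp), "row 2, column 'x_um'")

  ## write -> read is the identity, field for field
  sl <- simulateSlide(plantedSlideConfig(11, 1L))
  out <- withr::local_tempfile(fileext = ".csv")
  writeCellTable(sl$table, out)
  back <- readCellTable(out, sampleId = sampleId(sl$table))
  orig <- cellData(sl$table)
  got <- cellData(back)[, colnames(orig)]
  expect_equal(got, orig, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("region GeoJSON reads, validates geometry, and round-trips", {
  sq <- function(x0, y0, x1, y1) cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  rs <- RegionSet(list(list(label = "tumor", coords = sq(0, 0, 1000, 1000)),
                       list(label = "stroma",
                            coords = sq(1000, 0, 2500, 1000))), "s")
  tmp <- withr::local_tempfile(fileext = ".geojson")
  writeRegions(rs, tmp)
  back <- readRegions(tmp, sampleId = "s")
  expect_equal(regionPolygons(back), regionPolygons(rs))

  ## empty FeatureCollection -> empty RegionSet
  writeLines('{"type":"FeatureCollection","features":[]}', tmp)
  expect_length(regionPolygons(readRegions(tmp)), 0L)

  ## unknown label rejected
  writeLines(paste0('{"type":"FeatureCollection","features":[{"type":"Feature",',
                    '"properties":{"label":"weird"},"geometry":{"type":"Polygon",',
                    '"coordinates":[[[0,0],[1,0],[1,1],[0,0]]]}}]}'), tmp)
  expect_error(readRegions(tmp), "unknown region label 'weird'")

  ## self-intersecting (bow-tie) ring rejected
  bow <- list(list(label = "tumor",
                   coords = cbind(c(0, 100, 0, 100), c(0, 100, 100, 0))))
  expect_error(RegionSet(bow), "self-intersecting")
})

test_that("compartment assignment follows the closed-polygon, tumor-precedence rules", {
  sq <- function(x0, y0, x1, y1) cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  rs <- RegionSet(list(list(label = "tumor", coords = sq(0, 0, 1000, 1000)),
                       list(label = "stroma",
                            coords = sq(0, 0, 2000, 2000))), "s")
  ct <- CellTable(data.frame(cell_id = c("in", "out", "edge", "stromal"),
                             x_um = c(500, 2500, 1000, 1500),
                             y_um = c(500, 500, 500, 500)), "s")
  got <- cellData(assignCompartments(ct, rs))$compartment
  ## boundary point is inside; tumor wins over enclosing stroma
  expect_equal(got, c("tumor", "unassigned", "tumor", "stroma"))
  expect_error(assignCompartments(ct, RegionSet(list())), "non-empty")
})

test_that("compartment labels agree with a per-cell point-in-polygon oracle", {
  set.seed(99)
  poly1 <- cbind(c(100, 700, 800, 400, 120), c(100, 80, 600, 750, 500))
  poly2 <- cbind(c(500, 950, 950, 500), c(500, 500, 950, 950))
  rs <- RegionSet(list(list(label = "tumor", coords = poly1),
                       list(label = "stroma", coords = poly2)), "s")
  n <- 1000L
  ct <- CellTable(data.frame(cell_id = sprintf("c%04d", 1:n),
                             x_um = runif(n, 0, 1000),
                             y_um = runif(n, 0, 1000)), "s")
  got <- cellData(assignCompartments(ct, rs))$compartment
  df <- cellData(ct)
  want <- vapply(seq_len(n), function(i) {
    if (pipOracle(df$x_um[i], df$y_um[i], poly1)) "tumor"
    else if (pipOracle(df$x_um[i], df$y_um[i], poly2)) "stroma"
    else "unassigned"
  }, character(1L))
  expect_equal(got, want)
})

test_that("clinical and expression readers validate their contracts", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,time_months,event,score",
               "p1,10,1,0.5", "p2,20,0,-0.2"), tmp)
  clin <- readClinical(tmp)
  expect_equal(nrow(clin), 2L)
  writeLines(c("sample_id,time_months,event", "p1,-3,1"), tmp)
  expect_error(readClinical(tmp), "positive")

  m <- matrix(rnorm(12), 3L, 4L,
              dimnames = list(c("G1", "G2", "G3"),
                              sprintf("s%d", 1:4)))
  out <- withr::local_tempfile(fileext = ".csv")
  writeExpression(m, out)
  expect_equal(readExpression(out), m, tolerance = 1e-9)
  writeLines(c("gene,s1", "A,1", "A,2"), out)
  expect_error(readExpression(out), "duplicate gene")
})
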