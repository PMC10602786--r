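test_that("counts close to relative abundances and closure is idempotent", {
  m <- matrix(c(10, 10, 10,
                5, 5, 0,
                0, 0, 30), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("a", "b", "c")))
  tab <- abundance_table(m, rep("G1", 3), mode = "counts")
  rel <- to_relative(tab)
  expect_equal(unname(rel$values),
               matrix(c(1/3, 1/3, 1/3, 0.5, 0.5, 0, 0, 0, 1),
                      nrow = 3, byrow = TRUE))
  expect_identical(to_relative(rel), rel)
})

test_that("table validation rejects bad inputs", {
  m <- matrix(1:6, 2, 3, dimnames = list(NULL, c("a", "b", "a")))
  expect_error(abundance_table(m, c("G1", "G1"), mode = "counts"),
               "duplicate taxon")
  m2 <- matrix(c(-1, 2, 3, 4), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(abundance_table(m2, c("G1", "G1"), mode = "counts"),
               "non-negative")
  m3 <- matrix(c(0, 1, 0, 2), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(to_relative(abundance_table(m3, c("G1", "G1"),
                                           mode = "counts")),
               "degenerate")
  # relative rows must close
  m4 <- matrix(c(0.5, 0.4, 0.5, 0.5), 2, 2,
               dimnames = list(NULL, c("a", "b")))
  expect_error(abundance_table(m4, c("G1", "G1"), mode = "relative"),
               "sum to 1")
})

test_that("abundance tables round-trip through TSV exactly", {
  set.seed(3)
  m <- matrix(runif(24), 4, 6,
              dimnames = list(paste0("G", rep(1:2, each = 2), "_r", 1:2),
                              paste0("tax", 1:6)))
  tab <- to_relative(abundance_table(m, rep(c("G1", "G2"), each = 2),
                                     rep(1:2, 2), mode = "counts"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(tab, path)
  back <- read_abundance_table(path, mode = "relative")
  expect_identical(back$values, tab$values)
  expect_identical(back$generation, tab$generation)
  expect_identical(back$replicate, tab$replicate)
})

test_that("minimal BIOM-style JSON is accepted", {
  path <- withr::local_tempfile(fileext = ".json")
  biom <- list(
    matrix_type = "sparse", shape = c(2, 3),
    rows = list(list(id = "taxA"), list(id = "taxB")),
    columns = list(list(id = "s1", metadata = list(generation = "G1")),
                   list(id = "s2", metadata = list(generation = "G1")),
                   list(id = "s3", metadata = list(generation = "G2"))),
    data = list(c(0, 0, 5), c(0, 2, 3), c(1, 1, 7)))
  jsonlite::write_json(biom, path, auto_unbox = TRUE)
  tab <- read_abundance_table(path, dialect = "biom")
  expect_equal(dim(tab), c(3L, 2L))
  expect_equal(tab$values["s1", "taxA"], 5)
  expect_equal(tab$values["s2", "taxB"], 7)
  expect_equal(tab$generation, c("G1", "G1", "G2"))
})

test_that("degradation efficiency follows the residual-mass ratio", {
  expect_equal(degradation_efficiency(10, 5), 0.5)
  expect_equal(degradation_efficiency(10, 10), 0)
  expect_equal(degradation_efficiency(8.0, 5.416), 0.323)
  # negative efficiencies reported, never clipped
  expect_equal(degradation_efficiency(10, 12), -0.2)
  expect_true(all(degradation_efficiency(runif(50, 1, 10),
                                         runif(50, 0, 10)) <= 1))
  expect_error(degradation_efficiency(0, 1), "positive")
})

test_that("degradation records round-trip through CSV", {
  rec <- degradation_record(
    sample_id = c("G1_r1", "G1_r2"), generation = "G1", replicate = 1:2,
    fraction = "TPH", residual_control = c(1, 1),
    residual_treatment = c(0.6771, 0.71))
  expect_equal(rec$efficiency, c(0.3229, 0.29))
  path <- withr::local_tempfile(fileext = ".csv")
  write_degradation_records(rec, path)
  back <- read_degradation_records(path)
  expect_equal(back$efficiency, rec$efficiency)
  expect_identical(back$sample_id, rec$sample_id)
})

test_that("networks round-trip exactly in both formats", {
  set.seed(11)
  nodes <- paste0("g", 1:7)
  edges <- data.frame(taxon_a = c("g1", "g2", "g3", "g1", "g5"),
                      taxon_b = c("g2", "g3", "g4", "g4", "g6"),
                      sign = c("+", "-", "+", "+", "-"),
                      weight = runif(5, 0.1, 3),
                      q = runif(5, 0, 0.05))
  net <- consortium_network(nodes, edges)
  for (fmt in c("edgelist", "graphml")) {
    path <- withr::local_tempfile(
      fileext = paste0(".", ifelse(fmt == "graphml", "graphml", "tsv")))
    write_network(net, path, format = fmt)
    back <- read_network(path, format = fmt)
    expect_identical(back$nodes, net$nodes)
    expect_identical(back$edges, net$edges)
  }
  # empty network keeps its declared node set
  empty <- consortium_network(nodes)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(empty, path, format = "edgelist")
  back <- read_network(path)
  expect_identical(back$nodes, nodes)
  expect_equal(nrow(back$edges), 0L)
})

test_that("network invariants are enforced", {
  expect_error(consortium_network("a", data.frame(
    taxon_a = "a", taxon_b = "a", sign = "+", weight = 1, q = 0.01)),
    "self-edges")
  expect_error(consortium_network(c("a", "b"), data.frame(
    taxon_a = c("a", "b"), taxon_b = c("b", "a"),
    sign = "+", weight = 1, q = 0.01)),
    "one edge per")
  expect_error(consortium_network(c("a", "b"), data.frame(
    taxon_a = "a", taxon_b = "c", sign = "+", weight = 1, q = 0.01)),
    "node set")
})
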