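test_that("single-record parse collapses atoms and orders endpoints canonically", {
  tab <- parse_contact_table("0\thbbb\tA:ARG:333:NH1\tA:GLU:329:OE1", "r1")
  expect_s3_class(tab, "contact_table")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$frame, 0L)
  expect_equal(tab$res_a, "A:GLU:329")
  expect_equal(tab$res_b, "A:ARG:333")
  expect_equal(attr(tab, "n_frames"), 1L)
})

test_that("contacts between the same residue pair via different atoms dedup to one edge", {
  lines <- c("# header",
             "0\thbbb\tA:ARG:333:NH1\tA:GLU:329:OE1",
             "0\thbsb\tA:ARG:333:NE\tA:GLU:329:OE2")
  tab <- parse_contact_table(lines, "r1")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$type, "hbbb,hbsb")  # interaction types kept as metadata
})

test_that("parser reports malformed lines by number and rejects empty input", {
  expect_error(parse_contact_table(c("# c", "0\thb\tA:A:1:X"), "r"),
               "line 2")
  expect_error(parse_contact_table(c("x\thb\tA:A:1:X\tA:B:2:Y"), "r"),
               "non-integer frame")
  expect_error(parse_contact_table(character(0), "r"), "empty")
  expect_error(parse_contact_table("# only comments", "r"), "empty")
})

test_that("write -> parse round-trips a synthetic table exactly", {
  spec <- generator_spec(n_systems = 1, replicas_per_system = 1,
                         n_frames = 40, n_residues = 20,
                         states = matrix(runif(30, 0.3, 0.7), 30, 1),
                         boundaries = integer(0), flip_noise = 0.05,
                         seed = 11)
  tab <- generate_ensemble(spec)$tables[[1]]
  expect_gt(nrow(tab), 100)
  path <- tempfile(fileext = ".tsv")
  write_contact_table(tab, path)
  back <- parse_contact_table(path, attr(tab, "replica_id"))
  plain <- function(t) data.frame(t[, c("frame", "type", "res_a", "res_b")])
  expect_equal(plain(back), plain(tab))
  expect_equal(attr(back, "n_frames"), attr(tab, "n_frames"))
})

test_that("vocabulary is the sorted union of pairs and row-order invariant", {
  t1 <- parse_contact_table("0\thb\tA:ALA:1:CB\tA:GLY:5:CA", "a")
  t2 <- parse_contact_table("0\thb\tA:GLY:5:CA\tA:VAL:9:CB", "b")
  v <- build_vocabulary(list(t1, t2))
  expect_equal(v$key, c("A:ALA:1--A:GLY:5", "A:GLY:5--A:VAL:9"))
  expect_equal(build_vocabulary(list(t2, t1))$key, v$key)
  expect_equal(build_vocabulary(t1)$key, "A:ALA:1--A:GLY:5")

  lines <- c("3\thb\tA:LYS:7:NZ\tA:ASP:2:OD1",
             "0\tvdw\tA:ALA:1:CB\tA:LYS:7:NZ",
             "1\thb\tA:ASP:2:OD1\tA:LYS:7:NZ")
  v1 <- build_vocabulary(parse_contact_table(lines, "x"))
  v2 <- build_vocabulary(parse_contact_table(rev(lines), "x"))
  expect_identical(v1$key, v2$key)
})

test_that("occupancy matrix matches contact counts and handles empty frames", {
  tab <- parse_contact_table("0\thb\tA:ALA:1:CB\tA:GLY:5:CA", "r",
                             n_frames = 2)
  v <- build_vocabulary(tab)
  occ <- to_occupancy(tab, v)
  expect_identical(occ$matrix, matrix(c(1L, 0L), 2, 1,
                                      dimnames = list(NULL, v$key)))

  spec <- generator_spec(n_systems = 1, replicas_per_system = 2,
                         n_frames = 60, n_residues = 15,
                         states = matrix(runif(25, 0.2, 0.8), 25, 1),
                         boundaries = integer(0), seed = 3)
  tabs <- generate_ensemble(spec)$tables
  vv <- build_vocabulary(tabs)
  for (tab in tabs) {
    occ <- to_occupancy(tab, vv)
    counts <- table(factor(pair_key <- paste(tab$res_a, tab$res_b, sep = "--"),
                           levels = vv$key))
    expect_equal(unname(colSums(occ$matrix)), as.vector(counts))
  }
})

test_that("occupancy construction rejects pairs outside the vocabulary", {
  t1 <- parse_contact_table("0\thb\tA:ALA:1:CB\tA:GLY:5:CA", "a")
  t2 <- parse_contact_table("0\thb\tA:GLY:5:CA\tA:VAL:9:CB", "b")
  v1 <- build_vocabulary(t1)
  expect_error(to_occupancy(t2, v1), "not in vocabulary")
})

test_that("frame graphs keep the full node set and mirror the matrix", {
  lines <- c("0\thb\tA:ALA:1:CB\tA:GLY:5:CA",
             "2\thb\tA:GLY:5:CA\tA:VAL:9:CB")
  tab <- parse_contact_table(lines, "r", n_frames = 3)
  occ <- to_occupancy(tab, build_vocabulary(tab))
  gs <- to_frame_graphs(occ)
  expect_length(gs, 3L)
  expect_equal(gs[[1]]$nodes, c("A:ALA:1", "A:GLY:5", "A:VAL:9"))
  expect_equal(nrow(gs[[2]]$edges), 0L)       # empty frame keeps all nodes
  expect_equal(length(gs[[2]]$nodes), 3L)
  expect_equal(sum(vapply(gs, function(g) nrow(g$edges), integer(1))),
               sum(occ$matrix))
})

test_that("coarse-grained builder applies the radius and cutoff conventions", {
  # beads at controlled distances from a mutation site at the origin
  mk <- function(xs, frame = 0) data.frame(
    frame = frame, chain = "A", resname = "BEA", resid = seq_along(xs),
    x = xs, y = 0, z = 0)
  coords <- mk(c(0, 5, 12, 16))   # site, 5 A, 12 A, 16 A
  tab <- build_cg_contacts(coords, "A:BEA:1")
  # bead 4 at 16 A > 15 A is excluded from the node set
  expect_false(any(grepl(":4$", c(tab$res_a, tab$res_b))))
  # 5 A < 6 A -> edge present; 7 A apart (5 vs 12) -> no edge
  expect_true("A:BEA:1--A:BEA:2" %in% paste(tab$res_a, tab$res_b, sep = "--"))
  expect_false("A:BEA:2--A:BEA:3" %in% paste(tab$res_a, tab$res_b, sep = "--"))
  expect_error(build_cg_contacts(coords, "A:BEA:99"), "unknown mutation site")
})

test_that("coarse-grained edge set is invariant under bead permutation", {
  set.seed(42)
  beads <- make_toy_beads(n_frames = 3, n_beads = 10, seed = 5)
  t1 <- build_cg_contacts(beads, "A:BEA:3")
  t2 <- build_cg_contacts(beads[sample.int(nrow(beads)), ], "A:BEA:3")
  expect_equal(as.data.frame(t1), as.data.frame(t2))
})

test_that("parse -> occupancy -> graphs is invariant to input row order", {
  spec <- generator_spec(n_systems = 1, replicas_per_system = 1,
                         n_frames = 25, n_residues = 12,
                         states = matrix(runif(20, 0.3, 0.7), 20, 1),
                         boundaries = integer(0), seed = 8)
  tab <- generate_ensemble(spec)$tables[[1]]
  lines <- readLines({p <- tempfile(); write_contact_table(tab, p); p})
  header <- grepl("^#", lines)
  set.seed(1)
  shuffled <- c(lines[header], sample(lines[!header]))
  t1 <- parse_contact_table(lines, "r")
  t2 <- parse_contact_table(shuffled, "r")
  expect_equal(as.data.frame(t1), as.data.frame(t2))
})
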