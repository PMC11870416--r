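test_that("loading assigns roles and validates sample locations", {
  arg <- twoTipTree()
  expect_s4_class(arg, "SpatialARG")
  expect_equal(length(sampleIds(arg)), 2L)
  expect_equal(recombinationNodes(arg), integer(0))
  expect_equal(rootIds(arg), 2L)

  f1 <- oneLoopArg()
  expect_equal(recombinationNodes(f1), 4L)
  expect_equal(nodeTable(f1)$role[nodeTable(f1)$id == 4], "recombination")
  expect_equal(rootIds(f1), 6L)

  # a sample without a location row is refused, naming the node
  expect_error(
    spatialARG(data.frame(id = 0:2, time = c(0, 0, 1),
                          is_sample = c(TRUE, TRUE, FALSE)),
               data.frame(parent = 2L, child = 0:1, left = 0, right = 10),
               data.frame(node_id = 0L, x = 0)),
    "missing location.*1")

  # an edge whose parent is not older than its child is structurally invalid
  expect_error(
    spatialARG(data.frame(id = 0:1, time = c(0, 0),
                          is_sample = c(TRUE, FALSE)),
               data.frame(parent = 1L, child = 0L, left = 0, right = 10),
               data.frame(node_id = 0L, x = 0)),
    "strictly older")

  # more than two parents is invalid
  expect_error(
    spatialARG(data.frame(id = 0:3, time = c(0, 1, 1, 1),
                          is_sample = c(TRUE, FALSE, FALSE, FALSE)),
               data.frame(parent = 1:3, child = 0L,
                          left = c(0, 10, 20), right = c(10, 20, 30)),
               data.frame(node_id = 0L, x = 0)),
    "more than 2 parents")
})

test_that("chopping truncates spanning edges and creates roots at the cutoff", {
  # cutoff older than the oldest node: unchanged with a notice
  arg <- twoTipTree(T = 100)
  expect_message(out <- chopArg(arg, 2000), "unchanged")
  expect_equal(nodeTable(out), nodeTable(arg))

  # two lineages uncoalesced at the cutoff: two fresh roots exactly there
  out <- chopArg(arg, 50)
  expect_equal(length(rootIds(out)), 2L)
  expect_true(all(nodeTable(out)$time[nodeTable(out)$role == "root"] == 50))
  # fresh ids above all existing ids
  expect_true(all(rootIds(out) > max(nodeTable(arg)$id)))

  # idempotence: chopping again at the same time is a no-op
  out2 <- suppressMessages(chopArg(out, 50))
  expect_identical(nodeTable(out2), nodeTable(out))
  expect_identical(edgeTable(out2), edgeTable(out))

  # on a simulated ARG all root times equal the cutoff or are older-history
  # coalescences below it
  sim <- simulateModelArg(ns = 8, targetRecombinations = 3, seed = 42)
  cut <- max(nodeTable(sim)$time) * 0.3
  ch <- chopArg(sim, cut)
  rt <- nodeTable(ch)$time[match(rootIds(ch), nodeTable(ch)$id)]
  expect_true(all(rt <= cut + 1e-12))
  expect_true(max(nodeTable(ch)$time) <= cut)
})

test_that("findLoops returns one constraint per closing recombination node", {
  expect_length(findLoops(twoTipTree()), 0L)

  lp <- findLoops(oneLoopArg())
  expect_length(lp, 1L)
  expect_equal(lp[[1]]@recombinationNode, 4L)
  expect_equal(lp[[1]]@topNode, 6L)
  sides <- list(lp[[1]]@leftPath, lp[[1]]@rightPath)
  expect_setequal(vapply(sides, paste, "", collapse = "-"),
                  c("6-5-4", "6-4"))
  # the two sides share only their endpoints
  expect_length(intersect(sides[[1]][-c(1, length(sides[[1]]))],
                          sides[[2]][-c(1, length(sides[[2]]))]), 0L)

  # every closing recombination node yields a constraint on random ARGs
  for (seed in 1:5) {
    arg <- simulateModelArg(ns = 5, targetRecombinations = 3, seed = seed)
    expect_length(findLoops(arg), length(recombinationNodes(arg)))
  }

  # chopping through a loop's top leaves an open, constraint-free loop
  open <- suppressMessages(chopArg(symmetricLoopArg(), 1.25))
  lp <- findLoops(open)
  expect_length(lp, 0L)
  expect_equal(attr(lp, "openLoops"), 2L)
})

test_that("write/load round trip preserves the graph bit-exactly", {
  arg <- simulateModelArg(ns = 6, targetRecombinations = 2, seed = 9, dims = 2)
  loc <- simulateLocations(arg, mu = c(0.123456789012345, -2), sigma2 = 1,
                           seed = 10, dims = 2)
  arg <- withSampleLocations(arg, loc)
  pre <- file.path(tempdir(), "rt")
  writeArg(arg, pre)
  back <- loadArg(paste0(pre, ".nodes.tsv"), paste0(pre, ".edges.tsv"),
                  paste0(pre, ".locations.csv"))
  expect_identical(nodeTable(back), nodeTable(arg))
  expect_identical(edgeTable(back), edgeTable(arg))
  expect_identical(sampleLocations(back), sampleLocations(arg))
  expect_identical(sequenceLength(back), sequenceLength(arg))
})

test_that("window extraction and marginal trees follow the breakpoints", {
  arg <- oneLoopArg(b = 50)
  expect_equal(treeBreakpoints(arg), c(0, 50, 100))
  expect_equal(treeIndexAt(arg, 0), 1L)
  expect_equal(treeIndexAt(arg, 50), 2L)
  expect_error(treeIndexAt(arg, 100), "outside")

  left <- marginalTree(arg, 10)
  expect_equal(recombinationNodes(left), integer(0))
  # in the left tree, E's parent is F
  expect_true(any(edgeTable(left)$parent == 5 & edgeTable(left)$child == 4))
  expect_false(any(edgeTable(left)$parent == 6 & edgeTable(left)$child == 4))

  whole <- extractWindow(arg, 0, 100)
  expect_equal(sort(nodeTable(whole)$id), sort(nodeTable(arg)$id))
})

test_that("simplifyArg contracts unary pass-through chains only", {
  # chain: sample 0 - unary 1 - unary 2 - root 3
  arg <- spatialARG(
    data.frame(id = 0:3, time = 0:3,
               is_sample = c(TRUE, FALSE, FALSE, FALSE)),
    data.frame(parent = 1:3, child = 0:2, left = 0, right = 10),
    data.frame(node_id = 0L, x = 0))
  s <- simplifyArg(arg)
  expect_equal(sort(nodeTable(s)$id), c(0L, 3L))
  expect_equal(edgeTable(s),
               data.frame(parent = 3L, child = 0L, left = 0, right = 10))

  # recombination and coalescent nodes survive
  f1 <- simplifyArg(oneLoopArg())
  expect_true(4L %in% nodeTable(f1)$id)
  expect_equal(recombinationNodes(f1), 4L)
})
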