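write_tmp <- function(lines, ext = ".csv") {
  tf <- tempfile(fileext = ext)
  writeLines(lines, tf)
  tf
}

test_that("a plain 2x2 incidence matrix is parsed with correct descriptors", {
  net <- read_incidence(write_tmp(c("1,0", "1,1")))
  p <- network_properties(net)
  expect_equal(p$S_P, 2)
  expect_equal(p$S_A, 2)
  expect_equal(p$L, 3)
  expect_equal(p$C_B, 0.75)
  ds <- degree_sequences(net)
  expect_equal(sort(as.integer(ds$plant)), c(1, 2))
  expect_equal(sort(as.integer(ds$animal)), c(1, 2))
})

test_that("labelled, quantitative and tab-separated matrices are handled", {
  net <- read_incidence(write_tmp(c("x\tbee\tfly", "rose\t2\t0", "daisy\t0.5\t3"),
                                  ext = ".tsv"))
  expect_setequal(net$plant_ids, c("rose", "daisy"))
  expect_setequal(net$animal_ids, c("bee", "fly"))
  expect_equal(network_properties(net)$L, 3)  # binarized at > 0
  # transpose: the file's rows become animals, its columns plants
  tnet <- read_incidence(write_tmp(c("1,0", "1,1")), transpose = TRUE)
  expect_equal(as.integer(degree_sequences(tnet)$animal), c(1, 2))
  expect_equal(as.integer(degree_sequences(tnet)$plant), c(2, 1))
})

test_that("all-zero rows are dropped with a warning", {
  expect_warning(net <- read_incidence(write_tmp(c("1,1", "0,0", "0,1"))),
                 "all-zero")
  expect_equal(network_properties(net)$S_P, 2)
})

test_that("format errors carry a location", {
  expect_error(read_incidence(write_tmp(c("1,0", "1"))), "ragged")
  expect_error(read_incidence(write_tmp(c("1,0", "1,x"))), "row 2, column 2")
  expect_error(suppressWarnings(read_incidence(write_tmp("0,0"))), "no links")
})

test_that("incidence and edge-list writers round-trip synthetic networks", {
  for (seed in 1:3) {
    net <- generate_network(15, 12, 0.25, seed = seed)
    fi <- tempfile(fileext = ".csv")
    write_incidence(net, fi)
    back <- read_incidence(fi)
    expect_equal(back$links[order(back$links$plant, back$links$animal), ],
                 net$links[order(net$links$plant, net$links$animal), ],
                 ignore_attr = TRUE)
    fe <- tempfile(fileext = ".txt")
    write_edgelist(net, fe)
    back2 <- read_edgelist(fe)
    expect_equal(back2$links[order(back2$links$plant, back2$links$animal), ],
                 net$links[order(net$links$plant, net$links$animal), ],
                 ignore_attr = TRUE)
    # canonical output is bit-stable
    fe2 <- tempfile()
    write_edgelist(back2, fe2)
    expect_identical(readLines(fe), readLines(fe2))
  }
})

test_that("edge lists deduplicate and reject bipartite violations", {
  net <- read_edgelist(write_tmp(c("# comment", "p1 a1", "p1 a2", "p2 a1")))
  expect_equal(network_properties(net)$L, 3)
  dup <- read_edgelist(write_tmp(c("p1 a1", "p1 a1", "p2 a1")))
  expect_equal(network_properties(dup)$L, 2)
  expect_error(read_edgelist(write_tmp(c("x y", "y z"))), "bipartite violation")
})

test_that("food-web reduction follows the basal-consumer rule", {
  # 3-level chain: c eats b, b eats a -> only b-a survives
  chain <- reduce_foodweb(data.frame(consumer = c("c", "b"),
                                     resource = c("b", "a")))
  expect_equal(chain$plant_ids, "a")
  expect_equal(chain$animal_ids, "b")
  expect_equal(network_properties(chain)$L, 1)
  # omnivory: c eats a and b; b eats a -> plants {a}, animals {b, c}
  omn <- reduce_foodweb(data.frame(consumer = c("c", "c", "b"),
                                   resource = c("a", "b", "a")))
  expect_equal(omn$plant_ids, "a")
  expect_setequal(omn$animal_ids, c("b", "c"))
  expect_equal(network_properties(omn)$L, 2)
})

test_that("detritus labels force taxa onto the basal side", {
  # d consumes a, but the detritus override puts d on the plant side: its
  # outgoing link is discarded (basal taxa cannot be animals), and a, left
  # without consumers, drops out
  web <- data.frame(consumer = c("d", "e"), resource = c("a", "d"))
  red <- reduce_foodweb(web, detritus_labels = "d")
  expect_equal(red$plant_ids, "d")
  expect_equal(red$animal_ids, "e")
  expect_equal(network_properties(red)$L, 1)
})

test_that("self-loops are ignored and empty reductions signal explicitly", {
  red <- reduce_foodweb(data.frame(consumer = c("b", "b"),
                                   resource = c("b", "a")))
  expect_equal(red$plant_ids, "a")
  expect_error(reduce_foodweb(data.frame(consumer = "a", resource = "a")),
               class = "bimaxent_empty_network")
})

test_that("reducing an already-bipartite web returns it unchanged", {
  net <- generate_network(10, 8, 0.3, seed = 4)
  asweb <- data.frame(consumer = net$links$animal, resource = net$links$plant)
  red <- reduce_foodweb(asweb)
  expect_equal(red$links[order(red$links$plant, red$links$animal), ],
               net$links[order(net$links$plant, net$links$animal), ],
               ignore_attr = TRUE)
})

test_that("degree sequences always satisfy the handshake identity", {
  for (seed in 1:5) {
    net <- generate_network(20, 15, 0.2, seed = seed)
    p <- network_properties(net)
    ds <- degree_sequences(net)
    expect_equal(sum(ds$plant), p$L)
    expect_equal(sum(ds$animal), p$L)
    expect_true(all(ds$plant >= 1) && all(ds$plant <= p$S_A))
    expect_true(all(ds$animal >= 1) && all(ds$animal <= p$S_P))
    expect_gt(p$C_B, 0)
    expect_lte(p$C_B, 1)
  }
})
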