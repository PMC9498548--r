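# Causal loop diagrams: construction, polarity, cycle enumeration and the
# packaged social-determinants fixture.

test_that("diagrams are built from edges with conflict detection", {
  expect_length(causal_diagram(list())$nodes, 0L)

  d <- causal_diagram(list(signed_edge("A", "B", 1),
                           signed_edge("B", "A", -1)))
  expect_setequal(d$nodes, c("A", "B"))
  expect_equal(nrow(d$edges), 2L)

  expect_error(causal_diagram(list(signed_edge("A", "B", 1),
                                   signed_edge("A", "B", -1))),
               "conflicting")
  # an exact duplicate is collapsed, not an error
  dup <- causal_diagram(list(signed_edge("A", "B", 1),
                             signed_edge("A", "B", 1)))
  expect_equal(nrow(dup$edges), 1L)
})

test_that("loop polarity is the sign product, and flipping one edge flips it", {
  expect_equal(loop_polarity(c(1L, 1L, 1L, 1L)), "reinforcing")
  expect_equal(loop_polarity(c(1L, -1L, 1L)), "balancing")
  expect_equal(loop_polarity(c(-1L, -1L, 1L)), "reinforcing")

  set.seed(42)
  for (i in 1:20) {
    signs <- sample(c(-1L, 1L), sample(2:6, 1L), replace = TRUE)
    j <- sample(length(signs), 1L)
    flipped <- signs
    flipped[j] <- -flipped[j]
    expect_false(loop_polarity(signs) == loop_polarity(flipped))
  }
})

test_that("simple cycles are enumerated once up to rotation", {
  tri <- causal_diagram(list(signed_edge("A", "B", 1), signed_edge("B", "C", 1),
                             signed_edge("C", "A", 1)))
  expect_length(enumerate_simple_cycles(tri), 1L)

  pair <- causal_diagram(list(signed_edge("X", "Y", 1),
                              signed_edge("Y", "X", -1)))
  loops <- enumerate_simple_cycles(pair)
  expect_length(loops, 1L)
  expect_length(loops[[1]]$cycle, 2L)
  expect_equal(loops[[1]]$polarity, "balancing")

  k3 <- causal_diagram(list(
    signed_edge("A", "B", 1), signed_edge("B", "A", 1),
    signed_edge("A", "C", 1), signed_edge("C", "A", 1),
    signed_edge("B", "C", 1), signed_edge("C", "B", 1)))
  loops <- enumerate_simple_cycles(k3)
  expect_length(loops, 5L)              # three 2-cycles, two 3-cycles
  expect_equal(cycle_keys(loops), brute_force_cycles(k3))
  expect_length(enumerate_simple_cycles(k3, max_len = 2), 3L)
  expect_error(enumerate_simple_cycles(k3, max_len = 1), "max_len")
})

test_that("enumeration agrees with brute force on random signed digraphs", {
  set.seed(1234)
  for (i in 1:40) {
    d <- random_diagram(n = sample(3:8, 1L), p = 0.35)
    expect_equal(cycle_keys(enumerate_simple_cycles(d)),
                 brute_force_cycles(d), info = paste("diagram", i))
  }
})

test_that("the social-determinants diagram carries the expected structure", {
  d <- sdoh_diagram()
  expect_true(all(c("UnderpaidEmployment", "LowIncome", "Poverty",
                    "Unemployment", "SubstandardEducation", "Stress",
                    "PoorHealth", "Morbidity", "Mortality",
                    "PublicAssistance", "LimitedAccessToCare") %in% d$nodes))
  i <- which(d$edges$src == "Poverty" & d$edges$dst == "Stress")
  expect_length(i, 1L)
  expect_equal(d$edges$sign[i], 1L)
  expect_true(all(d$edges$channel %in% c("disparity", "general")))
  expect_true(any(d$edges$channel == "disparity"))
})

test_that("labelled loops classify to six reinforcing and four balancing", {
  cls <- classify_labeled_loops(sdoh_diagram(), sdoh_loop_labels())
  pol <- setNames(cls$table$polarity, cls$table$label)
  expect_equal(unname(pol[paste0("R", 1:6)]), rep("reinforcing", 6))
  expect_equal(unname(pol[paste0("B", 1:4)]), rep("balancing", 4))
  expect_equal(cls$counts, c(reinforcing = 6L, balancing = 4L))

  two <- causal_diagram(list(signed_edge("A", "B", 1),
                             signed_edge("B", "A", -1)))
  one <- classify_labeled_loops(two, list(L1 = c("A", "B")))
  expect_equal(one$table$polarity, "balancing")

  expect_error(classify_labeled_loops(two, list(L2 = c("A", "B", "C"))),
               "L2")
})

test_that("every labelled loop is among the enumerated cycles of the fixture", {
  d <- sdoh_diagram()
  keys <- cycle_keys(enumerate_simple_cycles(d, max_len = 4))
  for (lab in names(sdoh_loop_labels())) {
    cyc <- sdoh_loop_labels()[[lab]]
    i <- which(cyc == min(cyc))[1L]
    canon <- if (i == 1L) cyc else c(cyc[i:length(cyc)], cyc[seq_len(i - 1L)])
    expect_true(paste(canon, collapse = "|") %in% keys, info = lab)
  }
})

test_that("diagrams round-trip through the edge-list format and export to DOT", {
  d <- sdoh_diagram()
  f <- tempfile(fileext = ".txt")
  write_edge_list(d, f)
  d2 <- read_edge_list(f)
  expect_equal(d2$nodes, d$nodes)
  expect_equal(d2$edges[order(d2$edges$src, d2$edges$dst), ],
               d$edges[order(d$edges$src, d$edges$dst), ],
               ignore_attr = TRUE)

  dot <- tempfile(fileext = ".dot")
  write_dot(d, dot)
  lines <- readLines(dot)
  expect_true(any(grepl("color=red", lines)))
  expect_true(any(grepl("\"Poverty\" -> \"Stress\" \\[label=\"\\+\"", lines)))
})
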