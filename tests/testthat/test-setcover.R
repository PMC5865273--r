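test_that("instances are validated on construction", {
  expect_error(set_cover_instance(c("a", "b"), list(s1 = "a")),
               "union")
  expect_error(set_cover_instance("a", list("a")), "named")
  expect_error(set_cover_instance("a", list(s1 = "a", s2 = character(0))),
               "empty")
})

test_that("build_instance inverts per-read argmax sets", {
  # the twelve-read worked instance, encoded as annotations
  argmax <- list(x1 = c("y1", "y3"), x2 = c("y1", "y4"), x3 = c("y1", "y5"),
                 x4 = c("y1", "y3"), x5 = c("y1", "y2", "y4"),
                 x6 = c("y1", "y2", "y5"), x7 = c("y3", "y4"),
                 x8 = c("y2", "y4"), x9 = c("y2", "y5"),
                 x10 = c("y3", "y6"), x11 = c("y4", "y6"), x12 = "y5")
  ann <- lapply(names(argmax), function(id)
    structure(list(read_id = id, nodes = argmax[[id]], score = 1,
                   indicator = "rand"), class = "read_annotation"))
  inst <- build_instance(ann)
  want <- example_family()
  expect_setequal(names(inst$family), names(want))
  for (nm in names(want)) expect_setequal(inst$family[[nm]], want[[nm]])

  # unambiguous reads give a partition
  ann2 <- lapply(1:4, function(i)
    structure(list(read_id = paste0("r", i),
                   nodes = paste0("n", (i + 1) %/% 2), score = 1,
                   indicator = "rand"), class = "read_annotation"))
  inst2 <- build_instance(ann2)
  expect_equal(sum(lengths(inst2$family)), length(inst2$elements))

  set.seed(53)
  for (rep in 1:5) {
    nodes <- paste0("n", 1:4)
    am <- lapply(1:6, function(i) sample(nodes, sample(1:3, 1)))
    ann3 <- lapply(seq_along(am), function(i)
      structure(list(read_id = paste0("r", i), nodes = am[[i]], score = 1,
                     indicator = "rand"), class = "read_annotation"))
    inst3 <- build_instance(ann3)
    expect_setequal(unlist(inst3$family), inst3$elements)
  }
})

test_that("greedy cover follows largest-gain with lexicographic ties", {
  g <- greedy_cover(example_instance())
  expect_equal(g$chosen, c("y1", "y4", "y5", "y3"))
  expect_equal(g$size, 4L)

  part <- set_cover_instance(c("a", "b", "c", "d"),
                             list(s1 = c("a", "b"), s2 = c("c", "d")))
  expect_setequal(greedy_cover(part)$chosen, c("s1", "s2"))
  expect_equal(greedy_cover(part)$overlap, 0L)

  set.seed(59)
  for (rep in 1:8) {
    inst <- random_instance(n_el = 7, n_sub = 5)
    g <- greedy_cover(inst)
    expect_setequal(unlist(inst$family[g$chosen]), inst$elements)
    opt <- oracle_cover(inst, "size")$obj
    expect_lte(g$size, (1 + log(length(inst$elements))) * opt)
  }
})

test_that("exact covers match the worked example and exhaustive search", {
  inst <- example_instance()
  mc <- min_cardinality_cover(inst)
  expect_equal(mc$chosen, c("y3", "y4", "y5"))
  mt <- min_total_size_cover(inst)
  expect_equal(mt$chosen, c("y3", "y4", "y5"))
  expect_equal(mt$total_size, 13L)
  expect_equal(mt$overlap, 1L)

  part <- set_cover_instance(c("a", "b"), list(s1 = "a", s2 = "b"))
  expect_setequal(min_cardinality_cover(part)$chosen, c("s1", "s2"))
  expect_equal(min_total_size_cover(part)$overlap, 0L)

  set.seed(61)
  for (rep in 1:10) {
    inst <- random_instance(n_el = sample(5:8, 1), n_sub = sample(4:7, 1))
    expect_equal(min_cardinality_cover(inst)$chosen,
                 oracle_cover(inst, "size")$chosen)
    expect_equal(min_total_size_cover(inst)$chosen,
                 oracle_cover(inst, "total")$chosen)
  }

  big <- set_cover_instance(as.character(1:41),
                            stats::setNames(as.list(as.character(1:41)),
                                            paste0("s", 1:41)))
  expect_error(min_total_size_cover(big), "greedy")
})

test_that("least total size implies least overlap", {
  set.seed(67)
  for (rep in 1:6) {
    inst <- random_instance(n_el = 6, n_sub = 5)
    mt <- min_total_size_cover(inst)
    # global minimum overlap over every cover, by exhaustion
    nm <- names(inst$family)
    best <- Inf
    for (bits in 1:(2^length(nm) - 1)) {
      sel <- nm[bitwAnd(bits, 2^(seq_along(nm) - 1)) > 0]
      if (!setequal(unlist(inst$family[sel]), inst$elements)) next
      best <- min(best, sum(lengths(inst$family[sel])) -
                          length(inst$elements))
    }
    expect_equal(mt$overlap, best)
  }
})

test_that("overlap identity holds for every solver", {
  inst <- example_instance()
  for (cv in list(greedy_cover(inst), min_cardinality_cover(inst),
                  min_total_size_cover(inst))) {
    expect_equal(cv$overlap,
                 sum(lengths(inst$family[cv$chosen])) -
                   length(inst$elements))
    expect_setequal(unlist(inst$family[cv$chosen]), inst$elements)
  }
})

test_that("the overlap-gap family separates cover size from overlap", {
  inst <- overlap_gap_instance(3)
  expect_length(inst$family, 5L)
  expect_length(inst$elements, 6L)
  expect_error(overlap_gap_instance(2), "at least 3")

  for (k in 3:6) {
    inst <- overlap_gap_instance(k)
    n <- 2L * k
    # the two near-complete subsets form a size-2 cover with overlap n - 2
    expect_setequal(unique(unlist(inst$family[c("q1", "q2")])),
                    inst$elements)
    expect_equal(sum(lengths(inst$family[c("q1", "q2")])) - n, n - 2L)
    # smallest cover has size 2; least-total-size is the perfect matching
    expect_equal(min_cardinality_cover(inst)$size, 2L)
    mt <- min_total_size_cover(inst)
    expect_equal(mt$size, k)
    expect_equal(mt$overlap, 0L)
    expect_setequal(mt$chosen, sprintf("p%02d", 1:k))
    # hence a minimum-cardinality cover can have strictly more overlap
    expect_gt(min_cardinality_cover(inst)$overlap, mt$overlap)
  }
})

test_that("reads are distributed uniformly over their covering nodes", {
  inst <- example_instance()
  mt <- min_total_size_cover(inst)
  w <- assign_reads(inst, mt)
  expect_equal(w$x7, c(y3 = 0.5, y4 = 0.5))
  expect_equal(w$x1, c(y3 = 1))
  expect_true(all(abs(vapply(w, sum, 0) - 1) < 1e-12))

  set.seed(71)
  for (rep in 1:5) {
    inst <- random_instance()
    cv <- greedy_cover(inst)
    w <- assign_reads(inst, cv)
    expect_true(all(abs(vapply(w, sum, 0) - 1) < 1e-12))
  }
})

test_that("abundance profiles are percentages summing to one hundred", {
  inst <- example_instance()
  prof <- abundance_profile(assign_reads(inst, min_total_size_cover(inst)))
  expect_equal(round(as.vector(prof[c("y3", "y4", "y5")]), 2),
               c(29.17, 37.50, 33.33))
  expect_equal(sum(prof), 100)

  one <- set_cover_instance(c("a", "b"), list(s = c("a", "b")))
  expect_equal(as.vector(
    abundance_profile(assign_reads(one, greedy_cover(one)))), 100)

  set.seed(73)
  for (rep in 1:5) {
    inst <- random_instance()
    prof <- abundance_profile(assign_reads(inst, greedy_cover(inst)))
    expect_equal(sum(prof), 100)
    expect_true(all(prof >= 0))
  }
})

test_that("profiles roll up to a requested rank", {
  f <- tempfile()
  writeLines(c("s1\tk__B; p__P1; c__C1; o__O1; f__F1; g__G1; s__A",
               "s2\tk__B; p__P1; c__C1; o__O1; f__F1; g__G1; s__B",
               "s3\tk__B; p__P2; c__C2; o__O2; f__F2; g__G2; s__C"), f)
  tr <- read_greengenes(f)
  prof <- structure(c(s1 = 50, s2 = 25, s3 = 25), class = "abundance_profile")
  up <- rollup_profile(tr, prof, "phylum")
  expect_equal(as.vector(up[c("p__P1", "p__P2")]), c(75, 25))
  expect_equal(sum(up), 100)

  # everything under one phylum collapses to it
  prof2 <- structure(c(s1 = 60, s2 = 40), class = "abundance_profile")
  expect_equal(as.vector(rollup_profile(tr, prof2, "phylum")["p__P1"]), 100)

  expect_error(rollup_profile(tr, prof, "superkingdom"), "rank")

  # a node with no ranked ancestor aggregates under Other, total preserved
  prof3 <- structure(c(s1 = 90, root = 10), class = "abundance_profile")
  up3 <- rollup_profile(tr, prof3, "phylum")
  expect_equal(as.vector(up3["Other"]), 10)
  expect_equal(sum(up3), 100)

  # nodes with no ranked ancestor fall into the Other bucket
  tr2 <- complete_binary_tree(4)  # no ranks at all -> error path
  expect_error(rollup_profile(tr2, prof, "phylum"), "rank")
})

test_that("cover and profile writers emit parseable TSV", {
  inst <- example_instance()
  mt <- min_total_size_cover(inst)
  f1 <- tempfile(); f2 <- tempfile()
  write_cover(inst, mt, f1)
  cov <- utils::read.delim(f1, stringsAsFactors = FALSE)
  expect_equal(cov$node, c("y3", "y4", "y5"))
  write_profile(abundance_profile(assign_reads(inst, mt)), f2)
  prof <- utils::read.delim(f2, colClasses = c("character", "character",
                                               "numeric"))
  expect_equal(prof$abundance_pct[prof$node == "y4"], "37.50")
  expect_equal(sum(prof$abundance), 100)
})
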