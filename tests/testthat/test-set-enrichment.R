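test_that("Fisher over-representation matches brute-force enumeration", {
  r <- fisherEnrichment(universe = 20, k = 2, m = 5, n = 4)
  expect_equal(pFisher(r), bruteHyperTail(2, 5, 4, 20), tolerance = 1e-12)

  set.seed(3)
  for (i in 1:50) {
    N <- sample(10:400, 1)
    m <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(max(0, n + m - N):min(m, n), 1)
    r <- fisherEnrichment(universe = N, k = k, m = m, n = n)
    expect_equal(pFisher(r), bruteHyperTail(k, m, n, N), tolerance = 1e-10)
    # definitional identity: fold * (n/N) * m = k
    expect_equal(foldEnrichment(r) * (n / N) * m, k, tolerance = 1e-9)
    # cross-check against the standard distribution function
    expect_equal(pFisher(r),
                 phyper(k - 1, m, N - m, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("zero overlap gives fold 0 and p 1", {
  r <- fisherEnrichment(universe = 100, k = 0, m = 10, n = 10)
  expect_equal(foldEnrichment(r), 0)
  expect_equal(pFisher(r), 1)
  expect_equal(pEase(r), 1)
  expect_false(isSignificant(r))
})

test_that("enrichment from gene vectors resolves members against the universe", {
  universe <- sprintf("u%03d", 1:100)
  set <- c(universe[1:10], "outsider1", "outsider2")
  lst <- c(universe[6:20], "outsider1")
  r <- fisherEnrichment(lst, set, universe)
  expect_equal(setSize(r), 10)      # outsiders dropped before counting m
  expect_equal(listSize(r), 15)
  expect_equal(overlapCount(r), 5)
  expect_error(fisherEnrichment(lst, set, character()), "empty universe")
})

test_that("EASE correction decrements the overlap and is conservative", {
  r1 <- easeFisher(universe = 1000, k = 1, m = 20, n = 50)
  expect_equal(pEase(r1), 1)

  ra <- fisherEnrichment(universe = 1000, k = 10, m = 20, n = 50)
  rb <- fisherEnrichment(universe = 1000, k = 9, m = 20, n = 50)
  expect_equal(pEase(ra), pFisher(rb), tolerance = 1e-12)

  set.seed(8)
  for (i in 1:200) {
    N <- sample(20:2000, 1)
    m <- sample(1:(N %/% 2), 1); n <- sample(1:(N %/% 2), 1)
    k <- sample(max(0, n + m - N):min(m, n), 1)
    r <- fisherEnrichment(universe = N, k = k, m = m, n = n)
    expect_gte(pEase(r), pFisher(r))
  }
})

test_that("printed-table arithmetic reproduces percentages, stars and folds", {
  # construct a universe and lists realising published-style marginals
  universe <- sprintf("g%05d", 1:14075)
  comp <- universe[1:28]
  lists <- list(
    t1 = c(comp[1:6], universe[1000:1334]),   # n = 341, k = 6
    t2 = c(comp[1:8], universe[2000:2478]),   # n = 487, k = 8
    t3 = c(comp[1:23], universe[3000:3405]))  # n = 429, k = 23
  tab <- enrichmentTable(lists, list(compartmental = comp), universe)
  cmp <- tab[tab$set == "compartmental", ]
  expect_equal(cmp$percent[cmp$timepoint == "t1"], 21.4)
  expect_equal(cmp$percent[cmp$timepoint == "t2"], 28.6)
  expect_equal(cmp$percent[cmp$timepoint == "t3"], 82.1)
  expect_true(all(cmp$significant))
  expect_identical(cmp$cell[cmp$timepoint == "t1"], "6* (21.4%)")
  gen <- tab[tab$set == "_universe_", ]
  expect_equal(gen$percent[gen$timepoint == "t3"], 3.0)
  expect_equal(round(cmp$fold[cmp$timepoint == "t3"]), 27)
})

test_that("empty-after-resolution sets are reported untestable", {
  universe <- sprintf("g%03d", 1:50)
  tab <- enrichmentTable(list(t1 = universe[1:5]),
                         list(ghost = c("x1", "x2")), universe)
  row <- tab[tab$set == "ghost", ]
  expect_false(row$testable)
  expect_identical(row$cell, "untestable")
})

test_that("planted gene-set enrichment is starred, unplanted sets rarely", {
  set.seed(17)
  universe <- sprintf("g%04d", 1:2000)
  lst <- universe[1:100]
  planted <- c(universe[1:30], universe[500:519])       # 30/50 in list
  nulls <- lapply(1:40, function(i) sample(universe, 50))
  names(nulls) <- sprintf("null%02d", 1:40)
  tab <- enrichmentTable(list(t1 = lst),
                         c(list(planted = planted), nulls), universe)
  expect_true(tab$significant[tab$set == "planted"])
  false_star <- mean(tab$significant[grepl("^null", tab$set)])
  expect_lt(false_star, 0.2)   # nominal alpha = 0.05, generous MC slack
})

test_that("term enrichment ranks the self-term and planted terms on top", {
  universe <- sprintf("g%04d", 1:500)
  lst <- universe[1:25]
  ann <- rbind(
    data.frame(gene_id = lst, term_id = "SELF", term_name = "the list",
               is_pns_related = 1),
    data.frame(gene_id = sample(universe, 200), term_id = "BG",
               term_name = "background", is_pns_related = 0))
  out <- termEnrichment(lst, ann, universe)
  expect_identical(out$term_id[1], "SELF")
  expect_identical(out$is_pns_related[1], 1L)

  # planted term among the top ranks in a GO-like annotation
  set.seed(9)
  terms <- lapply(1:30, function(i) sample(universe, 40))
  names(terms) <- sprintf("T%02d", 1:30)
  terms$PLANT <- c(lst[1:15], sample(setdiff(universe, lst), 25))
  ann2 <- do.call(rbind, lapply(names(terms), function(t)
    data.frame(gene_id = terms[[t]], term_id = t, term_name = t,
               is_pns_related = 0)))
  out2 <- termEnrichment(lst, ann2, universe, top = 5)
  expect_true("PLANT" %in% out2$term_id)
  expect_lte(nrow(out2), 5)

  # shuffling gene labels destroys the planted signal most of the time
  set.seed(10)
  ps <- replicate(20, {
    shuffled <- setNames(sample(universe), universe)
    ann3 <- ann2
    ann3$gene_id <- shuffled[ann3$gene_id]
    row <- termEnrichment(lst, ann3, universe, top = 31)
    row$p_ease[row$term_id == "PLANT"]
  })
  expect_gte(mean(ps > 0.05), 0.9)
})
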