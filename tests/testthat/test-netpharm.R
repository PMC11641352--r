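test_that("merge_disease_genes unions, deduplicates and applies the strict score filter", {
  g <- merge_disease_genes(list(c("a", "b"), c("b", "c"), c("c", "d")))
  expect_equal(g, c("A", "B", "C", "D"))

  scored <- data.frame(symbol = c("g1", "g2", "g3"), score = c(4.9, 5.0, 5.1))
  expect_equal(merge_disease_genes(list(scored), threshold = 5), "G3")
  expect_equal(merge_disease_genes(list(scored), threshold = 5, strict = FALSE),
               c("G2", "G3"))
  expect_error(merge_disease_genes(list(data.frame(symbol = "x", score = 1))),
               "empty")
})

test_that("merged size is bounded by the sum of list sizes, equal iff disjoint", {
  set.seed(61)
  pool <- sprintf("G%03d", 1:60)
  for (rep in 1:25) {
    lists <- replicate(3, sample(pool, sample(5:20, 1)), simplify = FALSE)
    total <- sum(lengths(lists))
    merged <- merge_disease_genes(lists)
    expect_lte(length(merged), total)
    disjoint <- all(lengths(lists) == lengths(lapply(lists, unique))) &&
      length(unique(unlist(lists))) == total
    expect_equal(length(merged) == total, disjoint)
  }
})

test_that("scored lists sized 1386/859/770 with 586 cross-listed symbols merge to 2429", {
  universe <- sprintf("G%04d", 1:2429)
  a <- universe[1:1386]
  b <- c(universe[1:300], universe[1387:1945])          # 300 repeats + 559 fresh
  c_ <- c(universe[301:586], universe[1946:2429])       # 286 repeats + 484 fresh
  expect_equal(lengths(list(a, b, c_)), c(1386L, 859L, 770L))
  merged <- merge_disease_genes(list(a, b, c_))
  expect_equal(length(merged), 2429L)
})

test_that("gene_overlap is a symmetric, idempotent set intersection", {
  ov <- gene_overlap(c("g1", "g2", "g3"), c("g2", "g3", "g4"))
  expect_equal(ov$genes, c("G2", "G3"))
  expect_equal(ov$count, 2L)
  expect_equal(gene_overlap(c("a"), c("b"))$count, 0L)
  s <- c("x", "y", "z")
  expect_equal(gene_overlap(s, s)$genes, gene_set(s))
  set.seed(15)
  for (rep in 1:20) {
    A <- sample(sprintf("G%02d", 1:30), 10)
    B <- sample(sprintf("G%02d", 1:30), 10)
    expect_identical(gene_overlap(A, B), gene_overlap(B, A))
  }
})

test_that("rank_molecules orders by count descending with id tie-breaks", {
  tmap <- list(A = sprintf("G%d", 1:5), B = sprintf("G%d", 1:3),
               C = sprintf("G%d", 3:5), D = "G1")
  disease <- sprintf("G%d", 1:10)
  r <- rank_molecules(tmap, disease, top = 3)
  expect_equal(r$id, c("A", "B", "C"))
  expect_equal(r$count, c(5L, 3L, 3L))

  none <- rank_molecules(list(B = "X1", A = "X2"), disease)
  expect_equal(none$id, c("A", "B"))
  expect_equal(none$count, c(0L, 0L))
  expect_error(rank_molecules(list(), disease), "empty target map")
})

test_that("rank_molecules matches an exhaustive counting oracle on random maps", {
  set.seed(33)
  pool <- sprintf("G%03d", 1:80)
  for (rep in 1:10) {
    tmap <- setNames(
      replicate(20, sample(pool, sample(3:25, 1)), simplify = FALSE),
      sprintf("MOL%02d", 1:20)
    )
    disease <- sample(pool, 40)
    r <- rank_molecules(tmap, disease)
    counts <- vapply(tmap, function(g) length(intersect(unique(toupper(g)),
                                                        toupper(disease))), 1L)
    ord <- order(-counts, names(counts))
    expect_equal(r$id, names(counts)[ord])
    expect_equal(r$count, unname(counts[ord]))
  }
})

test_that("top_hubs ranks by degree with symbol tie-breaks and truncates", {
  star <- data.frame(from = rep("H", 5), to = sprintf("L%d", 1:5))
  expect_equal(top_hubs(star, 1)$gene, "H")

  tiny <- data.frame(from = c("A", "B"), to = c("B", "C"))
  r <- top_hubs(tiny, 10)
  expect_equal(nrow(r), 3L)
  expect_equal(r$gene[1], "B")
  expect_equal(r$gene[2:3], c("A", "C"))  # degree tie -> symbol order

  pair <- data.frame(from = "N2", to = "N1")
  expect_equal(top_hubs(pair, 2)$gene, c("N1", "N2"))
})

test_that("top_hubs equals a brute-force degree tally on random graphs", {
  set.seed(71)
  for (rep in 1:100) {
    n <- sample(5:50, 1)
    nodes <- sprintf("V%02d", seq_len(n))
    m <- sample(n:(2 * n), 1)
    edges <- unique(data.frame(
      from = sample(nodes, m, replace = TRUE),
      to = sample(nodes, m, replace = TRUE)
    ))
    edges <- edges[edges$from != edges$to, ]
    # drop reversed duplicates so the tally counts each undirected edge once
    key <- apply(edges, 1, function(r) paste(sort(r), collapse = "|"))
    edges <- edges[!duplicated(key), ]
    if (nrow(edges) == 0) next
    r <- top_hubs(edges, n)
    deg <- oracle_degrees(edges)
    ord <- order(-deg, names(deg))
    expect_equal(r$gene, names(deg)[ord])
    expect_equal(r$degree, unname(deg[ord]))
  }
  expect_error(top_hubs(data.frame(from = character(), to = character())),
               "empty network")
})

test_that("hypergeom_enrich matches exhaustive enumeration for small universes", {
  # N=10, K=5, n=4, k=4 -> choose(5,4)*choose(5,0)/choose(10,4) = 5/210
  uni <- sprintf("G%02d", 1:10)
  res <- hypergeom_enrich(uni[1:4], list(term = uni[1:5]), universe = uni)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)

  set.seed(55)
  for (rep in 1:30) {
    N <- sample(4:12, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    uni <- sprintf("U%02d", seq_len(N))
    ann <- if (K > 0) uni[seq_len(K)] else character()
    query <- sample(uni, n)
    res <- hypergeom_enrich(query, list(t = ann), universe = uni)
    k <- length(intersect(query, ann))
    expect_equal(res$p_value, oracle_hypergeom(N, K, n, k), tolerance = 1e-12)
    expect_true(res$p_value >= 0 && res$p_value <= 1)
    expect_gte(res$p_adjusted, res$p_value)
  }
})

test_that("empty annotation terms give p = 1 and BH follows the step-up rule", {
  uni <- sprintf("G%02d", 1:10)
  res <- hypergeom_enrich(uni[1:3], list(empty = character()), universe = uni)
  expect_equal(res$p_value, 1)

  # raw {0.01, 0.02, 0.03} -> BH-adjusted all 0.03
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  # BH through the enrichment interface stays monotone in rank order
  set.seed(9)
  uni <- sprintf("U%02d", 1:12)
  ann <- lapply(1:6, function(i) sample(uni, sample(2:8, 1)))
  names(ann) <- sprintf("T%d", 1:6)
  res <- hypergeom_enrich(sample(uni, 5), ann, universe = uni)
  expect_true(all(diff(res$p_adjusted) >= -1e-15))
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_error(hypergeom_enrich(c("ZZ9"), ann, universe = uni), "ZZ9")
})

test_that("merge_neighbor_lists reproduces hub-expansion union arithmetic", {
  # 2 hubs + two 20-gene lists with exactly one symbol duplicated -> 41
  hubs <- c("PPARG", "PTGS2")
  l1 <- sprintf("A%02d", 1:20)
  l2 <- c(sprintf("B%02d", 1:19), "A01")
  expect_length(merge_neighbor_lists(hubs, list(l1, l2)), 41L)
  # fully disjoint lists of sizes 2, 20, 20 -> 42
  expect_length(merge_neighbor_lists(hubs, list(sprintf("C%02d", 1:20),
                                                sprintf("D%02d", 1:20))), 42L)
  expect_length(merge_neighbor_lists(hubs, list(l1, l1)), 22L)
})

test_that("TSV / GMT readers round-trip the netpharm inputs", {
  dir <- withr::local_tempdir()
  gl <- file.path(dir, "genecards.tsv")
  writeLines(c("symbol\tscore", "lep\t7.5", "ADIPOQ\t4.2", "PPARG\t9.1"), gl)
  sl <- read_scored_gene_list(gl)
  expect_equal(merge_disease_genes(list(sl), threshold = 5), c("LEP", "PPARG"))

  tm <- file.path(dir, "targets.tsv")
  writeLines(c("molecule\tsymbol", "m1\tPPARG", "m1\tPTGS2", "m2\tLEP"), tm)
  tmap <- read_target_map(tm)
  expect_equal(sort(names(tmap)), c("m1", "m2"))
  expect_setequal(tmap$m1, c("PPARG", "PTGS2"))

  el <- file.path(dir, "edges.tsv")
  writeLines(c("a\tb", "PPARG\tPTGS2", "PPARG\tLEP", "PTGS2\tPPARG"), el)
  g <- read_edge_list(el)
  expect_equal(igraph::ecount(g), 2) # reversed duplicate collapsed
  expect_equal(top_hubs(g, 1)$gene, "PPARG")

  gmt <- file.path(dir, "sets.gmt")
  writeLines(c("SET1\tdesc\tPPARG\tLEP", "SET2\tdesc\tPTGS2"), gmt)
  sets <- read_gmt(gmt)
  expect_equal(names(sets), c("SET1", "SET2"))
  expect_equal(sets$SET1, c("LEP", "PPARG"))
})
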