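test_that("best_combination screens the bundled docking table as published", {
  tab <- docking_table()
  expect_equal(nrow(tab), 12L)
  best_ptgs2 <- best_combination(tab, "PTGS2")
  expect_equal(best_ptgs2$molecule, "Hederagenin")
  expect_equal(best_ptgs2$energy, -8.8)
  best_pparg <- best_combination(tab, "PPARG")
  expect_equal(best_pparg$molecule, "Triptonide")
  expect_equal(best_pparg$energy, -6.5)
  # global optimum is the PTGS2 combination
  expect_equal(best_combination(tab)$energy, -8.8)
})

test_that("best_combination handles single rows, ties and bad input", {
  one <- data.frame(molecule = "X", target = "T", energy = -3)
  expect_equal(best_combination(one)$molecule, "X")

  ties <- data.frame(molecule = c("B", "A", "A"), target = c("T1", "T2", "T1"),
                     energy = c(-5, -5, -5))
  b <- best_combination(ties)
  expect_equal(c(b$molecule, b$target), c("A", "T1"))

  expect_error(best_combination(one, target = "NOPE"), "unknown target")
  expect_error(best_combination(one[0, ]), "empty")
  dup <- rbind(one, one)
  expect_error(best_combination(dup), "duplicate")
  inf <- data.frame(molecule = "X", target = "T", energy = Inf)
  expect_error(best_combination(inf), "non-finite")
})

test_that("best_combination equals a full-scan oracle on random tables", {
  set.seed(77)
  for (rep in 1:1000) {
    nr <- sample(1:30, 1)
    tab <- unique(data.frame(
      molecule = sample(sprintf("M%02d", 1:8), nr, replace = TRUE),
      target = sample(c("T1", "T2", "T3"), nr, replace = TRUE)
    ))
    tab$energy <- round(rnorm(nrow(tab), -6, 2), 1)
    b <- best_combination(tab)
    ord <- order(tab$energy, tab$molecule, tab$target)
    expect_equal(unlist(b), unlist(tab[ord[1], ]), ignore_attr = TRUE)
  }
})

test_that("aggregate_snapshots derives sums, means and sample sds with exact identities", {
  one <- data.frame(evdw = -50, eele = -10, gsolv = 30)
  agg1 <- aggregate_snapshots(one)
  expect_equal(agg1$summary$mean, c(-50, -10, 30, -60, -30))
  expect_equal(agg1$summary$sd, rep(0, 5))

  const <- data.frame(evdw = rep(-50, 6), eele = rep(-10, 6), gsolv = rep(30, 6))
  aggc <- aggregate_snapshots(const)
  expect_equal(aggc$summary$mean, c(-50, -10, 30, -60, -30))
  expect_equal(aggc$summary$sd, rep(0, 5))

  set.seed(12)
  rnd <- data.frame(evdw = rnorm(20, -55, 3), eele = rnorm(20, -12, 5),
                    gsolv = rnorm(20, 35, 4))
  agg <- aggregate_snapshots(rnd)
  s <- setNames(agg$summary$mean, agg$summary$component)
  expect_equal(s[["ggas"]], s[["evdw"]] + s[["eele"]], tolerance = 1e-9)
  expect_equal(s[["gtotal"]], s[["ggas"]] + s[["gsolv"]], tolerance = 1e-9)
  expect_true(all(agg$summary$sd >= 0))
  expect_equal(s[["evdw"]], mean(rnd$evdw))
  expect_equal(agg$summary$sd[1], sd(rnd$evdw))

  bad <- data.frame(snapshot = 1:3, evdw = c(-1, NaN, -2), eele = 0, gsolv = 0)
  expect_error(aggregate_snapshots(bad), "snapshot\\(s\\) 2")
})

test_that("snapshot aggregation recovers generator ground truth within sampling error", {
  mu <- c(evdw = -54.88, eele = -32.45, gsolv = 47.21)
  sg <- c(evdw = 3.73, eele = 18.59, gsolv = 12.81)
  snaps <- gen_mmpbsa_snapshots(mu, sg, n = 20, seed = 88)
  agg <- aggregate_snapshots(snaps)
  s <- setNames(agg$summary$mean, agg$summary$component)
  for (cn in names(mu)) {
    expect_lt(abs(s[[cn]] - mu[[cn]]), 3 * sg[[cn]] / sqrt(20))
  }
})

test_that("totals_from_means reproduces printed MM/PBSA rows", {
  # fully self-consistent published rows at 2 dp
  expect_equal(unname(totals_from_means(-54.88, -32.45, 47.21, digits = 2)),
               c(-87.33, -40.12))
  expect_equal(unname(totals_from_means(-60.23, -7.18, 32.38, digits = 2)),
               c(-67.41, -35.03))
  expect_equal(unname(totals_from_means(0, 0, 0)), c(0, 0))
  expect_equal(unname(totals_from_means(gsolv = 47.21, ggas = -87.33)),
               c(-87.33, -40.12))
})

test_that("every bundled MM/PBSA row is component-consistent to within 0.01 kcal/mol", {
  inconsistent <- 0L
  for (target in c("PPARG", "PTGS2")) {
    tab <- mmpbsa_table(target)
    for (i in seq_len(nrow(tab))) {
      tt <- totals_from_means(tab$evdw_mean[i], tab$eele_mean[i],
                              tab$gsolv_mean[i], digits = 2)
      dgas <- abs(tt[["ggas"]] - tab$ggas_mean[i])
      dtot <- abs(tt[["gtotal"]] - tab$gtotal_mean[i])
      expect_lte(dgas, 0.01 + 1e-9)
      expect_lte(dtot, 0.01 + 1e-9)
      if (dgas > 1e-9 || dtot > 1e-9) inconsistent <- inconsistent + 1L
    }
  }
  # half of the published rows carry independently rounded totals
  expect_equal(inconsistent, 6L)
})

test_that("hbond_stats computes occupancies and bonds per frame", {
  # pair present in 925 of 1000 frames -> 92.5%
  fr <- data.frame(frame = 1:925, donor = "ARG81-Side", acceptor = "6Q5271-Side")
  hs <- hbond_stats(fr, n_frames = 1000)
  expect_equal(hs$occupancy$occupancy_pct, 92.5)
  expect_equal(hs$mean_bonds_per_frame, 0.925)

  # frames with bond counts [2, 2, 2, 3, 1] -> mean 2.0
  counts <- c(2, 2, 2, 3, 1)
  fr2 <- do.call(rbind, lapply(seq_along(counts), function(f) {
    data.frame(frame = f, donor = sprintf("D%d", seq_len(counts[f])),
               acceptor = "A")
  }))
  expect_equal(hbond_stats(fr2)$mean_bonds_per_frame, 2)

  # absent pair has no row; empty-marker rows keep the denominator honest
  fr3 <- data.frame(frame = 1:4, donor = c("D", "", "", ""),
                    acceptor = c("A", "", "", ""))
  hs3 <- hbond_stats(fr3)
  expect_equal(hs3$n_frames, 4L)
  expect_equal(hs3$occupancy$occupancy_pct, 25)
  expect_equal(hs3$mean_bonds_per_frame, 0.25)
  expect_error(hbond_stats(fr3[0, ]), "at least one frame")
})

test_that("repeated pairs in a frame count once for occupancy but fully for the mean", {
  fr <- data.frame(frame = c(1, 1, 2), donor = "D", acceptor = "A")
  hs <- hbond_stats(fr, n_frames = 2)
  expect_equal(hs$occupancy$occupancy_pct, 100)
  expect_equal(hs$mean_bonds_per_frame, 1.5)
})

test_that("occupancy and mean recomputed by an independent tally agree on random frame sets", {
  set.seed(19)
  for (rep in 1:20) {
    nf <- sample(10:60, 1)
    nb <- sample(0:80, 1)
    fr <- data.frame(
      frame = sample.int(nf, nb, replace = TRUE),
      donor = sample(c("D1", "D2", "D3"), nb, replace = TRUE),
      acceptor = sample(c("A1", "A2"), nb, replace = TRUE)
    )
    hs <- hbond_stats(fr, n_frames = nf)
    expect_equal(hs$mean_bonds_per_frame, nb / nf, tolerance = 1e-12)
    if (nb > 0) {
      for (i in seq_len(nrow(hs$occupancy))) {
        d <- hs$occupancy$donor[i]; a <- hs$occupancy$acceptor[i]
        manual <- length(unique(fr$frame[fr$donor == d & fr$acceptor == a]))
        expect_identical(hs$occupancy$frames_present[i], manual)
        expect_equal(hs$occupancy$occupancy_pct[i], 100 * manual / nf)
      }
    }
  }
})

test_that("CSV readers normalize the Unicode minus", {
  dir <- withr::local_tempdir()
  dk <- file.path(dir, "dock.csv")
  writeLines(c("molecule,target,energy", "Hederagenin,PTGS2,−8.8"), dk)
  tab <- read_docking_table(dk)
  expect_equal(tab$energy, -8.8)

  sn <- file.path(dir, "snaps.csv")
  writeLines(c("snapshot,evdw,eele,gsolv", "1,−50.0,−10.0,30.0"), sn)
  agg <- aggregate_snapshots(read_snapshots(sn))
  expect_equal(agg$summary$mean, c(-50, -10, 30, -60, -30))
})
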